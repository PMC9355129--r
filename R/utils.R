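# internal helpers: group labels, seeded substreams, DNA encoding

.GROUPS <- c("Q", "A", "PAN")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a local RNG state; restores .Random.seed on exit so
# generator calls never perturb the caller's random stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Named substream seed derived from a master seed: a small polynomial hash
# of the stream name folded into the seed, kept inside 32-bit integer range.
# Changing one stage's parameters therefore never shifts another stage's draws.
substream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1014741823
  as.integer((abs(seed) %% 1014741823 + h * 2) %% 2147483629)
}

# Encode DNA as integers A=1 C=2 G=3 T=4; anything else (lowercase soft-mask,
# N, gaps) becomes 0 and is treated as masked by the scanner.
encode_dna <- function(seq) {
  v <- utf8ToInt(seq)
  out <- integer(length(v))
  out[v == 65L] <- 1L
  out[v == 67L] <- 2L
  out[v == 71L] <- 3L
  out[v == 84L] <- 4L
  out
}

.stop_scalar <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
}
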