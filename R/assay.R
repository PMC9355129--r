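# Bench-side quantification: exon retention, ddCt, reporter ratio,
# cycloheximide-chase half-life.

#' Percent exon retention from gel band intensities
#'
#' `100 * I_FL / (I_FL + I_dE6)` for the exon-included (full-length) and
#' exon-skipped band of a splicing RT-PCR resolved on a gel. With
#' `molar_correct`, intensities are first divided by amplicon length so the
#' ratio counts molecules rather than stained mass.
#'
#' @param intensity_fl,intensity_de6 band intensities (arbitrary units,
#'   >= 0; not both zero). Vectorised.
#' @param molar_correct divide intensities by amplicon lengths first.
#' @param length_fl,length_de6 amplicon lengths in bp (required when
#'   `molar_correct`).
#' @return percent retention in \[0, 100\].
#' @export
#' @examples
#' percent_exon_retention(3, 1)  # 75
percent_exon_retention <- function(intensity_fl, intensity_de6,
                                   molar_correct = FALSE,
                                   length_fl = NULL, length_de6 = NULL) {
  if (any(intensity_fl < 0) || any(intensity_de6 < 0))
    stop("negative intensity", call. = FALSE)
  if (any(intensity_fl + intensity_de6 == 0))
    stop("both band intensities are zero", call. = FALSE)
  if (molar_correct) {
    if (is.null(length_fl) || is.null(length_de6))
      stop("molar correction needs both amplicon lengths", call. = FALSE)
    intensity_fl <- intensity_fl / length_fl
    intensity_de6 <- intensity_de6 / length_de6
  }
  100 * intensity_fl / (intensity_fl + intensity_de6)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_reference) - (Ct_target_cal - Ct_reference_cal)`;
#' fold change is `2^-ddCt` (amplification efficiency fixed at 2).
#'
#' @param ct_target,ct_reference sample Ct values (target and reference
#'   gene).
#' @param ct_target_cal,ct_reference_cal calibrator-sample Ct values.
#' @return fold change (> 0). Vectorised.
#' @export
ddct_fold_change <- function(ct_target, ct_reference, ct_target_cal,
                             ct_reference_cal) {
  cts <- cbind(ct_target, ct_reference, ct_target_cal, ct_reference_cal)
  if (any(!is.finite(cts))) stop("non-finite Ct value", call. = FALSE)
  2^-((ct_target - ct_reference) - (ct_target_cal - ct_reference_cal))
}

#' Dual-reporter normalised fold change
#'
#' eGFP signal normalised to the co-delivered mCherry reference, relative to
#' a calibrator sample: `(egfp/mcherry) / (egfp_cal/mcherry_cal)`.
#'
#' @param egfp,mcherry sample reporter signals (> 0).
#' @param egfp_cal,mcherry_cal calibrator signals (> 0).
#' @return fold change. Vectorised.
#' @export
reporter_ratio <- function(egfp, mcherry, egfp_cal, mcherry_cal) {
  v <- cbind(egfp, mcherry, egfp_cal, mcherry_cal)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all reporter signals must be positive", call. = FALSE)
  (egfp / mcherry) / (egfp_cal / mcherry_cal)
}

#' In-frame exon length conversions
#'
#' For an in-frame cassette exon (length divisible by 3), the number of
#' residues it encodes is its length over 3; e.g. the 84-nt alternative
#' exon 6 of *Lef1* encodes the 28 residues missing from the short isoform.
#'
#' @param nt exon length in nucleotides (multiple of 3).
#' @return number of encoded amino-acid residues.
#' @export
#' @examples
#' exon_residue_count(84)  # 28
exon_residue_count <- function(nt) {
  if (any(nt %% 3 != 0))
    stop("an in-frame exon length must be a multiple of 3", call. = FALSE)
  nt / 3
}

#' @rdname exon_residue_count
#' @param aa number of residues.
#' @return exon length in nucleotides.
#' @export
exon_nt_length <- function(aa) 3 * aa

#' Protein half-life from a cycloheximide-chase series
#'
#' Fits ordinary least squares of `log(intensity)` on time (the standard
#' log-linear model for first-order decay after translation block):
#' `k = -slope`, `t_half = ln(2)/k`. A non-positive decay rate returns a
#' flagged fit with `t_half = Inf`.
#'
#' @param time_h timepoints in hours; >= 3 points, strictly increasing,
#'   starting at 0.
#' @param intensity loading-control-normalised intensities (> 0).
#' @return object of class `half_life_fit`: `k` (per hour), `t_half`
#'   (hours), `r_squared`, `flagged`, `n`.
#' @export
#' @examples
#' fit_half_life(c(0, 1, 2, 4), exp(-log(2) / 2 * c(0, 1, 2, 4)))
fit_half_life <- function(time_h, intensity) {
  if (length(time_h) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (length(intensity) != length(time_h))
    stop("time and intensity lengths differ", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (time_h[1L] != 0) stop("first timepoint must be 0", call. = FALSE)
  if (any(!is.finite(intensity) | intensity <= 0))
    stop("intensities must be positive", call. = FALSE)
  fit <- stats::lm(log(intensity) ~ time_h)
  slope <- unname(stats::coef(fit)[2L])
  y <- log(intensity)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0
  k <- -slope
  structure(list(k = k,
                 t_half = if (k > 0) log(2) / k else Inf,
                 r_squared = r2, flagged = k <= 0,
                 n = length(time_h)),
            class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  if (x$flagged)
    cat(sprintf("half-life fit: no decay (k = %.4g /h), t1/2 = Inf%s\n",
                x$k, " [flagged]"))
  else
    cat(sprintf("half-life fit: k = %.4g /h, t1/2 = %.3g h, R2 = %.3f (n=%d)\n",
                x$k, x$t_half, x$r_squared, x$n))
  invisible(x)
}
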