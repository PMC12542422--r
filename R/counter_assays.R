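# Counter assays: gamma-H2AX positive-cell fraction (DNA damage) and the
# per-nucleus integrated GFP of a degron reporter (proteasome activity /
# protein synthesis). Both replace manual counting with explicit,
# configurable positivity rules calibrated on a negative-control condition.

#' gamma-H2AX-positive cell fraction
#'
#' A cell is positive when its nuclear gamma-H2AX top-hat focus count
#' reaches `spot_min`, or when its nuclear mean intensity exceeds a
#' control-calibrated threshold (negative-control mean + `mean_k` SD). The
#' fraction is positives over all segmented nuclei.
#'
#' @param nuclei a [label_grid()] segmented from the Hoechst channel of the
#'   same site.
#' @param h2ax gamma-H2AX channel matrix.
#' @param spot_min minimum focus count for positivity (default 5).
#' @param control_means optional numeric vector of per-nucleus mean
#'   intensities from the negative-control condition, used to calibrate the
#'   intensity rule; if `NULL` the intensity rule is skipped.
#' @param mean_k SD multiplier of the calibrated intensity rule.
#' @param spot_radius_um,spot_thresh top-hat focus detection parameters.
#' @return list of class `counter_assay_result`: `n`, `positive_fraction`,
#'   `per_cell` (cell, spots, mean intensity, positive), `threshold`.
#'   `NA` fraction with a reason when there are no nuclei.
#' @export
h2ax_positive_fraction <- function(nuclei, h2ax, spot_min = 5L,
                                   control_means = NULL, mean_k = 3,
                                   spot_radius_um = 2.0,
                                   spot_thresh = 0.15) {
  n_lab <- max(nuclei$labels)
  if (n_lab == 0)
    return(structure(list(n = 0L, positive_fraction = NA_real_,
                          per_cell = NULL, threshold = NA_real_,
                          reason = "no nuclei"),
                     class = "counter_assay_result"))
  ps <- nuclei$pixel_size_um
  lab <- nuclei$labels
  idx <- which(lab > 0); l <- lab[idx]
  st <- per_label_stats(h2ax[idx], l, n_lab)
  br_d <- 2L * max(1L, as.integer(round(spot_radius_um / ps))) + 1L
  th_img <- as.matrix(EBImage::whiteTopHat(
    EBImage::Image(h2ax), EBImage::makeBrush(br_d, shape = "disc")))
  spot_lab <- as.matrix(EBImage::bwlabel(EBImage::Image(th_img > spot_thresh)))
  spots <- integer(n_lab)
  for (li in seq_len(n_lab)) {
    sp <- spot_lab[idx[l == li]]
    spots[li] <- length(unique(sp[sp > 0]))
  }
  thr <- if (!is.null(control_means) && length(control_means) >= 2)
    mean(control_means) + mean_k * stats::sd(control_means) else NA_real_
  positive <- spots >= spot_min |
    (!is.na(thr) & st$mean > thr)
  structure(list(n = n_lab,
                 positive_fraction = mean(positive),
                 per_cell = data.frame(cell = seq_len(n_lab), spots = spots,
                                       mean_intensity = st$mean,
                                       positive = positive),
                 threshold = thr),
            class = "counter_assay_result")
}

#' Per-nucleus integrated GFP of the degron reporter
#'
#' Sums the GFP channel over each segmented nucleus. The condition summary
#' is the median integrated intensity and the GFP-positive fraction against
#' a threshold calibrated from a negative (e.g. uninduced) condition.
#'
#' @param nuclei a [label_grid()] (segmented from the DNA channel).
#' @param gfp GFP channel matrix.
#' @param control_integrated optional per-nucleus integrated intensities of
#'   the negative condition; positivity threshold = its mean + `mean_k` SD.
#' @param mean_k SD multiplier.
#' @return list of class `counter_assay_result`: `n`, `integrated`
#'   (per-nucleus vector), `median_integrated`, `positive_fraction`,
#'   `threshold`.
#' @export
nuclear_gfp_levels <- function(nuclei, gfp, control_integrated = NULL,
                               mean_k = 3) {
  n_lab <- max(nuclei$labels)
  if (n_lab == 0)
    return(structure(list(n = 0L, integrated = numeric(0),
                          median_integrated = NA_real_,
                          positive_fraction = NA_real_,
                          threshold = NA_real_, reason = "no nuclei"),
                     class = "counter_assay_result"))
  lab <- nuclei$labels
  idx <- which(lab > 0)
  st <- per_label_stats(gfp[idx], lab[idx], n_lab)
  thr <- if (!is.null(control_integrated) && length(control_integrated) >= 2)
    mean(control_integrated) + mean_k * stats::sd(control_integrated)
  else NA_real_
  structure(list(n = n_lab, integrated = st$sum,
                 median_integrated = stats::median(st$sum),
                 positive_fraction = if (is.na(thr)) NA_real_
                                     else mean(st$sum > thr),
                 threshold = thr),
            class = "counter_assay_result")
}

#' @export
print.counter_assay_result <- function(x, ...) {
  cat("Counter-assay result: n =", x$n)
  if (!is.null(x$positive_fraction) && !is.na(x$positive_fraction))
    cat(", positive fraction =", round(x$positive_fraction, 3))
  if (!is.null(x$median_integrated) && !is.na(x$median_integrated))
    cat(", median integrated =", signif(x$median_integrated, 4))
  cat("\n")
  invisible(x)
}

#' Degradation readout: ratio of median nuclear GFP (+auxin / -auxin)
#'
#' @param plus_auxin,minus_auxin `counter_assay_result`s from
#'   [nuclear_gfp_levels()].
#' @return numeric ratio of medians.
#' @export
gfp_degradation_ratio <- function(plus_auxin, minus_auxin) {
  if (is.na(plus_auxin$median_integrated) ||
      is.na(minus_auxin$median_integrated) ||
      minus_auxin$median_integrated <= 0)
    return(NA_real_)
  plus_auxin$median_integrated / minus_auxin$median_integrated
}
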