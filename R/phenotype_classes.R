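#' Canonical per-cell phenotype classes
#'
#' The eight phenotype classes used throughout the pipeline, in their fixed
#' canonical order: the four interphase localization classes (nucleolar,
#' nucleolar/nucleoplasmic, nucleoplasmic, cytoplasmic reporter signal),
#' followed by mitotic cells, apoptotic cells, cells without fluorescence
#' signal, and incorrectly segmented cells. The order is load-bearing: class
#' probability vectors, confusion matrices and tie-breaking in the classifier
#' all follow it.
#'
#' @return character vector of length 8.
#' @export
#' @examples
#' phenotype_classes()
phenotype_classes <- function() {
  c("nucleolar", "nucleolar_nucleoplasmic", "nucleoplasmic", "cytoplasmic",
    "mitotic", "apoptotic", "no_signal", "missegmented")
}

#' Interphase localization classes (subset of [phenotype_classes()])
#' @return character vector of length 4.
#' @keywords internal
interphase_classes <- function() phenotype_classes()[1:4]

assert_classes <- function(x, what = "class labels") {
  bad <- setdiff(unique(as.character(x)), phenotype_classes())
  if (length(bad))
    stopf("unknown %s: %s", what, paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Validate an 8-class probability vector
#' @param p numeric vector.
#' @return the vector, named by class, after validation.
#' @keywords internal
assert_prob8 <- function(p, what = "probability vector") {
  if (length(p) != 8L || anyNA(p) || any(p < 0))
    stopf("%s must be 8 nonnegative values", what)
  if (abs(sum(p) - 1) > 1e-8)
    stopf("%s must sum to 1 (got %.6f)", what, sum(p))
  stats::setNames(as.numeric(p), phenotype_classes())
}

#' Screen readouts
#'
#' The four microscopic readouts: ENP1 immunofluorescence without and with
#' leptomycin B (LMB), and the RPS2-YFP / RPL29-GFP ribosomal-protein
#' reporter lines.
#'
#' @return character vector of length 4.
#' @export
screen_readouts <- function() {
  c("enp1_minus_lmb", "enp1_plus_lmb", "rps2_yfp", "rpl29_gfp")
}

#' Hit / non-hit class mapping for a readout
#'
#' Encodes which phenotype classes count as hits and non-hits for each
#' readout. Mitotic, apoptotic, signal-free and missegmented cells are always
#' excluded from hit-rate denominators. For the -LMB ENP1 readout the
#' denominator is ambiguous in the source material, so three variants are
#' selectable:
#' \describe{
#'   \item{"methods"}{(default) non-hit = nucleolar and
#'     nucleolar/nucleoplasmic signal.}
#'   \item{"results"}{non-hit = nucleolar signal only (rate over cells with
#'     either nucleoplasmic or nucleolar signal).}
#'   \item{"interphase"}{non-hit = all other interphase classes (rate over
#'     all interphase cells).}
#' }
#'
#' @param readout one of [screen_readouts()].
#' @param denominator denominator convention for `enp1_minus_lmb`; ignored
#'   for other readouts.
#' @return an object of class `readout_spec`: list with `readout`, `hit`,
#'   `non_hit`, `excluded` character vectors.
#' @export
#' @examples
#' readout_spec("enp1_plus_lmb")
readout_spec <- function(readout = screen_readouts(),
                         denominator = c("methods", "results", "interphase")) {
  readout <- match.arg(readout)
  denominator <- match.arg(denominator)
  excluded <- c("mitotic", "apoptotic", "no_signal", "missegmented")
  spec <- switch(readout,
    enp1_minus_lmb = list(
      hit = "nucleoplasmic",
      non_hit = switch(denominator,
        methods    = c("nucleolar", "nucleolar_nucleoplasmic"),
        results    = "nucleolar",
        interphase = c("nucleolar", "nucleolar_nucleoplasmic", "cytoplasmic"))),
    enp1_plus_lmb = list(
      hit = "nucleolar",
      non_hit = c("nucleolar_nucleoplasmic", "nucleoplasmic")),
    rps2_yfp = ,
    rpl29_gfp = list(
      hit = c("nucleolar", "nucleolar_nucleoplasmic", "nucleoplasmic"),
      non_hit = "cytoplasmic"))
  out <- list(readout = readout, hit = spec$hit, non_hit = spec$non_hit,
              excluded = setdiff(phenotype_classes(),
                                 c(spec$hit, spec$non_hit)))
  stopifnot(all(out$excluded %in% c(excluded, "cytoplasmic", "nucleolar",
                                    "nucleolar_nucleoplasmic")),
            !anyDuplicated(c(out$hit, out$non_hit)),
            all(excluded %in% out$excluded))
  class(out) <- "readout_spec"
  out
}

#' @export
print.readout_spec <- function(x, ...) {
  cat("Readout:", x$readout, "\n")
  cat("  hit     :", paste(x$hit, collapse = ", "), "\n")
  cat("  non-hit :", paste(x$non_hit, collapse = ", "), "\n")
  cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Default readout specs for all four readouts
#' @inheritParams readout_spec
#' @return named list of `readout_spec` objects.
#' @export
default_readout_specs <- function(denominator = "methods") {
  stats::setNames(
    lapply(screen_readouts(), readout_spec, denominator = denominator),
    screen_readouts())
}
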