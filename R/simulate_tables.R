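# Table-mode screen simulation: draws per-well class counts directly from
# the effect model (optionally pushed through a classifier confusion matrix),
# producing the same schema that image-mode classification followed by
# class_counts() yields. This lets the full 1172-compound, 3-replicate,
# 4-readout screen be exercised at desk scale without rendering images.

#' Simulate per-well class-count tables for a whole screen
#'
#' For every (readout, replicate, well): the well activity is the compound's
#' base activity plus Beta per-well jitter; the true class counts are
#' multinomial draws from the mixed class distribution; observed counts are
#' obtained by perturbing true counts through the classifier confusion
#' matrix (rows = truth). Empty wells are skipped.
#'
#' @param layout a `plate_map` (or rbind of several) from
#'   [build_screen_layout()].
#' @param model an [effect_model()].
#' @param cells_per_well expected classified-cell count per well; realized
#'   counts are Poisson around this mean.
#' @param confusion optional 8x8 row-stochastic confusion matrix in
#'   canonical class order (`NULL` = identity, no misclassification).
#' @param replicates number of biological replicates (>= 1).
#' @param readouts readouts to simulate.
#' @param seed master seed; all randomness derives from it.
#' @return data.frame with columns `readout`, `replicate`, `plate`, `well`,
#'   `role`, `compound_id`, `activity` (realized), `n_cells`, and one count
#'   column per phenotype class.
#' @export
simulate_screen_tables <- function(layout, model,
                                   cells_per_well = 360,
                                   confusion = NULL,
                                   replicates = 3L,
                                   readouts = screen_readouts(),
                                   seed = 1L) {
  if (replicates < 1) stopf("replicates must be >= 1")
  readouts <- match.arg(readouts, screen_readouts(), several.ok = TRUE)
  if (!is.null(confusion)) {
    confusion <- as.matrix(confusion)
    if (!all(dim(confusion) == c(8, 8)) ||
        any(abs(rowSums(confusion) - 1) > 1e-8) || any(confusion < 0))
      stopf("confusion matrix must be 8x8 row-stochastic")
    if (max(abs(confusion - diag(8))) < 1e-12) confusion <- NULL
  }
  wells <- layout[layout$role != "empty", , drop = FALSE]
  cls <- phenotype_classes()
  blocks <- list(); bi <- 0L
  for (ro in readouts) {
    ri <- match(ro, screen_readouts())  # stream keyed by readout identity
    pc <- model$p_ctrl[, ro]; pa <- model$p_act[, ro]
    base <- vapply(seq_len(nrow(wells)), function(i)
      base_activity(model, wells$role[i], wells$compound_id[i], ro),
      numeric(1))
    for (rep_i in seq_len(replicates)) {
      counts <- with_seed(child_seed(seed, (ri - 1L) * 64L + rep_i), {
        act <- pmin(1, base + sample_jitter(model, nrow(wells)))
        n <- stats::rpois(nrow(wells), cells_per_well)
        m <- matrix(0L, nrow(wells), 8L, dimnames = list(NULL, cls))
        for (i in seq_len(nrow(wells))) {
          p <- (1 - act[i]) * pc + act[i] * pa
          true_ct <- stats::rmultinom(1, n[i], p)[, 1]
          if (is.null(confusion)) m[i, ] <- true_ct
          else {
            obs <- integer(8)
            for (k in which(true_ct > 0))
              obs <- obs + stats::rmultinom(1, true_ct[k], confusion[k, ])[, 1]
            m[i, ] <- obs
          }
        }
        list(m = m, act = act, n = n)
      })
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(readout = ro, replicate = rep_i,
                                 plate = wells$plate, well = wells$well,
                                 role = wells$role,
                                 compound_id = wells$compound_id,
                                 activity = counts$act, n_cells = counts$n,
                                 stringsAsFactors = FALSE)
      blocks[[bi]] <- cbind(blocks[[bi]], as.data.frame(counts$m))
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
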