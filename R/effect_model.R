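# Effect model: how a compound shifts the per-cell phenotype class
# distribution of a well, per readout. A well's class distribution is the
# mixture p = (1 - a) * p_ctrl + a * p_act, with activity a in [0, 1].

# Baseline (DMSO) and fully-active class probability vectors per readout.
# Rows follow phenotype_classes(); columns follow screen_readouts().
# Stipulated defaults: the source screen reports no per-class baseline
# frequencies, so these encode the qualitative picture (ENP1 nucleolar at
# baseline without LMB, largely released with LMB; RP reporters cytoplasmic
# at baseline; actives shift signal nucleoplasmic / nucleolar / nuclear
# respectively) with realistic fractions of excluded classes.
default_p_ctrl <- function() {
  m <- cbind(
    enp1_minus_lmb = c(0.55, 0.18, 0.02, 0.05, 0.04, 0.03, 0.08, 0.05),
    enp1_plus_lmb  = c(0.02, 0.25, 0.48, 0.05, 0.04, 0.03, 0.08, 0.05),
    rps2_yfp       = c(0.01, 0.02, 0.02, 0.75, 0.04, 0.03, 0.08, 0.05),
    rpl29_gfp      = c(0.01, 0.02, 0.02, 0.75, 0.04, 0.03, 0.08, 0.05))
  rownames(m) <- phenotype_classes()
  m
}

default_p_act <- function() {
  m <- cbind(
    enp1_minus_lmb = c(0.05, 0.10, 0.60, 0.02, 0.04, 0.06, 0.08, 0.05),
    enp1_plus_lmb  = c(0.60, 0.15, 0.05, 0.02, 0.04, 0.06, 0.05, 0.03),
    rps2_yfp       = c(0.25, 0.30, 0.25, 0.05, 0.04, 0.03, 0.05, 0.03),
    rpl29_gfp      = c(0.25, 0.30, 0.25, 0.05, 0.04, 0.03, 0.05, 0.03))
  rownames(m) <- phenotype_classes()
  m
}

#' Build a compound effect model
#'
#' Describes, per readout, the baseline (DMSO) class-probability vector
#' `p_ctrl`, the fully-active vector `p_act`, and a per-compound activity
#' `a` in `[0, 1]`; a treated well's class distribution is
#' `(1 - a) * p_ctrl + a * p_act`. Negative-control and inactive-library
#' wells additionally receive Beta-distributed per-well activity jitter
#' (default mean 0.02) so the DMSO null has nonzero variance, as a
#' standard-deviation-based hit threshold requires.
#'
#' @param active named numeric vector: activity per active library compound
#'   (compounds absent from the vector are inactive, activity 0). May also be
#'   a compounds-by-readouts matrix for readout-specific activity.
#' @param control_activity activity of positive-control wells.
#' @param p_ctrl,p_act 8-by-4 class-by-readout probability matrices; rows in
#'   canonical class order, columns in [screen_readouts()] order.
#' @param jitter_mean mean of the Beta per-well activity jitter.
#' @param jitter_shape1 first Beta shape parameter; the second is derived
#'   from the mean.
#' @return an object of class `effect_model`.
#' @export
#' @examples
#' em <- effect_model(active = c(cmpd0001 = 0.8))
#' well_class_probs(em, "enp1_plus_lmb", activity = 0.8)
effect_model <- function(active = numeric(0),
                         control_activity = 0.9,
                         p_ctrl = default_p_ctrl(),
                         p_act = default_p_act(),
                         jitter_mean = 0.02,
                         jitter_shape1 = 2) {
  p_ctrl <- as.matrix(p_ctrl); p_act <- as.matrix(p_act)
  stopifnot(identical(colnames(p_ctrl), screen_readouts()),
            identical(colnames(p_act), screen_readouts()))
  for (r in screen_readouts()) {
    assert_prob8(p_ctrl[, r], paste0("p_ctrl[", r, "]"))
    assert_prob8(p_act[, r], paste0("p_act[", r, "]"))
  }
  if (is.matrix(active)) {
    stopifnot(identical(colnames(active), screen_readouts()))
    if (any(active < 0 | active > 1)) stopf("activity must be in [0, 1]")
  } else if (length(active)) {
    if (is.null(names(active)) || any(!nzchar(names(active))))
      stopf("`active` must be named by compound id")
    if (any(active < 0 | active > 1)) stopf("activity must be in [0, 1]")
  }
  stopifnot(control_activity >= 0, control_activity <= 1,
            jitter_mean >= 0, jitter_mean < 1, jitter_shape1 > 0)
  structure(list(active = active,
                 control_activity = control_activity,
                 p_ctrl = p_ctrl, p_act = p_act,
                 jitter_mean = jitter_mean,
                 jitter_shape1 = jitter_shape1,
                 jitter_shape2 = if (jitter_mean > 0)
                   jitter_shape1 * (1 - jitter_mean) / jitter_mean else Inf),
            class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  n_act <- if (is.matrix(x$active)) nrow(x$active) else length(x$active)
  cat("Effect model:", n_act, "active compound(s);",
      "control activity", x$control_activity, "\n")
  cat("  per-well jitter: Beta(", x$jitter_shape1, ",",
      round(x$jitter_shape2, 2), "), mean", x$jitter_mean, "\n")
  invisible(x)
}

#' Base activity of a compound/role under an effect model (no jitter)
#' @param model an `effect_model`.
#' @param role well role string.
#' @param compound_id compound identifier.
#' @param readout readout name.
#' @return numeric activity in `[0, 1]`; `NA` for empty wells.
#' @export
base_activity <- function(model, role, compound_id, readout) {
  if (role == "empty") return(NA_real_)
  if (startsWith(role, "positive_control")) return(model$control_activity)
  if (role == "dmso") return(0)
  if (is.matrix(model$active)) {
    if (compound_id %in% rownames(model$active))
      return(model$active[compound_id, readout])
    return(0)
  }
  if (compound_id %in% names(model$active))
    return(unname(model$active[compound_id]))
  0
}

#' Sample per-well activity jitter
#' @param model an `effect_model`.
#' @param n number of draws.
#' @return numeric vector of Beta draws (0 if jitter disabled).
#' @keywords internal
sample_jitter <- function(model, n) {
  if (model$jitter_mean <= 0) return(rep(0, n))
  stats::rbeta(n, model$jitter_shape1, model$jitter_shape2)
}

#' Class probability vector for a well
#' @param model an `effect_model`.
#' @param readout readout name.
#' @param activity well activity in `[0, 1]`.
#' @return named length-8 probability vector.
#' @export
well_class_probs <- function(model, readout, activity) {
  readout <- match.arg(readout, screen_readouts())
  if (is.na(activity) || activity < 0 || activity > 1)
    stopf("activity must be in [0, 1]")
  p <- (1 - activity) * model$p_ctrl[, readout] +
    activity * model$p_act[, readout]
  assert_prob8(p, "mixed class distribution")
}
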