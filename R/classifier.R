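# Supervised eight-class phenotype classification on the per-cell feature
# table, emulating the interactive training step of high-content screening
# tools with a seeded random-forest ensemble.

#' Train a phenotype classifier
#'
#' @param features data.frame containing (at least) the columns of
#'   [feature_names()].
#' @param labels character vector of true classes (subset of
#'   [phenotype_classes()]); length `nrow(features)`.
#' @param seed integer seed; training is reproducible given the seed.
#' @param ntree number of trees.
#' @return object of class `phenotype_classifier`: the fitted ensemble,
#'   feature schema, per-feature normalization (centre/scale), per-class
#'   training counts, and the seed.
#' @export
train_classifier <- function(features, labels, seed = 1L, ntree = 300L) {
  assert_classes(labels)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stopf("need at least 2 classes to train, got %d", length(unique(labels)))
  miss <- setdiff(feature_names(), names(features))
  if (length(miss))
    stopf("feature table missing: %s", paste(miss, collapse = ", "))
  x <- as.matrix(features[, feature_names()])
  if (nrow(x) != length(labels)) stopf("features/labels length mismatch")
  centre <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale_, "/")
  y <- factor(labels, levels = phenotype_classes())
  fit <- with_seed(seed,
    randomForest::randomForest(xs, droplevels(y), ntree = ntree))
  structure(list(fit = fit, features = feature_names(),
                 classes = phenotype_classes(),
                 centre = centre, scale = scale_,
                 train_counts = table(y), seed = seed),
            class = "phenotype_classifier")
}

#' @export
print.phenotype_classifier <- function(x, ...) {
  cat("Phenotype classifier (random forest,",
      x$fit$ntree, "trees; seed", x$seed, ")\n")
  print(x$train_counts)
  invisible(x)
}

#' Classify cells from their features
#'
#' Predicts the posterior class distribution for every cell and assigns the
#' argmax class; posterior ties are broken in favour of the earlier class in
#' the canonical order.
#'
#' @param model a `phenotype_classifier`.
#' @param features data.frame with the training feature schema.
#' @return data.frame: `class` (character), then one posterior column per
#'   phenotype class (each row sums to 1). Zero rows in, zero rows out.
#' @export
classify_cells <- function(model, features) {
  miss <- setdiff(model$features, names(features))
  if (length(miss))
    stopf("feature schema mismatch; missing: %s", paste(miss, collapse = ", "))
  cls <- model$classes
  if (nrow(features) == 0) {
    out <- data.frame(class = character(0))
    for (cl in cls) out[[cl]] <- numeric(0)
    return(out)
  }
  x <- as.matrix(features[, model$features])
  xs <- sweep(sweep(x, 2, model$centre), 2, model$scale, "/")
  pr <- stats::predict(model$fit, xs, type = "prob")
  post <- matrix(0, nrow(xs), length(cls), dimnames = list(NULL, cls))
  post[, colnames(pr)] <- pr
  post <- post / pmax(rowSums(post), 1e-12)
  out <- data.frame(class = posterior_argmax(post), stringsAsFactors = FALSE)
  names(out) <- "class"
  cbind(out, as.data.frame(post))
}

#' Argmax class of a posterior matrix with canonical tie-breaking
#'
#' Posterior ties go to the earlier class in the canonical order.
#'
#' @param post numeric matrix with one column per phenotype class, in
#'   canonical order.
#' @return character vector of classes.
#' @export
posterior_argmax <- function(post) {
  phenotype_classes()[max.col(post, ties.method = "first")]
}

#' Evaluate a classifier on held-out labelled cells
#'
#' @param model a `phenotype_classifier`.
#' @param features held-out feature table.
#' @param labels true classes of the held-out cells.
#' @return list: `confusion` (8x8 matrix, rows = truth, cols = predicted),
#'   `accuracy`, `per_class` (data.frame of precision/recall/n).
#' @export
evaluate_classifier <- function(model, features, labels) {
  assert_classes(labels)
  pred <- classify_cells(model, features)$class
  cls <- phenotype_classes()
  conf <- table(factor(labels, cls), factor(pred, cls))
  conf <- matrix(conf, 8, 8, dimnames = list(truth = cls, predicted = cls))
  tp <- diag(conf)
  per_class <- data.frame(
    class = cls,
    n = rowSums(conf),
    precision = ifelse(colSums(conf) > 0, tp / colSums(conf), NA_real_),
    recall = ifelse(rowSums(conf) > 0, tp / rowSums(conf), NA_real_),
    row.names = NULL)
  list(confusion = conf,
       accuracy = sum(tp) / max(sum(conf), 1),
       per_class = per_class)
}

#' Row-normalized confusion matrix usable by [simulate_screen_tables()]
#'
#' Rows with no held-out cells fall back to the identity row.
#'
#' @param confusion 8x8 count matrix (rows = truth).
#' @return 8x8 row-stochastic matrix.
#' @export
confusion_rates <- function(confusion) {
  rs <- rowSums(confusion)
  out <- confusion / ifelse(rs > 0, rs, 1)
  for (i in which(rs == 0)) out[i, i] <- 1
  out
}

#' Features with ground-truth classes from a rendered site
#'
#' Runs segmentation and feature extraction on a synthetic site and
#' transfers the simulator's true class to every segmented object by
#' maximum pixel overlap with the ground-truth label grid (objects whose
#' overlap fraction is below `min_overlap` get `NA`).
#'
#' @param site a `site_image` from [render_site()].
#' @param illum optional list of `illumination_model`s (`dna`, `reporter`)
#'   applied before segmentation.
#' @param ring_um cytoplasm ring width, um.
#' @param min_overlap minimum fraction of the object overlapping its
#'   ground-truth cell.
#' @return feature data.frame with an extra `true_class` column.
#' @export
labeled_features_from_site <- function(site, illum = NULL, ring_um = 6.5,
                                       min_overlap = 0.3) {
  ps <- site$optics$pixel_size_um
  dna <- site$hoechst; rep_ <- site$reporter
  if (!is.null(illum)) {
    dna <- correct_image(dna, illum$dna)
    rep_ <- correct_image(rep_, illum$reporter)
  }
  nuc <- segment_nuclei(dna, pixel_size_um = ps)
  rings <- cytoplasm_rings(nuc, width_um = ring_um)
  fx <- extract_features(nuc, rings, dna, rep_)
  if (nrow(fx) == 0) { fx$true_class <- character(0); return(fx) }
  truth <- site$labels
  fx$true_class <- NA_character_
  for (l in fx$cell) {
    sel <- nuc$labels == l
    tl <- truth[sel]
    tl <- tl[tl > 0]
    if (!length(tl)) next
    best <- as.integer(names(which.max(table(tl))))
    if (length(tl) / sum(sel) >= min_overlap)
      fx$true_class[fx$cell == l] <- site$cells$class[best]
  }
  fx
}

#' Build a labelled training set by simulation
#'
#' Renders sites whose cells are drawn uniformly from the eight classes and
#' collects segmented, ground-truth-labelled feature records — the synthetic
#' stand-in for interactive annotation.
#'
#' @param n_sites number of sites to render.
#' @param cells_per_site cells per site.
#' @param optics a [site_optics()].
#' @param seed master seed.
#' @return feature data.frame with `true_class` (unmatched objects dropped).
#' @export
make_training_set <- function(n_sites = 30L, cells_per_site = 30L,
                              optics = site_optics(), seed = 1L) {
  probs <- rep(1 / 8, 8)
  out <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    cells <- sample_well_cells(probs, cells_per_site,
                               seed = child_seed(seed, 2L * s),
                               geometry = cell_geometry(
                                 field_um = optics$field_px *
                                   optics$pixel_size_um))
    site <- render_site(cells, optics, seed = child_seed(seed, 2L * s + 1L))
    fx <- labeled_features_from_site(site)
    if (nrow(fx)) fx$site <- s
    out[[s]] <- fx
  }
  out <- do.call(rbind, out)
  out[!is.na(out$true_class), , drop = FALSE]
}
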