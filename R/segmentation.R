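# Nucleus segmentation from the Hoechst channel and the cytoplasm-ring
# proxy. The pipeline is the standard recipe: Gaussian pre-smoothing, Otsu
# threshold, hole filling, then a distance-transform watershed to split
# touching nuclei, followed by an area filter. Coordinates are 0-based
# row-major pixels; areas are reported in um^2 via the pixel size.

#' Container for a labelled segmentation
#'
#' @param labels integer matrix; 0 = background, k > 0 = cell k, labels
#'   contiguous 1..N.
#' @param pixel_size_um pixel size in micrometres.
#' @return object of class `label_grid`.
#' @export
label_grid <- function(labels, pixel_size_um) {
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_grid")
}

#' @export
print.label_grid <- function(x, ...) {
  cat(sprintf("label_grid: %dx%d px (%.2f um/px), %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um,
              max(x$labels)))
  invisible(x)
}

relabel_contiguous <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  lut <- integer(max(u)); lut[u] <- seq_along(u)
  lab[lab > 0] <- lut[lab[lab > 0]]
  lab
}

#' Segment nuclei from a Hoechst image
#'
#' @param img single-channel (illumination-corrected) matrix.
#' @param pixel_size_um pixel size, um.
#' @param blur_sigma_px Gaussian pre-smoothing sigma, px.
#' @param size_range_um2 retained nucleus area range, um^2.
#' @param split_tolerance watershed merge tolerance in distance-map depth
#'   units (px); adjacent basins whose peaks differ by less than this are
#'   merged, so smaller values split touching nuclei more aggressively.
#' @return a [label_grid()]; objects touching the image border are listed by
#'   [border_labels()]. A constant image yields zero objects.
#' @export
segment_nuclei <- function(img, pixel_size_um = 0.65,
                           blur_sigma_px = 1.5,
                           size_range_um2 = c(30, 800),
                           split_tolerance = 1) {
  stopifnot(is.matrix(img))
  if (diff(range(img)) < 1e-12)
    return(label_grid(matrix(0L, nrow(img), ncol(img)), pixel_size_um))
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma_px))
  nm <- (sm - min(sm)) / diff(range(sm))
  th <- EBImage::otsu(EBImage::Image(nm), range = c(0, 1))
  mask <- nm > th
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  d <- EBImage::distmap(EBImage::Image(mask))
  lab <- as.matrix(EBImage::imageData(
    EBImage::watershed(d, tolerance = split_tolerance, ext = 1L)))
  # area filter
  ct <- tabulate(lab[lab > 0])
  area <- ct * pixel_size_um^2
  drop <- which(area < size_range_um2[1] | area > size_range_um2[2])
  if (length(drop)) lab[lab %in% drop] <- 0L
  label_grid(relabel_contiguous(lab), pixel_size_um)
}

#' Labels of objects touching the image border
#' @param grid a `label_grid`.
#' @return integer vector of label ids.
#' @export
border_labels <- function(grid) {
  l <- grid$labels
  sort(unique(c(l[1, ], l[nrow(l), ], l[, 1], l[, ncol(l)])[
    c(l[1, ], l[nrow(l), ], l[, 1], l[, ncol(l)]) > 0]))
}

#' Ring dilation radius in pixels
#' @param width_um ring width, um.
#' @param pixel_size_um pixel size, um.
#' @return integer radius `round(width_um / pixel_size_um)`.
#' @export
ring_width_px <- function(width_um, pixel_size_um) {
  as.integer(round(width_um / pixel_size_um))
}

#' Cytoplasm ring proxy around segmented nuclei
#'
#' Dilates each nucleus by `round(width_um / pixel_size)` pixels; the ring
#' is the dilated area minus all nucleus pixels. Pixels reachable from
#' several nuclei are assigned to the nearest nucleus (Euclidean distance to
#' the nearest nucleus pixel; ties go to the lower label), so rings are
#' mutually disjoint and share the nucleus label space.
#'
#' @param nuclei a `label_grid` of nuclei.
#' @param width_um ring width, um (default 6.5).
#' @return a `label_grid` of rings.
#' @export
cytoplasm_rings <- function(nuclei, width_um = 6.5) {
  if (width_um <= 0) stopf("ring width must be positive")
  lab <- nuclei$labels
  n_lab <- max(lab)
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (n_lab == 0) return(label_grid(out, nuclei$pixel_size_um))
  r <- ring_width_px(width_um, nuclei$pixel_size_um)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dil <- as.matrix(EBImage::dilate(EBImage::Image(lab > 0), brush)) > 0
  ring_px <- dil & lab == 0
  best_d <- matrix(Inf, nrow(lab), ncol(lab))
  for (l in seq_len(n_lab)) {
    # distance of every non-nucleus pixel to nucleus l
    d_l <- as.matrix(EBImage::distmap(EBImage::Image(1 - (lab == l))))
    upd <- ring_px & d_l <= r & d_l < best_d
    out[upd] <- l
    best_d[upd] <- d_l[upd]
  }
  label_grid(out, nuclei$pixel_size_um)
}

#' Fixed per-cell feature names, in order
#' @return character vector of the 15 features.
#' @export
feature_names <- function() {
  c("area_um2", "eccentricity", "solidity",
    "dna_mean", "dna_integrated", "dna_sd",
    "rep_mean", "rep_integrated", "rep_sd",
    "ring_rep_mean", "ring_rep_integrated",
    "rep_topdecile_mean", "rep_topdecile_ratio", "rep_spot_count",
    "nuc_ring_ratio")
}

per_label_stats <- function(vals, labs, n_lab) {
  s <- m <- sd_ <- numeric(n_lab); ct <- integer(n_lab)
  if (length(labs)) {
    tab <- rowsum(cbind(vals, vals^2, 1), labs)
    ids <- as.integer(rownames(tab))
    ct[ids] <- tab[, 3]
    s[ids] <- tab[, 1]
    m[ids] <- tab[, 1] / tab[, 3]
    v <- pmax(tab[, 2] / tab[, 3] - (tab[, 1] / tab[, 3])^2, 0)
    sd_[ids] <- sqrt(v * tab[, 3] / pmax(tab[, 3] - 1, 1))
  }
  list(sum = s, mean = m, sd = sd_, count = ct)
}

poly_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Extract per-cell features from nucleus and ring masks
#'
#' One record per nucleus label, in the fixed order of [feature_names()]:
#' shape (area in um^2, eccentricity, solidity), per-channel nuclear
#' mean/integrated/SD intensity, ring reporter mean/integrated intensity,
#' nucleolar-proxy features (mean of the top decile of nuclear reporter
#' pixels, its ratio to the nuclear median, white-top-hat spot count) and
#' the nuclear/ring reporter ratio. Cells touching the image border keep
#' their features but carry `border = TRUE`; ratios whose denominator is
#' below `eps` are set to 0 and flagged via `ratio_flag`.
#'
#' @param nuclei,rings `label_grid`s sharing one label space.
#' @param dna,reporter channel matrices (same shape as the grids).
#' @param spot_radius_um top-hat structuring-disc radius for spot detection.
#' @param spot_thresh absolute top-hat height defining a spot.
#' @param eps denominator guard for ratios.
#' @return data.frame: `cell`, the 15 features, `border`, `ratio_flag`.
#' @export
extract_features <- function(nuclei, rings, dna, reporter,
                             spot_radius_um = 1.8, spot_thresh = 0.15,
                             eps = 1e-6) {
  lab <- nuclei$labels; rlab <- rings$labels
  stopifnot(all(dim(lab) == dim(dna)), all(dim(lab) == dim(reporter)),
            all(dim(lab) == dim(rlab)))
  ps <- nuclei$pixel_size_um
  n_lab <- max(lab)
  if (n_lab == 0) {
    out <- data.frame(cell = integer(0))
    for (f in feature_names()) out[[f]] <- numeric(0)
    out$border <- logical(0); out$ratio_flag <- logical(0)
    return(out)
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  dna_s <- per_label_stats(dna[idx], l, n_lab)
  rep_s <- per_label_stats(reporter[idx], l, n_lab)
  ridx <- which(rlab > 0)
  ring_s <- per_label_stats(reporter[ridx], rlab[ridx], n_lab)

  ecc <- sol <- td_mean <- td_ratio <- numeric(n_lab)
  spots <- integer(n_lab)
  # top-hat spot image computed once
  br_d <- 2L * max(1L, as.integer(round(spot_radius_um / ps))) + 1L
  th_img <- as.matrix(EBImage::whiteTopHat(
    EBImage::Image(reporter), EBImage::makeBrush(br_d, shape = "disc")))
  spot_lab <- as.matrix(EBImage::bwlabel(EBImage::Image(th_img > spot_thresh)))
  rows_by <- split(seq_along(l), l)
  for (nm in names(rows_by)) {
    li <- as.integer(nm); sel <- rows_by[[nm]]
    xs <- rc[sel, 1]; ys <- rc[sel, 2]
    mx <- mean(xs); my <- mean(ys)
    mu20 <- mean((xs - mx)^2) + 1 / 12  # pixel-extent correction
    mu02 <- mean((ys - my)^2) + 1 / 12
    mu11 <- mean((xs - mx) * (ys - my))
    tr <- (mu20 + mu02) / 2
    det_rt <- sqrt(max(((mu20 - mu02) / 2)^2 + mu11^2, 0))
    l1 <- tr + det_rt; l2 <- max(tr - det_rt, 0)
    ecc[li] <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
    h <- grDevices::chull(xs, ys)
    sol[li] <- min(length(sel) / max(poly_area(xs[h], ys[h]) +
                                       length(h) / 2 + 1, length(sel)), 1)
    v <- sort(reporter[idx[sel]], decreasing = TRUE)
    k <- max(1L, ceiling(length(v) / 10))
    td_mean[li] <- mean(v[seq_len(k)])
    med <- stats::median(v)
    td_ratio[li] <- if (med > eps) td_mean[li] / med else 0
    sp <- spot_lab[idx[sel]]
    spots[li] <- length(unique(sp[sp > 0]))
  }
  ring_mean <- ring_s$mean
  ratio_flag <- ring_mean <= eps
  nrr <- ifelse(ratio_flag, 0, rep_s$mean / ring_mean)
  bl <- border_labels(nuclei)
  out <- data.frame(cell = seq_len(n_lab),
                    area_um2 = dna_s$count * ps^2,
                    eccentricity = ecc, solidity = sol,
                    dna_mean = dna_s$mean, dna_integrated = dna_s$sum,
                    dna_sd = dna_s$sd,
                    rep_mean = rep_s$mean, rep_integrated = rep_s$sum,
                    rep_sd = rep_s$sd,
                    ring_rep_mean = ring_mean,
                    ring_rep_integrated = ring_s$sum,
                    rep_topdecile_mean = td_mean,
                    rep_topdecile_ratio = td_ratio,
                    rep_spot_count = spots,
                    nuc_ring_ratio = nrr,
                    border = seq_len(n_lab) %in% bl,
                    ratio_flag = ratio_flag)
  out
}

#' Match predicted to ground-truth labels by intersection-over-union
#'
#' Greedy one-to-one matching of label pairs in decreasing overlap; a pair
#' is a match when its IoU reaches `iou_min`.
#'
#' @param pred,truth integer label matrices of equal shape.
#' @param iou_min IoU threshold (default 0.5).
#' @return list: `pairs` (data.frame pred, truth, iou), `precision`,
#'   `recall` over non-background objects.
#' @export
match_labels <- function(pred, truth, iou_min = 0.5) {
  np <- max(pred); nt <- max(truth)
  sel <- pred > 0 & truth > 0
  pairs <- data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  if (any(sel)) {
    ov <- table(pred = pred[sel], truth = truth[sel])
    a_p <- tabulate(pred[pred > 0], np)
    a_t <- tabulate(truth[truth > 0], nt)
    df <- as.data.frame(ov, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    p_id <- as.integer(df$pred); t_id <- as.integer(df$truth)
    iou <- df$Freq / (a_p[p_id] + a_t[t_id] - df$Freq)
    ord <- order(iou, decreasing = TRUE)
    used_p <- logical(np); used_t <- logical(nt)
    for (i in ord) {
      if (iou[i] < iou_min) break
      if (!used_p[p_id[i]] && !used_t[t_id[i]]) {
        used_p[p_id[i]] <- TRUE; used_t[t_id[i]] <- TRUE
        pairs <- rbind(pairs, data.frame(pred = p_id[i], truth = t_id[i],
                                         iou = iou[i]))
      }
    }
  }
  list(pairs = pairs,
       precision = if (np > 0) nrow(pairs) / np else NA_real_,
       recall = if (nt > 0) nrow(pairs) / nt else NA_real_)
}
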