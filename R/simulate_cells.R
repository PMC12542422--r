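# Synthetic per-cell ground truth and site rendering.
#
# Cells are drawn from an effect-model class distribution, placed without
# overlap, and given class-conditional geometry and per-compartment
# intensities. The reporter-channel rendering table (relative levels in
# nucleoli / nucleoplasm / cytoplasm) makes the eight classes visually
# separable at the default signal-to-noise ratio:
#   nucleolar                1.00 / 0.25 / 0.20
#   nucleolar_nucleoplasmic  1.00 / 0.80 / 0.20
#   nucleoplasmic            0.30 / 0.90 / 0.20
#   cytoplasmic              0.50 / 0.30 / 1.00
#   mitotic                  condensed bright Hoechst blob, uniform reporter
#   apoptotic                fragmented small Hoechst blobs, dim reporter
#   no_signal                Hoechst only
#   missegmented             two fused nuclei rendered as one object

class_render_table <- function() {
  data.frame(
    class = phenotype_classes(),
    hoechst   = c(1.0, 1.0, 1.0, 1.0, 1.8, 1.2, 1.0, 1.0),
    nucleoli  = c(1.00, 1.00, 0.30, 0.50, 0.40, 0.15, 0.00, 0.60),
    nucleopl  = c(0.25, 0.80, 0.90, 0.30, 0.40, 0.15, 0.00, 0.45),
    cyto      = c(0.20, 0.20, 0.20, 1.00, 0.40, 0.10, 0.00, 0.25),
    stringsAsFactors = FALSE)
}

#' Default cell geometry parameters for the simulator
#'
#' Radii are in micrometres. Interphase nuclei are ~5 um disks; mitotic
#' cells condensed bright blobs; apoptotic cells fragmented into small
#' blobs; missegmented cells two fused nuclei sharing one label.
#'
#' @param field_um linear size of the square site field, um.
#' @param packing minimum centre distance as a fraction of summed radii.
#' @return list of geometry parameters.
#' @export
cell_geometry <- function(field_um = 256 * 0.65, packing = 0.9) {
  list(field_um = field_um, packing = packing,
       radius_mean = 5.0, radius_sd = 0.4, radius_range = c(4.0, 6.2),
       mitotic_radius = c(3.3, 3.7),
       apoptotic_n_frag = c(3L, 5L), apoptotic_frag_r = c(1.0, 1.5),
       nucleoli_n = c(2L, 4L), nucleoli_r = c(1.0, 1.6),
       nucleoli_spread = 0.55,
       max_tries = 200L)
}

runif_in <- function(n, range) stats::runif(n, range[1], range[2])

#' Sample the ground-truth cells of one well/site
#'
#' Draws each cell's true phenotype class from the supplied class
#' distribution, places cells without overlap (up to the packing tolerance),
#' and attaches class-conditional geometry and per-compartment intensity
#' levels used by [render_site()].
#'
#' @param probs length-8 class probability vector (canonical order), e.g.
#'   from [well_class_probs()].
#' @param n_cells number of cells to draw (>= 0).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param geometry list from [cell_geometry()].
#' @return data.frame with one row per cell: `cell`, `class`, `x_um`,
#'   `y_um`, `radius_um`, intensity levels, and list-columns `nucleoli`
#'   and `lobes` holding sub-disk offsets/radii (um). `fragmented` marks
#'   cells whose Hoechst signal is only in the lobes.
#' @export
sample_well_cells <- function(probs, n_cells, seed,
                              geometry = cell_geometry()) {
  probs <- assert_prob8(probs)
  stopifnot(n_cells >= 0)
  rt <- class_render_table()
  with_seed(seed, {
    cls <- if (n_cells > 0)
      sample(phenotype_classes(), n_cells, replace = TRUE, prob = probs)
    else character(0)
    radius <- pmin(pmax(stats::rnorm(n_cells, geometry$radius_mean,
                                     geometry$radius_sd),
                        geometry$radius_range[1]), geometry$radius_range[2])
    radius[cls == "mitotic"] <- runif_in(sum(cls == "mitotic"),
                                         geometry$mitotic_radius)
    # sequential packing: candidate centres rejected while too close to an
    # accepted one; a coarse spatial grid keeps the neighbour search local
    x <- y <- numeric(n_cells)
    margin <- max(radius, 0) + 1
    cell_sz <- 2 * geometry$packing * max(radius, 1)
    n_bins <- max(1L, floor(geometry$field_um / cell_sz))
    bins <- vector("list", n_bins * n_bins)
    bin_of <- function(cx, cy) {
      bx <- min(n_bins - 1L, floor(cx / geometry$field_um * n_bins))
      by <- min(n_bins - 1L, floor(cy / geometry$field_um * n_bins))
      c(bx, by)
    }
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (t in seq_len(geometry$max_tries)) {
        cx <- stats::runif(1, margin, geometry$field_um - margin)
        cy <- stats::runif(1, margin, geometry$field_um - margin)
        b <- bin_of(cx, cy)
        nb <- integer(0)
        for (dx in -1:1) for (dy in -1:1) {
          bx <- b[1] + dx; by <- b[2] + dy
          if (bx >= 0 && bx < n_bins && by >= 0 && by < n_bins)
            nb <- c(nb, bins[[bx + by * n_bins + 1L]])
        }
        if (!length(nb)) { placed <- TRUE }
        else {
          dmin <- geometry$packing * (radius[nb] + radius[i])
          placed <- all((x[nb] - cx)^2 + (y[nb] - cy)^2 >= dmin^2)
        }
        if (placed) break
      }
      x[i] <- cx; y[i] <- cy
      b <- bin_of(cx, cy)
      k <- b[1] + b[2] * n_bins + 1L
      bins[[k]] <- c(bins[[k]], i)
    }
    nucleoli <- vector("list", n_cells)
    lobes <- vector("list", n_cells)
    fragmented <- cls == "apoptotic"
    for (i in seq_len(n_cells)) {
      cl <- cls[i]
      if (cl %in% c(interphase_classes(), "no_signal", "missegmented")) {
        nn <- sample(seq(geometry$nucleoli_n[1], geometry$nucleoli_n[2]), 1)
        ang <- stats::runif(nn, 0, 2 * pi)
        rad <- stats::runif(nn, 0, geometry$nucleoli_spread * radius[i])
        nucleoli[[i]] <- data.frame(dx = rad * cos(ang), dy = rad * sin(ang),
                                    r = runif_in(nn, geometry$nucleoli_r))
      } else nucleoli[[i]] <- data.frame(dx = numeric(0), dy = numeric(0),
                                         r = numeric(0))
      if (cl == "missegmented") {
        a <- stats::runif(1, 0, pi)
        d <- 0.75 * radius[i]
        lobes[[i]] <- data.frame(dx = d * cos(a), dy = d * sin(a),
                                 r = 0.85 * radius[i])
      } else if (cl == "apoptotic") {
        nf <- sample(seq(geometry$apoptotic_n_frag[1],
                         geometry$apoptotic_n_frag[2]), 1)
        a <- stats::runif(nf, 0, 2 * pi)
        d <- stats::runif(nf, 0.3, 1.0) * radius[i] * 0.6
        lobes[[i]] <- data.frame(dx = d * cos(a), dy = d * sin(a),
                                 r = runif_in(nf, geometry$apoptotic_frag_r))
      } else lobes[[i]] <- data.frame(dx = numeric(0), dy = numeric(0),
                                      r = numeric(0))
    }
    lev <- rt[match(cls, rt$class), ]
    out <- data.frame(cell = seq_len(n_cells), class = cls,
                      x_um = x, y_um = y, radius_um = radius,
                      hoechst = lev$hoechst, rep_nucleoli = lev$nucleoli,
                      rep_nucleoplasm = lev$nucleopl, rep_cyto = lev$cyto,
                      fragmented = fragmented, stringsAsFactors = FALSE)
    out$nucleoli <- nucleoli
    out$lobes <- lobes
    out
  })
}

#' Optics / acquisition settings for site rendering
#'
#' @param pixel_size_um pixel size in micrometres (default 0.65, a typical
#'   10x configuration).
#' @param field_px image side length in pixels.
#' @param cyto_width_um width of the rendered cytoplasm annulus, um.
#' @param background per-channel background level, arbitrary units.
#' @param vignette list: `enabled`, `falloff` (fractional corner fall-off of
#'   the multiplicative gain), `offset` (additive term).
#' @param noise list: `enabled`, `photons` (Poisson photon scale per unit
#'   intensity), `gauss_sd` (additive Gaussian read noise).
#' @return list of class `site_optics`.
#' @export
site_optics <- function(pixel_size_um = 0.65, field_px = 256L,
                        cyto_width_um = 4,
                        background = c(dna = 0.02, reporter = 0.02),
                        vignette = list(enabled = TRUE, falloff = 0.3,
                                        offset = 0.01),
                        noise = list(enabled = TRUE, photons = 200,
                                     gauss_sd = 0.005)) {
  if (pixel_size_um <= 0) stopf("pixel size must be positive")
  structure(list(pixel_size_um = pixel_size_um, field_px = as.integer(field_px),
                 cyto_width_um = cyto_width_um, background = background,
                 vignette = vignette, noise = noise),
            class = "site_optics")
}

# paint value v on disk (cx, cy, r) [um] into matrix m (rows = y)
paint_disk <- function(m, cx, cy, r, v, ps) {
  n <- nrow(m)
  px <- (seq_len(n) - 0.5) * ps
  ix <- which(abs(px - cx) <= r); iy <- which(abs(px - cy) <= r)
  if (!length(ix) || !length(iy)) return(m)
  dx2 <- (px[ix] - cx)^2; dy2 <- (px[iy] - cy)^2
  sub <- outer(dy2, dx2, "+") <= r^2
  blk <- m[iy, ix, drop = FALSE]
  blk[sub] <- v
  m[iy, ix] <- blk
  m
}

#' The radial gain field a site's optics imply
#' @param optics a `site_optics` object.
#' @return `field_px` x `field_px` matrix; 1 at centre, `1 - falloff` at the
#'   corners; all ones when the vignette is disabled.
#' @export
vignette_gain <- function(optics) {
  n <- optics$field_px
  if (!isTRUE(optics$vignette$enabled)) return(matrix(1, n, n))
  u <- (seq_len(n) - 0.5) / n - 0.5
  r2 <- outer(u^2, u^2, "+") / 0.5  # corner radius^2 = 2*0.25
  1 - optics$vignette$falloff * r2
}

#' Render one site image from ground-truth cells
#'
#' Paints the Hoechst/DNA and reporter channels for a list of cells,
#' applies the multiplicative vignette gain and additive offset, and adds
#' seeded Poisson-Gaussian noise. Also returns the per-pixel ground-truth
#' nucleus label grid (cell ids).
#'
#' @param cells data.frame from [sample_well_cells()].
#' @param optics a [site_optics()] object.
#' @param seed integer seed for the noise.
#' @return list of class `site_image`: matrices `hoechst`, `reporter`
#'   (observed), `labels` (integer ground truth), `scene` (list of
#'   noise/vignette-free channels), `optics`, and the input `cells`.
#' @export
render_site <- function(cells, optics = site_optics(), seed = 1L) {
  ps <- optics$pixel_size_um
  n <- optics$field_px
  field_um <- n * ps
  if (nrow(cells) &&
      any(cells$x_um < 0 | cells$x_um > field_um |
          cells$y_um < 0 | cells$y_um > field_um))
    stopf("cell centres outside the %g um field", field_um)
  dna <- matrix(optics$background[["dna"]], n, n)
  rep_ <- matrix(optics$background[["reporter"]], n, n)
  labels <- matrix(0L, n, n)
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    # cytoplasm annulus first, then nucleus over it
    if (ci$rep_cyto > 0)
      rep_ <- paint_disk(rep_, ci$x_um, ci$y_um,
                         ci$radius_um + optics$cyto_width_um, ci$rep_cyto, ps)
    if (!ci$fragmented) {
      dna <- paint_disk(dna, ci$x_um, ci$y_um, ci$radius_um, ci$hoechst, ps)
      labels <- paint_disk(labels, ci$x_um, ci$y_um, ci$radius_um, i, ps)
      if (ci$rep_nucleoplasm > 0)
        rep_ <- paint_disk(rep_, ci$x_um, ci$y_um, ci$radius_um,
                           ci$rep_nucleoplasm, ps)
    }
    lb <- ci$lobes[[1]]
    for (k in seq_len(nrow(lb))) {
      dna <- paint_disk(dna, ci$x_um + lb$dx[k], ci$y_um + lb$dy[k],
                        lb$r[k], ci$hoechst, ps)
      labels <- paint_disk(labels, ci$x_um + lb$dx[k], ci$y_um + lb$dy[k],
                           lb$r[k], i, ps)
      if (ci$rep_nucleoplasm > 0)
        rep_ <- paint_disk(rep_, ci$x_um + lb$dx[k], ci$y_um + lb$dy[k],
                           lb$r[k], ci$rep_nucleoplasm, ps)
    }
    nc <- ci$nucleoli[[1]]
    if (ci$rep_nucleoli > 0)
      for (k in seq_len(nrow(nc)))
        rep_ <- paint_disk(rep_, ci$x_um + nc$dx[k], ci$y_um + nc$dy[k],
                           nc$r[k], ci$rep_nucleoli, ps)
  }
  gain <- vignette_gain(optics)
  offset <- if (isTRUE(optics$vignette$enabled)) optics$vignette$offset else 0
  observe <- function(scene) {
    img <- gain * scene
    if (isTRUE(optics$noise$enabled)) {
      ph <- optics$noise$photons
      img <- matrix(stats::rpois(length(img), ph * img) / ph, n, n)
      img <- img + stats::rnorm(length(img), 0, optics$noise$gauss_sd)
    }
    img + offset
  }
  obs <- with_seed(seed, list(hoechst = observe(dna),
                              reporter = observe(rep_)))
  structure(list(hoechst = obs$hoechst, reporter = obs$reporter,
                 labels = labels, scene = list(hoechst = dna, reporter = rep_),
                 optics = optics, cells = cells),
            class = "site_image")
}

#' Write a rendered site as a two-page TIFF plus ground truth
#'
#' Channel order is fixed: Hoechst first, reporter second. Ground truth is
#' written alongside as a 16-bit label TIFF and a per-cell CSV.
#'
#' @param site a `site_image`.
#' @param path output path stem (no extension); writes `<stem>.tif`,
#'   `<stem>_labels.tif`, `<stem>_cells.csv`.
#' @return `path`, invisibly.
#' @export
write_site_tiff <- function(site, path) {
  scale <- max(1, max(site$hoechst), max(site$reporter))
  img <- EBImage::Image(abind_2(pmax(site$hoechst, 0) / scale,
                                pmax(site$reporter, 0) / scale))
  EBImage::writeImage(img, paste0(path, ".tif"), type = "tiff",
                      bits.per.sample = 16L)
  EBImage::writeImage(EBImage::Image(site$labels / 65535),
                      paste0(path, "_labels.tif"), type = "tiff",
                      bits.per.sample = 16L)
  cells <- site$cells
  cells$nucleoli <- NULL; cells$lobes <- NULL
  utils::write.csv(cells, paste0(path, "_cells.csv"), row.names = FALSE)
  invisible(path)
}

abind_2 <- function(a, b) {
  out <- array(0, c(dim(a), 2))
  out[, , 1] <- a; out[, , 2] <- b
  out
}
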