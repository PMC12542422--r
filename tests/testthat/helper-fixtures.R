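# Shared simulation fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# Labelled training features rendered without vignette (screen features are
# computed after illumination correction), a classifier trained on 80% of
# them, and its held-out evaluation on the remaining 20%.
classifier_fixture <- function() {
  if (!is.null(.fixture_cache$clf)) return(.fixture_cache$clf)
  opt <- site_optics()
  opt$vignette$enabled <- FALSE
  ts <- make_training_set(n_sites = 40L, cells_per_site = 30L,
                          optics = opt, seed = 101L)
  idx <- rbscreen:::with_seed(11L, sample(nrow(ts), floor(0.8 * nrow(ts))))
  model <- train_classifier(ts[idx, ], ts$true_class[idx], seed = 7L)
  eval <- evaluate_classifier(model, ts[-idx, ], ts$true_class[-idx])
  .fixture_cache$clf <- list(train = ts, idx = idx, model = model,
                             eval = eval)
  .fixture_cache$clf
}

# Small rendered screen-like site set under DMSO-baseline class frequencies
# with vignette on, plus illumination models estimated from the set itself.
screen_sites_fixture <- function() {
  if (!is.null(.fixture_cache$sites)) return(.fixture_cache$sites)
  em <- effect_model()
  probs <- well_class_probs(em, "enp1_minus_lmb", 0)
  opt <- site_optics()
  sites <- lapply(1:50, function(s) {
    cells <- sample_well_cells(probs, stats::rpois(1, 40), seed = 300L + s)
    render_site(cells, opt, seed = 400L + s)
  })
  illum <- list(
    dna = estimate_illumination(lapply(sites, `[[`, "hoechst")),
    reporter = estimate_illumination(lapply(sites, `[[`, "reporter")))
  .fixture_cache$sites <- list(sites = sites, illum = illum, optics = opt)
  .fixture_cache$sites
}

# Classifier confusion under screen-like imaging: balanced-class sites
# rendered WITH vignette, illumination-corrected, then classified.
screen_confusion_fixture <- function() {
  if (!is.null(.fixture_cache$conf)) return(.fixture_cache$conf)
  clf <- classifier_fixture()
  scr <- screen_sites_fixture()
  feats <- list()
  for (s in 1:15) {
    cells <- sample_well_cells(rep(1 / 8, 8), 30, seed = 700L + s)
    site <- render_site(cells, scr$optics, seed = 800L + s)
    fx <- labeled_features_from_site(site, illum = scr$illum)
    feats[[s]] <- fx[!is.na(fx$true_class), ]
  }
  feats <- do.call(rbind, feats)
  ev <- evaluate_classifier(clf$model, feats, feats$true_class)
  .fixture_cache$conf <- list(features = feats, eval = ev,
                              rates = confusion_rates(ev$confusion))
  .fixture_cache$conf
}

# Confocal-like rendering for the counter assays (0.25 um/px, the
# follow-up assays are imaged at higher magnification than the 10x screen).
confocal_optics <- function(noise = TRUE) {
  o <- site_optics(pixel_size_um = 0.25, field_px = 320L,
                   background = c(dna = 0.02, reporter = 0.005))
  o$vignette$enabled <- FALSE
  o$noise$enabled <- noise
  o
}

foci_geometry <- function() {
  geo <- cell_geometry(field_um = 320 * 0.25)
  geo$nucleoli_n <- c(10L, 12L)   # gamma-H2AX focus count in positives
  geo$nucleoli_r <- c(0.4, 0.6)
  geo$nucleoli_spread <- 0.75
  geo
}

render_h2ax_site <- function(n, n_pos, seed, noise = TRUE) {
  cells <- sample_well_cells(c(0, 0, 1, 0, 0, 0, 0, 0), n, seed,
                             geometry = foci_geometry())
  cells$rep_nucleoplasm <- 0.12
  cells$rep_cyto <- 0
  cells$rep_nucleoli <- 0
  if (n_pos > 0) {
    cells$rep_nucleoli[seq_len(n_pos)] <- 1.0
    # foci repel each other: resample positions with a minimum separation
    # so the rendered focus count is unambiguous
    cells$nucleoli[seq_len(n_pos)] <- rbscreen:::with_seed(seed + 5L,
      lapply(seq_len(n_pos), function(i) {
        r_nuc <- cells$radius_um[i]
        pts <- matrix(numeric(0), 0, 2)
        while (nrow(pts) < 10) {
          cand <- stats::runif(2, -0.8 * r_nuc, 0.8 * r_nuc)
          if (sqrt(sum(cand^2)) > 0.85 * r_nuc) next
          if (nrow(pts) == 0 ||
              min(sqrt(rowSums(sweep(pts, 2, cand)^2))) > 1.6)
            pts <- rbind(pts, cand)
        }
        data.frame(dx = pts[, 1], dy = pts[, 2],
                   r = stats::runif(10, 0.4, 0.55))
      }))
  }
  render_site(cells, confocal_optics(noise), seed = seed + 1)
}

render_gfp_site <- function(n, level, seed, noise = TRUE) {
  cells <- sample_well_cells(c(0, 0, 1, 0, 0, 0, 0, 0), n, seed,
                             geometry = cell_geometry(field_um = 320 * 0.25))
  cells$rep_nucleoli <- level
  cells$rep_nucleoplasm <- level
  cells$rep_cyto <- 0
  render_site(cells, confocal_optics(noise), seed = seed + 1)
}

# A tiny hand-built plate layout for pipeline tests.
mini_layout <- function() {
  data.frame(
    plate = "plate01",
    well = well_name(rep(1:2, 5), rep(3:7, each = 2)),
    row = rep(1:2, 5), col = rep(3:7, each = 2),
    role = c("dmso", "dmso", "dmso", "dmso",
             "positive_control:mg132", "positive_control:mg132",
             "library", "library", "library", "library"),
    compound_id = c(rep("DMSO", 4), "mg132", "mg132",
                    "c1", "c2", "c3", "c4"),
    conc_uM = NA_real_, stringsAsFactors = FALSE)
}
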