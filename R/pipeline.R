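# End-to-end screen orchestration. Table mode draws per-well class counts
# straight from the effect model; image mode renders sites, corrects
# illumination, filters out-of-focus images, segments, extracts features and
# classifies, then both modes share one statistics path: hit rates ->
# DMSO thresholds -> z' QC -> replicate-rule hit calling.

#' Screen analysis configuration
#'
#' @param mode `"tables"` (default) or `"images"`.
#' @param readouts readouts to analyze.
#' @param replicates biological replicates.
#' @param cells_per_well expected classified cells per well (table mode).
#' @param sites_per_well imaged sites per well (image mode; the screen's
#'   3x3 montage is 9).
#' @param cells_per_site expected cells per site (image mode, Poisson mean).
#' @param optics a [site_optics()] (image mode).
#' @param ring_um cytoplasm ring width, um.
#' @param threshold_k DMSO threshold SD multiplier (default 5).
#' @param rule_k replicate rule: final hit needs `rule_k` of `replicates`
#'   above threshold.
#' @param denominator -LMB ENP1 denominator convention (see
#'   [readout_spec()]).
#' @param confusion optional 8x8 row-stochastic classifier confusion matrix
#'   (table mode).
#' @param illum_min_images minimum stack size for illumination estimation.
#' @param focus_fraction focus-filter rejection fraction of the median
#'   sharpness.
#' @param seed master seed for every source of randomness.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(mode = c("tables", "images"),
                          readouts = screen_readouts(),
                          replicates = 3L,
                          cells_per_well = 360,
                          sites_per_well = 9L,
                          cells_per_site = 40,
                          optics = site_optics(),
                          ring_um = 6.5,
                          threshold_k = 5,
                          rule_k = 2L,
                          denominator = "methods",
                          confusion = NULL,
                          illum_min_images = 50L,
                          focus_fraction = 0.2,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (threshold_k <= 0) stopf("threshold multiplier must be positive")
  if (ring_um <= 0) stopf("ring width must be positive")
  structure(list(mode = mode, readouts = readouts, replicates = replicates,
                 cells_per_well = cells_per_well,
                 sites_per_well = as.integer(sites_per_well),
                 cells_per_site = cells_per_site, optics = optics,
                 ring_um = ring_um, threshold_k = threshold_k,
                 rule_k = as.integer(rule_k), denominator = denominator,
                 confusion = confusion,
                 illum_min_images = as.integer(illum_min_images),
                 focus_fraction = focus_fraction, seed = as.integer(seed)),
            class = "screen_config")
}

# shared statistics path from a per-well class-count table
analyze_count_table <- function(tab, config) {
  specs <- default_readout_specs(config$denominator)
  rate_blocks <- lapply(unique(tab$readout), function(ro)
    readout_hit_rate(tab[tab$readout == ro, , drop = FALSE], specs[[ro]]))
  rate_table <- do.call(rbind, rate_blocks)
  rownames(rate_table) <- NULL
  dmso <- rate_table[rate_table$role == "dmso", ]
  thr <- do.call(rbind, lapply(
    split(dmso, interaction(dmso$readout, dmso$replicate, drop = TRUE)),
    function(d) data.frame(readout = d$readout[1], replicate = d$replicate[1],
                           dmso_mean = mean(d$hit_rate, na.rm = TRUE),
                           dmso_sd = stats::sd(d$hit_rate[!is.na(d$hit_rate)]),
                           threshold = dmso_threshold(d$hit_rate,
                                                      config$threshold_k))))
  rownames(thr) <- NULL
  lib <- rate_table[rate_table$role == "library", ]
  hit_report <- call_hits(lib, thr, k_of = config$rule_k,
                          n_replicates = config$replicates)
  qc <- qc_report(rate_table)
  list(rate_table = rate_table, thresholds = thr, hit_report = hit_report,
       qc = qc, readout_specs = specs)
}

#' Run the screen analysis end to end
#'
#' In table mode the per-well class counts come from
#' [simulate_screen_tables()]; in image mode every well's sites are
#' rendered, illumination-corrected (models estimated per readout/replicate
#' batch and channel), focus-filtered, segmented, featurized and classified.
#' Both modes then share the statistics path: readout hit rates per well,
#' per-replicate DMSO thresholds (mean + k SD), z' per positive control, and
#' replicate-rule hit calling.
#'
#' @param layout a `plate_map` (see [build_screen_layout()],
#'   [load_plate_map()]).
#' @param model an [effect_model()].
#' @param config a [screen_config()].
#' @param classifier a trained [train_classifier()] model (image mode); if
#'   `NULL` one is trained from simulated annotation at run time.
#' @return object of class `screen_result`: the per-well `counts` and
#'   `rate_table`, `thresholds`, `hit_report`, `qc`, the `config`, its
#'   `config_hash`, and a structured `log`.
#' @export
run_screen_analysis <- function(layout, model, config = screen_config(),
                                classifier = NULL) {
  stopifnot(inherits(layout, "data.frame"), inherits(model, "effect_model"),
            inherits(config, "screen_config"))
  log <- character(0)
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  say("mode=%s seed=%d replicates=%d", config$mode, config$seed,
      config$replicates)
  if (config$mode == "tables") {
    counts <- simulate_screen_tables(layout, model,
                                     cells_per_well = config$cells_per_well,
                                     confusion = config$confusion,
                                     replicates = config$replicates,
                                     readouts = config$readouts,
                                     seed = config$seed)
    say("table mode: %d well rows simulated", nrow(counts))
  } else {
    img <- run_image_mode(layout, model, config, classifier, say)
    counts <- img$counts
  }
  res <- analyze_count_table(counts, config)
  cfg_for_hash <- config
  cfg_for_hash$optics <- unclass(config$optics)
  structure(c(list(counts = counts, config = config,
                   config_hash = config_hash(unclass(cfg_for_hash)),
                   log = log),
              res),
            class = "screen_result")
}

run_image_mode <- function(layout, model, config, classifier, say) {
  wells <- layout[layout$role != "empty", , drop = FALSE]
  optics <- config$optics
  ps <- optics$pixel_size_um
  if (is.null(classifier)) {
    say("training classifier from simulated annotation")
    train_optics <- optics
    train_optics$vignette$enabled <- FALSE  # features are computed post-correction
    ts <- make_training_set(optics = train_optics,
                            seed = child_seed(config$seed, 9001L))
    classifier <- train_classifier(ts, ts$true_class,
                                   seed = child_seed(config$seed, 9002L))
  }
  rows <- list(); ri <- 0L
  cls <- phenotype_classes()
  for (ro_i in seq_along(config$readouts)) {
    ro <- config$readouts[ro_i]
    for (rep_i in seq_len(config$replicates)) {
      stream0 <- (ro_i - 1L) * 97L + rep_i * 7L
      # render all sites of this readout/replicate batch
      sites <- list(); site_well <- integer(0)
      with_seed(child_seed(config$seed, stream0), {
        act <- pmin(1, vapply(seq_len(nrow(wells)), function(i)
          base_activity(model, wells$role[i], wells$compound_id[i], ro),
          numeric(1)) + sample_jitter(model, nrow(wells)))
        n_site <- stats::rpois(nrow(wells) * config$sites_per_well,
                               config$cells_per_site)
        seeds <- sample.int(2^30, 2L * length(n_site))
        k <- 0L
        for (w in seq_len(nrow(wells))) {
          probs <- well_class_probs(model, ro, act[w])
          for (s in seq_len(config$sites_per_well)) {
            k <- k + 1L
            cells <- sample_well_cells(probs, n_site[k], seed = seeds[2 * k - 1],
                                       geometry = cell_geometry(
                                         field_um = optics$field_px * ps))
            sites[[k]] <- render_site(cells, optics, seed = seeds[2 * k])
            site_well[k] <- w
          }
        }
      })
      say("%s rep %d: rendered %d sites", ro, rep_i, length(sites))
      illum <- list(
        dna = estimate_illumination(lapply(sites, `[[`, "hoechst"),
                                    min_images = config$illum_min_images),
        reporter = estimate_illumination(lapply(sites, `[[`, "reporter"),
                                         min_images = config$illum_min_images))
      ff <- focus_filter(lapply(sites, `[[`, "hoechst"),
                         fraction = config$focus_fraction)
      keep <- which(ff$log$retained)
      if (length(keep) < length(sites))
        say("%s rep %d: focus filter rejected %d site(s)", ro, rep_i,
            length(sites) - length(keep))
      counts_m <- matrix(0L, nrow(wells), 8L, dimnames = list(NULL, cls))
      for (k in keep) {
        dna <- correct_image(sites[[k]]$hoechst, illum$dna)
        rep_ch <- correct_image(sites[[k]]$reporter, illum$reporter)
        nuc <- segment_nuclei(dna, pixel_size_um = ps)
        rings <- cytoplasm_rings(nuc, width_um = config$ring_um)
        fx <- extract_features(nuc, rings, dna, rep_ch)
        if (!nrow(fx)) next
        pred <- classify_cells(classifier, fx)$class
        tb <- table(factor(pred, cls))
        counts_m[site_well[k], ] <- counts_m[site_well[k], ] + as.integer(tb)
      }
      ri <- ri + 1L
      blk <- data.frame(readout = ro, replicate = rep_i,
                        plate = wells$plate, well = wells$well,
                        role = wells$role, compound_id = wells$compound_id,
                        n_cells = as.integer(rowSums(counts_m)),
                        stringsAsFactors = FALSE)
      rows[[ri]] <- cbind(blk, as.data.frame(counts_m))
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(counts = counts, classifier = classifier)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screen analysis (", x$config$mode, " mode, seed ",
      x$config$seed, ")\n", sep = "")
  cat("  wells analyzed:", nrow(x$counts), "well rows;",
      length(unique(x$counts$compound_id[x$counts$role == "library"])),
      "library compounds\n")
  cat("  config hash:", x$config_hash, "\n")
  print(x$hit_report)
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  zp <- object$qc$zprime
  cat("z' per readout (pooled positive controls, per replicate):\n")
  agg <- stats::aggregate(zprime ~ readout + replicate, zp, mean)
  print(agg, row.names = FALSE)
  cat("\nDMSO thresholds (mean + ", object$config$threshold_k, " SD):\n",
      sep = "")
  print(object$thresholds, row.names = FALSE)
  invisible(object)
}

#' Write a screen result bundle to disk
#'
#' Writes the per-well counts and rates as CSV and the hit-call report as
#' JSON; every file carries the config hash and seed, so an unchanged
#' configuration reproduces the bundle exactly.
#'
#' @param result a `screen_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- data.frame(config_hash = result$config_hash,
                     seed = result$config$seed)
  utils::write.csv(cbind(result$counts, prov),
                   file.path(dir, "well_counts.csv"), row.names = FALSE)
  utils::write.csv(cbind(result$rate_table, prov),
                   file.path(dir, "hit_rates.csv"), row.names = FALSE)
  utils::write.csv(cbind(result$qc$zprime, prov),
                   file.path(dir, "zprime.csv"), row.names = FALSE)
  hr <- result$hit_report
  jsonlite::write_json(
    list(config_hash = result$config_hash, seed = result$config$seed,
         rule = hr$rule, thresholds = result$thresholds,
         hits = hr$hits, union_hits = hr$union_hits,
         incomplete = hr$incomplete),
    file.path(dir, "hit_report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
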