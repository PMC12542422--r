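count_row <- function(...) {
  x <- list(...)
  base <- as.list(stats::setNames(rep(0L, 8), phenotype_classes()))
  base[names(x)] <- x
  as.data.frame(base)
}

test_that("class counts equal a brute-force tally and pool sites", {
  cells <- data.frame(
    plate = "p1",
    well = rep(c("A03", "A04"), c(5, 4)),
    site = c(1, 1, 2, 2, 3, 1, 1, 2, 2),
    class = c("nucleolar", "nucleolar", "mitotic", "nucleolar", "apoptotic",
              "cytoplasmic", "cytoplasmic", "cytoplasmic", "no_signal"))
  set.seed(2)
  cells <- cells[sample(nrow(cells)), ]  # order must not matter
  ct <- class_counts(cells)
  ct <- ct[order(ct$well), ]
  # brute-force oracle
  for (w in c("A03", "A04")) for (cl in phenotype_classes()) {
    expect_equal(ct[ct$well == w, cl],
                 sum(cells$well == w & cells$class == cl))
  }
  expect_equal(ct$nucleolar[1], 3)
  expect_error(class_counts(data.frame(plate = "p", well = "A01",
                                       class = "weird")), "unknown")
  empty <- class_counts(cells[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("readout hit rates follow the hit/non-hit class mapping", {
  # -LMB ENP1: hit = nucleoplasmic; non-hit = nucleolar + nucleolar/nucleopl.
  ct <- count_row(nucleoplasmic = 25L, nucleolar = 70L,
                  nucleolar_nucleoplasmic = 5L, mitotic = 9L)
  r <- readout_hit_rate(ct, readout_spec("enp1_minus_lmb"))
  expect_equal(r$hit_rate, 25 / 100)
  expect_equal(r$n_classified, 100)
  # RP reporter: hit = the three nuclear classes; non-hit = cytoplasmic
  ct2 <- count_row(nucleolar = 10L, nucleolar_nucleoplasmic = 5L,
                   nucleoplasmic = 5L, cytoplasmic = 80L, no_signal = 20L)
  r2 <- readout_hit_rate(ct2, readout_spec("rpl29_gfp"))
  expect_equal(r2$hit_rate, 20 / 100)
  # all cells in excluded classes: undefined
  ct3 <- count_row(mitotic = 10L, apoptotic = 5L)
  r3 <- readout_hit_rate(ct3, readout_spec("enp1_plus_lmb"))
  expect_true(is.na(r3$hit_rate))
  # adding excluded-class cells never changes a hit rate
  ct4 <- ct; ct4$mitotic <- ct4$mitotic + 500L; ct4$no_signal <- 100L
  expect_equal(readout_hit_rate(ct4, readout_spec("enp1_minus_lmb"))$hit_rate,
               r$hit_rate)
})

test_that("the -LMB ENP1 denominator conventions are selectable", {
  ct <- count_row(nucleoplasmic = 25L, nucleolar = 60L,
                  nucleolar_nucleoplasmic = 10L, cytoplasmic = 5L)
  expect_equal(readout_hit_rate(
    ct, readout_spec("enp1_minus_lmb", "methods"))$hit_rate, 25 / 95)
  expect_equal(readout_hit_rate(
    ct, readout_spec("enp1_minus_lmb", "results"))$hit_rate, 25 / 85)
  expect_equal(readout_hit_rate(
    ct, readout_spec("enp1_minus_lmb", "interphase"))$hit_rate, 25 / 100)
})

test_that("readout specs partition classes and always exclude non-scorable cells", {
  for (ro in screen_readouts()) {
    sp <- readout_spec(ro)
    expect_length(intersect(sp$hit, sp$non_hit), 0)
    expect_true(all(c("mitotic", "apoptotic", "no_signal", "missegmented")
                    %in% sp$excluded))
    expect_setequal(c(sp$hit, sp$non_hit, sp$excluded), phenotype_classes())
  }
})

test_that("z' matches hand-computed cases and its boundary behaviour", {
  expect_equal(zprime(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1)), 1)
  expect_equal(zprime(c(0.8, 0.9, 1.0), c(0.0, 0.1, 0.2)), 0.25)
  expect_true(is.na(zprime(c(0.4, 0.6), c(0.45, 0.55))))
  expect_error(zprime(0.5, c(0.1, 0.2)), ">= 2")
})

test_that("z' is affine-invariant and bounded by one", {
  set.seed(77)
  for (i in 1:25) {
    pos <- runif(sample(3:8, 1), 0.5, 1)
    neg <- runif(sample(3:8, 1), 0, 0.4)
    z <- zprime(pos, neg)
    expect_lte(z, 1)
    a <- runif(1, 0.2, 5) * sample(c(-1, 1), 1)
    b <- runif(1, -2, 2)
    expect_equal(zprime(a * pos + b, a * neg + b), z, tolerance = 1e-10)
  }
})

test_that("DMSO threshold is mean plus five sample SDs", {
  expect_equal(dmso_threshold(c(0.02, 0.03, 0.04)), 0.03 + 5 * 0.01)
  expect_equal(dmso_threshold(rep(0.07, 6)), 0.07)  # zero SD
  expect_error(dmso_threshold(0.05), ">= 2")
  set.seed(1)
  x <- runif(12)
  expect_gte(dmso_threshold(x), mean(x))
})

test_that("replicate rule calls hits like the mitoxantrone footnote", {
  rates <- data.frame(readout = "enp1_minus_lmb",
                      replicate = rep(1:3, 3),
                      compound_id = rep(c("mito", "dull", "na_case"), each = 3),
                      hit_rate = c(0.5, 0.1, 0.6,   # above, below, above
                                   0.1, 0.1, 0.1,
                                   NA, 0.6, 0.6))
  thr <- data.frame(readout = "enp1_minus_lmb", replicate = 1:3,
                    threshold = 0.3)
  rep_ <- call_hits(rates, thr, k_of = 2)
  expect_true("mito" %in% rep_$hits$enp1_minus_lmb)
  expect_false("dull" %in% rep_$hits$enp1_minus_lmb)
  # NA never counts as above, but still 2 of 3 above here
  expect_true("na_case" %in% rep_$hits$enp1_minus_lmb)
  # all below -> non-hit, and missing replicates are excluded with a log
  rates2 <- rates[rates$compound_id != "na_case" | rates$replicate != 1, ]
  rep2 <- call_hits(rates2, thr, k_of = 2, n_replicates = 3)
  expect_true("na_case" %in% rep2$incomplete)
  expect_false("na_case" %in% rep2$union_hits)
})

test_that("hit calls equal a brute-force scan of a random table", {
  set.seed(123)
  tab <- expand.grid(readout = c("rps2_yfp", "rpl29_gfp"),
                     replicate = 1:3,
                     compound_id = sprintf("c%02d", 1:50),
                     stringsAsFactors = FALSE)
  tab$hit_rate <- runif(nrow(tab), 0, 0.3)
  thr <- expand.grid(readout = c("rps2_yfp", "rpl29_gfp"), replicate = 1:3,
                     stringsAsFactors = FALSE)
  thr$threshold <- runif(nrow(thr), 0.1, 0.2)
  rep_ <- call_hits(tab, thr, k_of = 2)
  # brute force: loop every compound x readout
  for (ro in unique(tab$readout)) for (cm in unique(tab$compound_id)) {
    n_above <- 0
    for (rp in 1:3) {
      r <- tab$hit_rate[tab$readout == ro & tab$compound_id == cm &
                          tab$replicate == rp]
      t <- thr$threshold[thr$readout == ro & thr$replicate == rp]
      n_above <- n_above + (r > t)
    }
    expect_equal(cm %in% rep_$hits[[ro]], n_above >= 2)
  }
})

test_that("qc summaries report cell numbers and per-control z'", {
  em <- effect_model(active = c(act1 = 0.9))
  lay <- build_screen_layout(c("act1", sprintf("c%02d", 1:30)), n_plates = 1)
  tab <- simulate_screen_tables(lay, em, cells_per_well = 150,
                                replicates = 2, readouts = "rps2_yfp",
                                seed = 4)
  cfg <- screen_config(replicates = 2, cells_per_well = 150, seed = 4)
  an <- rbscreen:::analyze_count_table(tab, cfg)
  qc <- an$qc
  expect_setequal(unique(qc$zprime$control), default_positive_controls())
  expect_true(all(qc$zprime$zprime <= 1, na.rm = TRUE))
  expect_equal(nrow(qc$cells), 2)
  expect_true(all(qc$cells$mean_cells > 0))
  # two identical wells -> SD 0; single well -> SD flagged NA
  one <- data.frame(readout = "rps2_yfp", replicate = 1, role = "library",
                    n_classified = 100, hit_rate = 0.1)
  q1 <- qc_report(one)
  expect_true(is.na(q1$cells$sd_cells))
  two <- rbind(one, one)
  expect_equal(qc_report(two)$cells$sd_cells, 0)
})

test_that("false positives stay rare and seeded actives are recovered", {
  ids <- sprintf("c%04d", 1:300)
  active <- stats::setNames(rep(0.7, 5), ids[1:5])  # a >= 0.6
  lay <- build_screen_layout(ids, n_plates = 1)
  fp_total <- 0L
  for (s in 1:10) {
    em <- effect_model(active = active)
    res <- run_screen_analysis(lay, em,
                               screen_config(cells_per_well = 360,
                                             replicates = 3, seed = s))
    hits <- res$hit_report$union_hits
    expect_true(all(names(active) %in% hits))  # sensitivity 1.0
    fp_total <- fp_total + length(setdiff(hits, names(active)))
  }
  expect_lte(fp_total, 2)
})
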