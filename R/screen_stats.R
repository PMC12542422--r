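# Screen statistics: per-well class counts, readout-specific hit rates,
# z'-factor quality control, the DMSO-derived 5-SD hit threshold, and the
# replicate-aware hit-calling rule.
#
# Conventions: sample standard deviations (n - 1 denominator) throughout;
# hit rate = hits / (hits + non-hits) with the readout's excluded classes
# ignored; a well with an empty denominator has an undefined (NA) rate and
# never counts as above-threshold.

#' Tally per-well class counts from a per-cell table
#'
#' Sites within a well are pooled.
#'
#' @param cells data.frame with a `class` column plus grouping columns.
#' @param by grouping column names (default plate/well provenance).
#' @return data.frame: grouping columns, then one count column per
#'   phenotype class. Empty input gives an empty table.
#' @export
class_counts <- function(cells, by = c("plate", "well")) {
  cls <- phenotype_classes()
  if (nrow(cells) == 0) {
    out <- cells[, intersect(by, names(cells)), drop = FALSE]
    for (cl in cls) out[[cl]] <- integer(0)
    return(out)
  }
  assert_classes(cells$class)
  key <- interaction(cells[, by, drop = FALSE], drop = TRUE, sep = "\r")
  tab <- table(key, factor(cells$class, cls))
  keys <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- stats::setNames(as.data.frame(keys, stringsAsFactors = FALSE), by)
  out <- cbind(out, as.data.frame.matrix(tab))
  rownames(out) <- NULL
  out
}

#' Readout-specific hit rate from class counts
#'
#' @param counts data.frame with one column per phenotype class (e.g. from
#'   [class_counts()] or [simulate_screen_tables()]); any other columns are
#'   carried through.
#' @param spec a [readout_spec()].
#' @return the input with `hits`, `non_hits`, `n_classified`
#'   (hits + non-hits) and `hit_rate` columns appended; wells whose
#'   denominator is zero get `NA` rate.
#' @export
readout_hit_rate <- function(counts, spec) {
  stopifnot(inherits(spec, "readout_spec"))
  hm <- as.matrix(counts[, spec$hit, drop = FALSE])
  nm <- as.matrix(counts[, spec$non_hit, drop = FALSE])
  hits <- as.integer(rowSums(hm))
  non_hits <- as.integer(rowSums(nm))
  counts$hits <- hits
  counts$non_hits <- non_hits
  counts$n_classified <- hits + non_hits
  counts$hit_rate <- ifelse(hits + non_hits > 0,
                            hits / (hits + non_hits), NA_real_)
  counts
}

#' z'-factor of a positive/negative control pair
#'
#' `z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`, with sample
#' standard deviations. The statistic is undefined (NA, with a reason
#' attribute) when the two means coincide.
#'
#' @param pos,neg numeric vectors of per-well values (>= 2 each).
#' @return numeric z' (<= 1), or NA when undefined.
#' @export
#' @examples
#' zprime(c(0.8, 0.9, 1.0), c(0.0, 0.1, 0.2))  # 0.25
zprime <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) < 2 || length(neg) < 2)
    stopf("z' needs >= 2 values per group (got %d and %d)",
          length(pos), length(neg))
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (mu_p == mu_n)
    return(structure(NA_real_, reason = "equal group means"))
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
}

#' Hit-calling threshold from DMSO control wells
#'
#' Mean of the DMSO per-well rates plus `k` sample standard deviations
#' (default 5).
#'
#' @param dmso_rates numeric vector of DMSO per-well hit rates (>= 2).
#' @param k SD multiplier.
#' @return numeric threshold.
#' @export
#' @examples
#' dmso_threshold(c(0.02, 0.03, 0.04))  # 0.08
dmso_threshold <- function(dmso_rates, k = 5) {
  dmso_rates <- dmso_rates[!is.na(dmso_rates)]
  if (length(dmso_rates) < 2)
    stopf("threshold needs >= 2 DMSO wells, got %d", length(dmso_rates))
  if (k <= 0) stopf("threshold multiplier must be positive")
  mean(dmso_rates) + k * stats::sd(dmso_rates)
}

#' Call hits against per-replicate thresholds
#'
#' A compound is flagged in a replicate when its rate exceeds that
#' replicate's threshold (undefined rates never flag); it is a final hit
#' for a readout when flagged in at least `k_of` of the replicates present.
#' Compounds missing any replicate are reported as incomplete and excluded
#' from the final list.
#'
#' @param rates data.frame with columns `readout`, `replicate`,
#'   `compound_id`, `hit_rate` (one row per compound x replicate x readout).
#' @param thresholds data.frame with columns `readout`, `replicate`,
#'   `threshold`.
#' @param k_of replicate rule: hits must exceed the threshold in at least
#'   `k_of` of `n_replicates`.
#' @param n_replicates expected replicate count (default: max observed).
#' @return object of class `hit_call_report`: `flags` (per compound x
#'   replicate), `per_readout` (compound, n_above, final hit flag),
#'   `hits` (final hit list per readout), `union_hits`, `incomplete`,
#'   `thresholds`, `rule`.
#' @export
call_hits <- function(rates, thresholds, k_of = 2L, n_replicates = NULL) {
  need <- c("readout", "replicate", "compound_id", "hit_rate")
  stopifnot(all(need %in% names(rates)),
            all(c("readout", "replicate", "threshold") %in% names(thresholds)))
  if (is.null(n_replicates)) n_replicates <- max(rates$replicate)
  m <- merge(rates[, need], thresholds, by = c("readout", "replicate"),
             all.x = TRUE)
  if (anyNA(m$threshold))
    stopf("missing threshold for replicate(s): %s",
          paste(unique(paste(m$readout, m$replicate)[is.na(m$threshold)]),
                collapse = ", "))
  m$above <- !is.na(m$hit_rate) & m$hit_rate > m$threshold
  agg <- stats::aggregate(cbind(n_above = above, n_rep = !is.na(replicate)) ~
                            readout + compound_id, data = m, FUN = sum)
  agg$incomplete <- agg$n_rep < n_replicates
  agg$hit <- !agg$incomplete & agg$n_above >= k_of
  incomplete <- unique(agg$compound_id[agg$incomplete])
  hits <- split(agg$compound_id[agg$hit], agg$readout[agg$hit])
  structure(list(flags = m[order(m$readout, m$compound_id, m$replicate), ],
                 per_readout = agg[order(agg$readout, agg$compound_id), ],
                 hits = hits,
                 union_hits = sort(unique(agg$compound_id[agg$hit])),
                 incomplete = incomplete,
                 thresholds = thresholds,
                 rule = list(k_of = k_of, n_replicates = n_replicates)),
            class = "hit_call_report")
}

#' @export
print.hit_call_report <- function(x, ...) {
  cat(sprintf("Hit-call report (rule: >= %d of %d replicates)\n",
              x$rule$k_of, x$rule$n_replicates))
  for (ro in names(x$hits))
    cat(sprintf("  %-15s %d hit(s): %s\n", ro, length(x$hits[[ro]]),
                paste(x$hits[[ro]], collapse = ", ")))
  cat("  union:", length(x$union_hits), "compound(s)\n")
  if (length(x$incomplete))
    cat("  incomplete (excluded):", paste(x$incomplete, collapse = ", "), "\n")
  invisible(x)
}

#' Per-replicate quality-control summary
#'
#' Summarizes per-well classified-cell counts (mean, SD; SD is NA and
#' flagged at n = 1) and the z' of every positive control against DMSO,
#' per readout and replicate. Control wells are pooled across plates.
#'
#' @param rate_table output of [readout_hit_rate()] carrying `readout`,
#'   `replicate`, `role`, `n_classified`, `hit_rate` columns.
#' @return list: `cells` (per readout x replicate cell-count summary),
#'   `zprime` (per readout x replicate x positive control).
#' @export
qc_report <- function(rate_table) {
  key <- list(readout = rate_table$readout, replicate = rate_table$replicate)
  cells <- do.call(rbind, lapply(
    split(rate_table, interaction(key, drop = TRUE)), function(d)
      data.frame(readout = d$readout[1], replicate = d$replicate[1],
                 n_wells = nrow(d),
                 mean_cells = mean(d$n_classified),
                 sd_cells = if (nrow(d) > 1) stats::sd(d$n_classified)
                            else NA_real_)))
  rownames(cells) <- NULL
  zp <- list(); i <- 0L
  for (d in split(rate_table, interaction(key, drop = TRUE))) {
    neg <- d$hit_rate[d$role == "dmso"]
    pcs <- unique(d$role[startsWith(d$role, "positive_control:")])
    for (pc in pcs) {
      i <- i + 1L
      pos <- d$hit_rate[d$role == pc]
      zp[[i]] <- data.frame(
        readout = d$readout[1], replicate = d$replicate[1],
        control = sub("^positive_control:", "", pc),
        n_pos = sum(!is.na(pos)), n_neg = sum(!is.na(neg)),
        mu_pos = mean(pos, na.rm = TRUE), sd_pos = stats::sd(pos[!is.na(pos)]),
        mu_neg = mean(neg, na.rm = TRUE), sd_neg = stats::sd(neg[!is.na(neg)]),
        zprime = if (sum(!is.na(pos)) >= 2 && sum(!is.na(neg)) >= 2)
          as.numeric(zprime(pos, neg)) else NA_real_)
    }
  }
  list(cells = cells, zprime = do.call(rbind, zp))
}
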