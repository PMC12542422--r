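# 384-well plate geometry: rows A-P, columns 1-24. Control columns hold the
# DMSO solvent control and the positive-control drugs; the remaining 20
# columns hold the library.

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24
CONTROL_COLS <- c(1L, 2L, 23L, 24L)

#' Well name from row/column indices
#' @param row integer row 1-16 (A-P).
#' @param col integer column 1-24.
#' @return character like "A01".
#' @export
well_name <- function(row, col) sprintf("%s%02d", PLATE_ROWS[row], col)

#' Parse well names into row/column indices
#' @param well character vector like "A01".."P24".
#' @return data.frame with `row`, `col` integer columns.
#' @export
parse_well <- function(well) {
  ok <- grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", well)
  if (!all(ok))
    stopf("malformed well id(s): %s", paste(well[!ok], collapse = ", "))
  data.frame(row = match(substr(well, 1, 1), PLATE_ROWS),
             col = as.integer(substr(well, 2, 3)))
}

#' Default positive-control drugs
#'
#' The six positive-control compounds used in the screen: inhibitors of rDNA
#' transcription (actinomycin D, CX-5461), the proteasome (bortezomib,
#' MG132), and translation (cycloheximide, silvestrol).
#'
#' @return character vector of length 6.
#' @export
default_positive_controls <- function() {
  c("actinomycin_d", "bortezomib", "cx_5461",
    "cycloheximide", "mg132", "silvestrol")
}

#' Lay out a compound library over 384-well plates
#'
#' Places every library compound in exactly one well across the plate set.
#' Columns 1 and 23 of every plate are DMSO solvent-control wells; columns 2
#' and 24 cycle through the positive-control drugs; columns 3-22 hold library
#' compounds in row-major order. Library wells left over after all compounds
#' are placed are marked `empty`.
#'
#' @param compound_ids character vector of library compound identifiers
#'   (must be unique).
#' @param controls character vector of positive-control names (default the
#'   six in [default_positive_controls()]).
#' @param n_plates number of plates.
#' @param conc_uM library compound concentration recorded in the map.
#' @return a `plate_map` data.frame with columns `plate`, `well`, `row`,
#'   `col`, `role`, `compound_id`, `conc_uM`; one row per well
#'   (`384 * n_plates` rows).
#' @export
#' @examples
#' pm <- build_screen_layout(sprintf("cmpd%04d", 1:100), n_plates = 1)
#' table(pm$role)
build_screen_layout <- function(compound_ids,
                                controls = default_positive_controls(),
                                n_plates = 4L,
                                conc_uM = 1) {
  compound_ids <- as.character(compound_ids)
  if (anyDuplicated(compound_ids))
    stopf("duplicate compound ids")
  lib_cols <- setdiff(PLATE_COLS, CONTROL_COLS)
  capacity <- n_plates * length(PLATE_ROWS) * length(lib_cols)
  if (length(compound_ids) > capacity)
    stopf("library capacity exceeded: %d compounds for %d library wells (%d over)",
          length(compound_ids), capacity, length(compound_ids) - capacity)
  maps <- vector("list", n_plates)
  k <- 0L
  for (p in seq_len(n_plates)) {
    grid <- expand.grid(row = seq_along(PLATE_ROWS), col = PLATE_COLS)
    grid <- grid[order(grid$row, grid$col), ]
    role <- character(nrow(grid)); cmpd <- NA_character_; conc <- NA_real_
    df <- data.frame(plate = sprintf("plate%02d", p),
                     well = well_name(grid$row, grid$col),
                     row = grid$row, col = grid$col,
                     role = "empty", compound_id = NA_character_,
                     conc_uM = NA_real_, stringsAsFactors = FALSE)
    dmso <- df$col %in% c(1L, 23L)
    df$role[dmso] <- "dmso"
    df$compound_id[dmso] <- "DMSO"
    posc <- which(df$col %in% c(2L, 24L))
    ctrl_names <- controls[((seq_along(posc) - 1L) %% length(controls)) + 1L]
    df$role[posc] <- paste0("positive_control:", ctrl_names)
    df$compound_id[posc] <- ctrl_names
    lib <- which(df$col %in% lib_cols)
    n_take <- min(length(lib), length(compound_ids) - k)
    if (n_take > 0) {
      sel <- lib[seq_len(n_take)]
      df$role[sel] <- "library"
      df$compound_id[sel] <- compound_ids[k + seq_len(n_take)]
      df$conc_uM[sel] <- conc_uM
      k <- k + n_take
    }
    maps[[p]] <- df
  }
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  class(out) <- c("plate_map", "data.frame")
  out
}

#' Write a plate map to CSV
#' @param map a `plate_map` data.frame.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_plate_map <- function(map, file) {
  utils::write.csv(map[, c("plate", "well", "role", "compound_id", "conc_uM")],
                   file, row.names = FALSE)
  invisible(file)
}

#' Read and validate a plate map CSV
#'
#' Validates well ids against the A01-P24 grid, checks roles, and rejects
#' duplicate (plate, well) entries.
#'
#' @param file path to a CSV written by [write_plate_map()] (columns `plate`,
#'   `well`, `role`, `compound_id`, `conc_uM`).
#' @return a `plate_map` data.frame.
#' @export
load_plate_map <- function(file) {
  if (!file.exists(file)) stopf("plate map file not found: %s", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("plate", "well", "role", "compound_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("plate map missing column(s): %s",
                          paste(miss, collapse = ", "))
  rc <- parse_well(df$well)  # errors name the offending well ids
  df$row <- rc$row; df$col <- rc$col
  if (!"conc_uM" %in% names(df)) df$conc_uM <- NA_real_
  ok_role <- df$role %in% c("library", "dmso", "empty") |
    grepl("^positive_control:.+$", df$role)
  if (!all(ok_role))
    stopf("invalid role(s): %s", paste(unique(df$role[!ok_role]), collapse = ", "))
  key <- paste(df$plate, df$well)
  if (anyDuplicated(key))
    stopf("duplicate (plate, well) entries: %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  bad_ctrl <- df$role %in% c("library") & df$col %in% CONTROL_COLS
  if (any(bad_ctrl))
    stopf("library compounds in control columns at: %s",
          paste(paste(df$plate, df$well)[bad_ctrl], collapse = ", "))
  df <- df[, c("plate", "well", "row", "col", "role", "compound_id", "conc_uM")]
  class(df) <- c("plate_map", "data.frame")
  df
}
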