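#' Read a long-format plate table
#'
#' Reads one-well-per-row CSV describing one or more screening plates and
#' validates it into the canonical plate table used throughout the package.
#' Expected columns (renameable through `schema`): `plate_id`, `row`, `col`,
#' `cell_line`, `dose_level`, `drug1`, `drug2`, `is_control`, `count`.
#' Empty strings in `drug1`/`drug2` are treated as absent.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(count = "nuclei")`.
#' @return A validated tibble with the canonical columns, rows in file order.
#'   Each well is classified as control, singlet, or pair (see
#'   [classify_wells()]).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' plates <- generate_screen(screen_spec(n_drugs = 4, n_cell_lines = 1,
#'                                       doses = "high", seed = 1))$plates
#' write_plate_table(plates, tf)
#' read_plate_table(tf)
read_plate_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("plate table file does not exist: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(raw))
    if (length(bad) > 0) {
      abort(paste0("schema maps to columns absent from file: ",
                   paste(bad, collapse = ", ")))
    }
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(plate_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("plate table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- raw |>
    dplyr::select(dplyr::all_of(plate_cols)) |>
    dplyr::mutate(
      plate_id = as.character(.data$plate_id),
      row = as.integer(.data$row),
      col = as.integer(.data$col),
      cell_line = as.character(.data$cell_line),
      dose_level = as.character(.data$dose_level),
      drug1 = clean_drug(.data$drug1),
      drug2 = clean_drug(.data$drug2),
      is_control = as.logical(.data$is_control),
      count = as.numeric(.data$count)
    )
  validate_plate_table(tbl)
}

clean_drug <- function(x) {
  x <- trimws(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' Validate a plate table
#'
#' Checks the well-record invariants: controls carry no drug annotation,
#' combination wells name two distinct drugs, positions are unique within a
#' plate and inside the plate shape, counts are non-negative, and every plate
#' has at least two control (DMSO) wells.
#'
#' @param plates A plate table (tibble with the canonical columns).
#' @param plate_shape Integer vector `c(n_rows, n_cols)`; defaults to the
#'   maximum observed row/column, i.e. no constraint beyond positivity.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_plate_table <- function(plates, plate_shape = NULL) {
  plates <- tibble::as_tibble(plates)
  missing_cols <- setdiff(plate_cols, names(plates))
  if (length(missing_cols) > 0) {
    abort(paste0("plate table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(plates) == 0) abort("plate table is empty")
  if (anyNA(plates$count) || any(plates$count < 0)) {
    abort("counts must be present and non-negative")
  }
  if (anyNA(plates$row) || anyNA(plates$col) ||
      any(plates$row < 1) || any(plates$col < 1)) {
    abort("row/col must be 1-based positive integers")
  }
  if (!is.null(plate_shape)) {
    if (any(plates$row > plate_shape[1]) || any(plates$col > plate_shape[2])) {
      abort("well positions fall outside the stated plate shape")
    }
  }
  dup <- duplicated(plates[, c("plate_id", "row", "col")])
  if (any(dup)) {
    d <- plates[dup, ][1, ]
    abort(sprintf("duplicate well position: plate %s row %d col %d",
                  d$plate_id, d$row, d$col))
  }
  ctrl_drugged <- plates$is_control & (!is.na(plates$drug1) | !is.na(plates$drug2))
  if (any(ctrl_drugged)) {
    abort("control wells must not carry a drug annotation")
  }
  orphan2 <- !is.na(plates$drug2) & is.na(plates$drug1)
  if (any(orphan2)) abort("drug2 present without drug1")
  self_pair <- !is.na(plates$drug1) & !is.na(plates$drug2) &
    plates$drug1 == plates$drug2
  if (any(self_pair)) {
    abort(sprintf("self-combination (drug1 == drug2 == \"%s\") is invalid",
                  plates$drug1[self_pair][1]))
  }
  undrugged <- !plates$is_control & is.na(plates$drug1)
  if (any(undrugged)) abort("non-control wells must name at least drug1")
  n_ctrl <- plates |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(n = sum(.data$is_control), .groups = "drop")
  if (any(n_ctrl$n < 2)) {
    abort(sprintf(
      "plate %s has fewer than 2 control (DMSO) wells; a sample variance needs >= 2",
      n_ctrl$plate_id[n_ctrl$n < 2][1]
    ))
  }
  plates
}

#' Classify wells as control, singlet, or pair
#'
#' @param plates A plate table.
#' @return The table with a `well_type` factor column added
#'   (`"control"`, `"singlet"`, `"pair"`); the classification is total:
#'   every valid record falls in exactly one class.
#' @export
classify_wells <- function(plates) {
  plates |>
    dplyr::mutate(well_type = dplyr::case_when(
      .data$is_control ~ "control",
      !is.na(.data$drug2) ~ "pair",
      TRUE ~ "singlet"
    ))
}

#' Write a plate table to CSV
#'
#' @param plates A plate table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plates, path) {
  validate_plate_table(plates)
  write_results_table(plates[, plate_cols], path)
}

#' Write a result table to CSV
#'
#' Writes any result tibble with a header row; numeric columns keep at least
#' 15 significant digits so write-then-read round-trips preserve comparisons.
#'
#' @param table A non-empty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(table, path) {
  if (!is.data.frame(table)) abort("`table` must be a data frame")
  if (nrow(table) == 0) abort("refusing to write an empty table")
  out <- dplyr::mutate(
    tibble::as_tibble(table),
    dplyr::across(dplyr::where(is.double), \(x) sprintf("%.15g", x))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
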