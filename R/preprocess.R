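#' One-iteration median polish of log10 counts
#'
#' Removes additive row and column effects from the log10 of a count grid by
#' exactly one Tukey median-polish sweep (rows first, then columns), and
#' re-exponentiates. Because the polish is done on the log scale the adjusted
#' counts are always positive. Missing cells stay missing; medians over a row
#' or column ignore missing cells.
#'
#' @param grid Numeric matrix of positive counts; `NA` marks absent wells.
#' @param pseudocount Value substituted for zero counts before taking logs
#'   (with a warning); default 0.5.
#' @return A list with components `adjusted` (matrix, `10^(overall + residual)`),
#'   `overall`, `row_effects`, `col_effects`, `residuals` (all on the log10
#'   scale).
#' @export
#' @examples
#' g <- 10^matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE)
#' median_polish_log(g)$overall  # 2.5
median_polish_log <- function(grid, pseudocount = 0.5) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  if (nrow(grid) < 2 || ncol(grid) < 2) {
    abort("median polish needs a grid with at least 2 rows and 2 columns")
  }
  zero <- !is.na(grid) & grid == 0
  if (any(zero)) {
    warn(sprintf("%d zero count(s) replaced by pseudocount %g before log",
                 sum(zero), pseudocount))
    grid[zero] <- pseudocount
  }
  bad <- !is.na(grid) & grid <= 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("non-positive count at row %d, col %d", idx[1], idx[2]))
  }
  if (any(rowSums(!is.na(grid)) == 0) || any(colSums(!is.na(grid)) == 0)) {
    abort("every row and column must contain at least one finite count")
  }
  m <- log10(grid)
  row_med <- apply(m, 1, median, na.rm = TRUE)
  overall <- median(row_med)
  row_effects <- row_med - overall
  resid <- sweep(m, 1, row_med, "-")
  col_effects <- apply(resid, 2, median, na.rm = TRUE)
  resid <- sweep(resid, 2, col_effects, "-")
  list(
    adjusted = 10^(overall + resid),
    overall = overall,
    row_effects = row_effects,
    col_effects = col_effects,
    residuals = resid
  )
}

#' Trimmed-mean DMSO control value
#'
#' Drops `floor(n * trim_fraction)` smallest and largest values and averages
#' the rest; the default 10% per-side trim makes the plate control value
#' robust to the occasional failed or overgrown control well.
#'
#' @param counts Numeric vector of positive control-well counts.
#' @param trim_fraction Fraction trimmed from each tail, in `[0, 0.5)`.
#' @return The trimmed arithmetic mean.
#' @export
trimmed_mean_control <- function(counts, trim_fraction = 0.10) {
  if (length(counts) == 0) abort("no control counts supplied")
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    abort("trim_fraction must be in [0, 0.5)")
  }
  n <- length(counts)
  k <- floor(n * trim_fraction)
  if (n - 2 * k < 1) abort("trimming leaves no surviving control wells")
  s <- sort(counts)
  mean(s[(k + 1):(n - k)])
}

#' Compute viabilities from raw plate counts
#'
#' Per plate: optionally median-polish the log10 counts (one iteration),
#' compute the DMSO control value as the trimmed mean of the (adjusted)
#' control counts, and divide every well's adjusted count by it. Control
#' wells themselves are converted too, so their spread on the
#' `W = -log10(V)` scale calibrates the null variance downstream. Records are
#' annotated with the assay key (cell line, dose level).
#'
#' @param plates A validated plate table.
#' @param polish Apply the one-iteration median polish? Default `TRUE`.
#' @param trim_fraction Per-side trim for the control mean; default 0.10.
#' @param pseudocount Replacement for zero counts before logs; default 0.5.
#' @return A tibble with one row per well: `cell_line`, `dose_level`,
#'   `plate_id`, `well_type`, `drug1`, `drug2`, `count_adjusted`,
#'   `control_value`, `viability`, `w` (`-log10` viability).
#' @export
compute_viabilities <- function(plates, polish = TRUE, trim_fraction = 0.10,
                                pseudocount = 0.5) {
  plates <- validate_plate_table(plates)
  plates <- classify_wells(plates)

  per_plate <- plates |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_split() |>
    purrr::map(function(p) {
      adj <- p$count
      if (polish) {
        # rows/columns with no wells at all carry no information; drop them
        # from the polish grid rather than failing on all-missing medians
        rows_used <- sort(unique(p$row))
        cols_used <- sort(unique(p$col))
        grid <- matrix(NA_real_, length(rows_used), length(cols_used))
        idx <- cbind(match(p$row, rows_used), match(p$col, cols_used))
        grid[idx] <- p$count
        polished <- median_polish_log(grid, pseudocount = pseudocount)
        adj <- polished$adjusted[idx]
      } else {
        zero <- adj == 0
        if (any(zero)) {
          warn(sprintf("%d zero count(s) replaced by pseudocount %g",
                       sum(zero), pseudocount))
          adj[zero] <- pseudocount
        }
      }
      ctrl <- trimmed_mean_control(adj[p$well_type == "control"],
                                   trim_fraction = trim_fraction)
      dplyr::mutate(p,
        count_adjusted = adj,
        control_value = ctrl,
        viability = adj / ctrl,
        w = -log10(.data$viability)
      )
    }) |>
    purrr::list_rbind()

  out <- per_plate |>
    dplyr::mutate(order_pair(.data$drug1, .data$drug2)) |>
    dplyr::select(dplyr::all_of(c(
      "cell_line", "dose_level", "plate_id", "well_type", "drug1", "drug2",
      "count_adjusted", "control_value", "viability", "w"
    ))) |>
    dplyr::arrange(.data$cell_line, .data$dose_level)

  check_connectivity(out)
  out
}

# Warn when an assay's pair set does not connect all its drugs.
check_connectivity <- function(viab) {
  viab |>
    dplyr::filter(.data$well_type == "pair") |>
    dplyr::group_by(.data$cell_line, .data$dose_level) |>
    dplyr::group_walk(function(pairs, key) {
      g <- igraph::graph_from_data_frame(pairs[, c("drug1", "drug2")],
                                         directed = FALSE)
      if (igraph::components(g)$no > 1) {
        warn(sprintf(
          "assay (%s, %s): pair design is disconnected; singlet fit will fail",
          key$cell_line, key$dose_level
        ))
      }
    })
  invisible(viab)
}

#' Split a viability table into per-assay tables
#'
#' @param viab Output of [compute_viabilities()].
#' @return A named list of tibbles, one per `(cell_line, dose_level)` assay,
#'   names formatted `"<cell_line>.<dose_level>"`.
#' @export
split_assays <- function(viab) {
  keys <- viab |>
    dplyr::distinct(.data$cell_line, .data$dose_level) |>
    dplyr::arrange(.data$cell_line, .data$dose_level)
  parts <- purrr::map2(keys$cell_line, keys$dose_level, function(cl, dl) {
    dplyr::filter(viab, .data$cell_line == cl, .data$dose_level == dl)
  })
  names(parts) <- paste(keys$cell_line, keys$dose_level, sep = ".")
  parts
}
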