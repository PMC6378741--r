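# Build a per-assay viability tibble directly from W values, bypassing the
# plate/preprocessing layer; used to unit-test the model and inference
# layers against hand-computable systems.
make_assay <- function(pair_w, dmso_w = rep(0, 8), singlet_w = NULL,
                       cell_line = "cl1", dose_level = "high") {
  stopifnot(all(c("drug1", "drug2", "w") %in% names(pair_w)))
  rows <- list(
    tibble::tibble(
      well_type = "pair", drug1 = pair_w$drug1, drug2 = pair_w$drug2,
      w = pair_w$w
    ),
    tibble::tibble(
      well_type = "control", drug1 = NA_character_, drug2 = NA_character_,
      w = dmso_w
    )
  )
  if (!is.null(singlet_w)) {
    stopifnot(all(c("drug", "w") %in% names(singlet_w)))
    rows <- c(rows, list(tibble::tibble(
      well_type = "singlet", drug1 = singlet_w$drug, drug2 = NA_character_,
      w = singlet_w$w
    )))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      cell_line = cell_line, dose_level = dose_level, plate_id = "p1",
      viability = 10^(-w), count_adjusted = 1000 * viability,
      control_value = 1000, .before = 1
    )
}

# All C(n,2) pairs of n generically-named drugs.
full_pair_grid <- function(n) {
  drugs <- sprintf("drug%02d", seq_len(n))
  g <- t(utils::combn(drugs, 2))
  tibble::tibble(drug1 = g[, 1], drug2 = g[, 2])
}

# A tiny literal plate: 1 DMSO pair + singlets + combination, 2 plates of 2x2.
toy_plate_csv <- function(path) {
  writeLines(c(
    "plate_id,row,col,cell_line,dose_level,drug1,drug2,is_control,count",
    "p1,1,1,cl1,high,,,TRUE,1000",
    "p1,1,2,cl1,high,,,TRUE,980",
    "p1,2,1,cl1,high,aspirin,,FALSE,700",
    "p1,2,2,cl1,high,aspirin,bortezomib,FALSE,250"
  ), path)
  path
}
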