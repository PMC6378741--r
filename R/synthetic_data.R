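#' Specification for a synthetic combination screen
#'
#' Describes a complete sparse combination screen: per (cell line, dose)
#' assay, all `C(n, 2)` pair wells, one singlet well per drug, and DMSO
#' control wells, laid out pseudo-randomly on plates. True effects live on
#' the `W = -log10(V)` scale, where Bliss independence is additive; the
#' generator's noise is Gaussian on that scale, so the inference model is
#' exactly correct under it (real count noise is only approximately so).
#'
#' @param n_drugs Number of drugs (>= 3).
#' @param n_cell_lines Number of cell lines.
#' @param doses Character subset of `c("high", "low")`.
#' @param plate_shape `c(rows, cols)` per plate; default 16 x 24 (384-well).
#' @param n_dmso_per_plate DMSO control wells per plate (>= 2); default 16.
#' @param singlet_w_mean,singlet_w_sd Named numeric (per dose): mean and SD
#'   of the drug-level true `W_i`. Defaults: high dose mean 0.3 SD 0.2, low
#'   dose mean 0.1 SD 0.1 — moderate killing at the standard dose, weaker at
#'   one-fifth dose.
#' @param cell_line_w_sd SD of the drug x cell-line effect on `W`, shared
#'   between the doses (default 0.15); this is what makes singlet profiles
#'   correlate across doses.
#' @param noise_sd_w Per-well Gaussian noise SD on the `W` scale
#'   (default 0.05).
#' @param singlet_well_noise_multiplier Noise multiplier for singlet wells
#'   (>= 1, default 3): singlets are measured once, in practice noisily.
#' @param planted_synergies,planted_antagonisms Tibbles with columns
#'   `drug1`, `drug2`, `cell_line`, `dose_level`, `delta_w` (positive for
#'   synergy, negative for antagonism), added to the true `W_ij`.
#' @param promiscuous_drugs Tibble with `drug`, `prob`, `delta_w`: each
#'   partner x cell line unit independently receives a synergy of `delta_w`
#'   at both doses with probability `prob`.
#' @param row_col_artifact_sd Log10-scale SD of multiplicative per-plate row
#'   and column effects (default 0).
#' @param base_count Nominal DMSO nuclei count (default 1000).
#' @param seed Integer seed.
#' @return A `screen_spec` list.
#' @export
screen_spec <- function(n_drugs = 20,
                        n_cell_lines = 8,
                        doses = c("high", "low"),
                        plate_shape = c(16L, 24L),
                        n_dmso_per_plate = 16L,
                        singlet_w_mean = c(high = 0.3, low = 0.1),
                        singlet_w_sd = c(high = 0.2, low = 0.1),
                        cell_line_w_sd = 0.15,
                        noise_sd_w = 0.05,
                        singlet_well_noise_multiplier = 3,
                        planted_synergies = NULL,
                        planted_antagonisms = NULL,
                        promiscuous_drugs = NULL,
                        row_col_artifact_sd = 0,
                        base_count = 1000,
                        seed = 1) {
  stopifnot(n_drugs >= 3, n_cell_lines >= 1, n_dmso_per_plate >= 2,
            noise_sd_w >= 0, singlet_well_noise_multiplier >= 1,
            row_col_artifact_sd >= 0, cell_line_w_sd >= 0)
  doses <- match.arg(doses, c("high", "low"), several.ok = TRUE)
  spec <- list(
    n_drugs = as.integer(n_drugs),
    n_cell_lines = as.integer(n_cell_lines),
    doses = doses,
    plate_shape = as.integer(plate_shape),
    n_dmso_per_plate = as.integer(n_dmso_per_plate),
    singlet_w_mean = singlet_w_mean,
    singlet_w_sd = singlet_w_sd,
    cell_line_w_sd = cell_line_w_sd,
    noise_sd_w = noise_sd_w,
    singlet_well_noise_multiplier = singlet_well_noise_multiplier,
    planted_synergies = planted_synergies,
    planted_antagonisms = planted_antagonisms,
    promiscuous_drugs = promiscuous_drugs,
    row_col_artifact_sd = row_col_artifact_sd,
    base_count = base_count,
    seed = as.integer(seed)
  )
  structure(spec, class = "screen_spec")
}

#' Desk-scale default screen specification
#'
#' A documented default emulating the structure of a full 108-drug screen at
#' desk size: 20 drugs, 8 cell lines, both doses (190 pairs per assay),
#' well noise 0.05 on the W scale, singlet wells 3x noisier, three planted
#' specific synergies (`delta_w = 0.25`, i.e. 5x the well noise), one
#' promiscuous sensitizer, and mild plate row/column artifacts.
#'
#' @param seed Integer seed (default 1).
#' @return A `screen_spec`.
#' @export
default_screen_spec <- function(seed = 1) {
  drugs <- sprintf("drug%02d", 1:20)
  lines <- sprintf("line%02d", 1:8)
  planted <- dplyr::bind_rows(
    tidyr::expand_grid(drug1 = "drug02", drug2 = "drug07",
                       cell_line = lines[1:6],
                       dose_level = c("high", "low"), delta_w = 0.25),
    tidyr::expand_grid(drug1 = "drug04", drug2 = "drug11",
                       cell_line = lines[1:4],
                       dose_level = c("high", "low"), delta_w = 0.25),
    tidyr::expand_grid(drug1 = "drug09", drug2 = "drug18",
                       cell_line = lines,
                       dose_level = c("high", "low"), delta_w = 0.25)
  )
  antag <- tidyr::expand_grid(
    drug1 = "drug05", drug2 = "drug14", cell_line = lines[1:4],
    dose_level = c("high", "low"), delta_w = -0.25
  )
  screen_spec(
    n_drugs = 20, n_cell_lines = 8, doses = c("high", "low"),
    planted_synergies = planted,
    planted_antagonisms = antag,
    promiscuous_drugs = tibble::tibble(drug = "drug13", prob = 0.4,
                                       delta_w = 0.25),
    row_col_artifact_sd = 0.02,
    seed = seed
  )
}

#' Generate a synthetic screen
#'
#' Produces a plate table with the structure the analysis assumes plus the
#' ground truth used for parameter-recovery and power studies. Per (cell
#' line, dose): true `W_ij = W_i + W_j + delta` (planted effects), observed
#' pair `W` adds `N(0, noise_sd_w^2)`; singlet wells add
#' `N(0, (noise_sd_w * multiplier)^2)`; DMSO wells are `W = 0` plus noise.
#' Counts are `base_count * 10^(-W)` times per-plate multiplicative row and
#' column artifacts; wells are placed in pseudo-random order.
#'
#' @param spec A `screen_spec`.
#' @return List with `plates` (plate table tibble) and `truth` (list:
#'   `singlets` tibble of true `W_i` per cell line/dose, `planted` tibble of
#'   all planted effects including realized promiscuous ones, `spec`).
#' @export
generate_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  set.seed(spec$seed)
  drugs <- sprintf("drug%02d", seq_len(spec$n_drugs))
  lines <- sprintf("line%02d", seq_len(spec$n_cell_lines))
  pair_grid <- t(utils::combn(drugs, 2))
  n_pairs <- nrow(pair_grid)

  capacity <- prod(spec$plate_shape) - spec$n_dmso_per_plate
  if (capacity < 1) abort("plate shape leaves no room for treatment wells")
  n_treat <- n_pairs + spec$n_drugs
  n_plates_per_assay <- ceiling(n_treat / capacity)
  if (n_plates_per_assay > 100) {
    abort("screen needs more than 100 plates per assay; reduce n_drugs or enlarge plate_shape")
  }

  # drug-level effects: per-dose base plus cell-line interaction shared
  # across doses (source of cross-dose consistency)
  base_w <- purrr::map(spec$doses, function(d) {
    rnorm(spec$n_drugs, spec$singlet_w_mean[[d]], spec$singlet_w_sd[[d]])
  })
  names(base_w) <- spec$doses
  cl_effect <- matrix(rnorm(spec$n_drugs * spec$n_cell_lines,
                            0, spec$cell_line_w_sd),
                      spec$n_drugs, spec$n_cell_lines,
                      dimnames = list(drugs, lines))

  # realize promiscuous-drug synergies once, at both doses
  promiscuous_planted <- NULL
  if (!is.null(spec$promiscuous_drugs) && nrow(spec$promiscuous_drugs) > 0) {
    promiscuous_planted <- purrr::pmap(spec$promiscuous_drugs,
      function(drug, prob, delta_w) {
        units <- tidyr::expand_grid(partner = setdiff(drugs, drug),
                                    cell_line = lines)
        hit <- units[stats::runif(nrow(units)) < prob, ]
        if (nrow(hit) == 0) return(NULL)
        tidyr::expand_grid(hit, dose_level = spec$doses) |>
          dplyr::mutate(order_pair(drug, .data$partner), delta_w = delta_w) |>
          dplyr::select(dplyr::all_of(c(
            "drug1", "drug2", "cell_line", "dose_level", "delta_w"
          )))
      }) |>
      purrr::list_rbind()
  }
  planted <- dplyr::bind_rows(
    spec$planted_synergies, spec$planted_antagonisms, promiscuous_planted
  )
  if (!is.null(planted) && nrow(planted) > 0) {
    planted <- dplyr::mutate(planted, order_pair(.data$drug1, .data$drug2)) |>
      dplyr::group_by(.data$drug1, .data$drug2, .data$cell_line,
                      .data$dose_level) |>
      dplyr::summarise(delta_w = sum(.data$delta_w), .groups = "drop")
  } else {
    planted <- tibble::tibble(drug1 = character(), drug2 = character(),
                              cell_line = character(),
                              dose_level = character(), delta_w = numeric())
  }

  truth_singlets <- tidyr::expand_grid(cell_line = lines,
                                       dose_level = spec$doses,
                                       drug = drugs) |>
    dplyr::mutate(
      w_true = base_w_lookup(base_w, .data$dose_level, .data$drug, drugs) +
        cl_effect[cbind(.data$drug, .data$cell_line)]
    )
  w_true_key <- setNames(
    truth_singlets$w_true,
    paste(truth_singlets$cell_line, truth_singlets$dose_level,
          truth_singlets$drug, sep = "\r")
  )

  assays <- tidyr::expand_grid(cell_line = lines, dose_level = spec$doses)
  plates <- purrr::pmap(assays, function(cell_line, dose_level) {
    kw <- function(drug) {
      w_true_key[paste(cell_line, dose_level, drug, sep = "\r")]
    }
    delta <- planted |>
      dplyr::filter(.data$cell_line == !!cell_line,
                    .data$dose_level == !!dose_level)
    delta_key <- setNames(delta$delta_w, paste(delta$drug1, delta$drug2,
                                               sep = "\r"))
    pair_delta <- delta_key[paste(pair_grid[, 1], pair_grid[, 2], sep = "\r")]
    pair_delta[is.na(pair_delta)] <- 0
    w_pair_true <- unname(kw(pair_grid[, 1]) + kw(pair_grid[, 2]) + pair_delta)
    treat <- dplyr::bind_rows(
      tibble::tibble(
        drug1 = pair_grid[, 1], drug2 = pair_grid[, 2],
        is_control = FALSE,
        w_obs = w_pair_true + rnorm(n_pairs, 0, spec$noise_sd_w)
      ),
      tibble::tibble(
        drug1 = drugs, drug2 = NA_character_, is_control = FALSE,
        w_obs = unname(kw(drugs)) +
          rnorm(spec$n_drugs, 0,
                spec$noise_sd_w * spec$singlet_well_noise_multiplier)
      )
    )
    # pseudo-random layout across plates
    treat <- treat[sample.int(nrow(treat)), ]
    treat$plate_idx <- rep(seq_len(n_plates_per_assay),
                           each = capacity)[seq_len(nrow(treat))]
    per_plate <- split(treat, treat$plate_idx)
    purrr::imap(per_plate, function(tp, idx) {
      dmso <- tibble::tibble(
        drug1 = NA_character_, drug2 = NA_character_, is_control = TRUE,
        w_obs = rnorm(spec$n_dmso_per_plate, 0, spec$noise_sd_w),
        plate_idx = as.integer(idx)
      )
      wells <- dplyr::bind_rows(tp, dmso)
      wells <- wells[sample.int(nrow(wells)), ]
      pos <- sample.int(prod(spec$plate_shape), nrow(wells))
      row_art <- rnorm(spec$plate_shape[1], 0, spec$row_col_artifact_sd)
      col_art <- rnorm(spec$plate_shape[2], 0, spec$row_col_artifact_sd)
      wells |>
        dplyr::mutate(
          plate_id = sprintf("%s_%s_p%d", cell_line, dose_level,
                             as.integer(idx)),
          row = as.integer((pos - 1) %% spec$plate_shape[1] + 1),
          col = as.integer((pos - 1) %/% spec$plate_shape[1] + 1),
          cell_line = cell_line,
          dose_level = dose_level,
          count = spec$base_count * 10^(-.data$w_obs +
                                          row_art[.data$row] +
                                          col_art[.data$col])
        ) |>
        dplyr::select(dplyr::all_of(plate_cols))
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()

  list(
    plates = plates,
    truth = list(singlets = truth_singlets, planted = planted, spec = spec)
  )
}

base_w_lookup <- function(base_w, dose_level, drug, drugs) {
  purrr::map2_dbl(dose_level, drug, function(d, g) {
    base_w[[d]][match(g, drugs)]
  })
}
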