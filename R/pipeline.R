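#' Run the full analysis pipeline
#'
#' Preprocess -> per-assay Bliss fit -> synergy inference -> dose combining
#' -> scoring -> export. Input is either a plate-table CSV path or a
#' `screen_spec` to simulate. Writes, under `out_dir`: `fit_summary.csv`,
#' `singlet_estimates.csv`, `synergy_calls.csv`, `combined_calls.csv`,
#' `ranked_combinations.csv`, and `heatmap.json`; returns the same objects
#' invisibly.
#'
#' @param config A list (or path to a YAML file parseable into one) with
#'   elements: `input` (CSV path) or `simulate` (a `screen_spec`), and
#'   optionally `schema`, `polish` (default `TRUE`), `trim_fraction` (0.10),
#'   `pseudocount` (0.5), `alpha` (0.05), `include_self` (`TRUE`),
#'   `out_dir` (required), `seed` (1).
#' @return Invisibly, a list with `viabilities`, `fits`, `fit_summary`,
#'   `calls`, `combined`, `T`, `Sc`, `ranked`, `heatmap_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(polish = TRUE, trim_fraction = 0.10, pseudocount = 0.5,
         alpha = 0.05, include_self = TRUE, seed = 1L, schema = NULL),
    config
  )
  if (is.null(cfg$out_dir)) abort("config must name an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  plates <- stage("input", {
    if (!is.null(cfg$input)) {
      read_plate_table(cfg$input, schema = cfg$schema)
    } else if (!is.null(cfg$simulate)) {
      spec <- cfg$simulate
      if (!inherits(spec, "screen_spec")) spec <- do.call(screen_spec, spec)
      generate_screen(spec)$plates
    } else {
      abort("config must provide either input (CSV path) or simulate (screen_spec)")
    }
  })

  viab <- stage("preprocess", compute_viabilities(
    plates, polish = cfg$polish, trim_fraction = cfg$trim_fraction,
    pseudocount = cfg$pseudocount
  ))
  fits <- stage("fit", fit_all_assays(viab))
  fsum <- fit_summary(fits)
  for (k in seq_len(nrow(fsum))) {
    inform(sprintf("assay (%s, %s): R^2 = %.3f, m = %d, n = %d",
                   fsum$cell_line[k], fsum$dose_level[k], fsum$r_squared[k],
                   fsum$m[k], fsum$n[k]))
  }
  calls <- stage("synergy", infer_synergy(viab, fits, alpha = cfg$alpha))
  combined <- stage("combine_doses", combine_doses(calls))
  T_mat <- stage("scoring", absolute_synergy_scores(combined))
  Sc_mat <- stage("scoring", specificity_scores(T_mat,
                                                include_self = cfg$include_self))
  ranked <- stage("scoring", rank_combinations(T_mat, Sc_mat))

  write_results_table(fsum, file.path(cfg$out_dir, "fit_summary.csv"))
  write_results_table(purrr::map(fits, tidy) |> purrr::list_rbind(),
                      file.path(cfg$out_dir, "singlet_estimates.csv"))
  write_results_table(calls, file.path(cfg$out_dir, "synergy_calls.csv"))
  write_results_table(combined, file.path(cfg$out_dir, "combined_calls.csv"))
  write_results_table(ranked,
                      file.path(cfg$out_dir, "ranked_combinations.csv"))
  heatmap_path <- file.path(cfg$out_dir, "heatmap.json")
  stage("export", export_heatmap_json(T_mat, Sc_mat, calls, fits,
                                      heatmap_path))

  invisible(list(
    viabilities = viab, fits = fits, fit_summary = fsum, calls = calls,
    combined = combined, T = T_mat, Sc = Sc_mat, ranked = ranked,
    heatmap_path = heatmap_path
  ))
}

#' Export the drug-by-drug heatmap payload as JSON
#'
#' The payload mirrors an interactive heatmap viewer: a score matrix in
#' sparse triplet form (absolute score for the lower triangle, specificity
#' score for the upper), and a per-pair detail block giving, per cell line
#' and dose, the observed combination viability with a DMSO-derived error
#' bar, the Bliss-expected viability with a propagated standard error, both
#' singlet estimates, and the synergy/antagonism flags. Standard errors on
#' the `W` scale map to the viability scale by the delta method
#' (`se_V = V * ln(10) * se_W`).
#'
#' @param T_mat,Sc_mat Score matrices (shared drug order).
#' @param calls Per-assay calls from [infer_synergy()].
#' @param fits Named list of `bliss_fit` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_heatmap_json <- function(T_mat, Sc_mat, calls, fits, path) {
  if (!identical(dimnames(T_mat), dimnames(Sc_mat))) {
    abort("T and Sc matrices must share the same drug order")
  }
  drugs <- rownames(T_mat)
  idx <- which(upper.tri(T_mat), arr.ind = TRUE)
  matrix_entries <- tibble::tibble(
    i = unname(idx[, 1]), j = unname(idx[, 2]),
    drug1 = drugs[idx[, 1]], drug2 = drugs[idx[, 2]],
    absolute_score = T_mat[idx], specificity_score = Sc_mat[idx]
  )

  singlet_tbl <- purrr::map(fits, tidy) |> purrr::list_rbind()
  # DMSO sd per assay is recovered from each pair's null variance minus the
  # two singlet se^2 terms (it was built as their sum)
  ln10 <- log(10)
  details <- calls |>
    dplyr::left_join(
      dplyr::select(singlet_tbl, dplyr::all_of(c(
        "cell_line", "dose_level", "drug", "w_hat", "se", "v_hat"
      ))),
      by = c("cell_line", "dose_level", "drug1" = "drug")
    ) |>
    dplyr::rename(w_hat_1 = "w_hat", se_1 = "se", v_hat_1 = "v_hat") |>
    dplyr::left_join(
      dplyr::select(singlet_tbl, dplyr::all_of(c(
        "cell_line", "dose_level", "drug", "w_hat", "se", "v_hat"
      ))),
      by = c("cell_line", "dose_level", "drug2" = "drug")
    ) |>
    dplyr::rename(w_hat_2 = "w_hat", se_2 = "se", v_hat_2 = "v_hat") |>
    dplyr::mutate(
      expected_v = .data$v_hat_1 * .data$v_hat_2,
      se_w_expected = sqrt(.data$se_1^2 + .data$se_2^2),
      expected_v_se = .data$expected_v * ln10 * .data$se_w_expected,
      dmso_sd_w = sqrt(pmax(.data$var_null - .data$se_1^2 - .data$se_2^2, 0)),
      observed_v_se = .data$viability * ln10 * .data$dmso_sd_w,
      singlet_1_se_v = .data$v_hat_1 * ln10 * .data$se_1,
      singlet_2_se_v = .data$v_hat_2 * ln10 * .data$se_2
    ) |>
    dplyr::select(dplyr::all_of(c(
      "drug1", "drug2", "cell_line", "dose_level", "viability",
      "observed_v_se", "expected_v", "expected_v_se",
      "v_hat_1", "singlet_1_se_v", "v_hat_2", "singlet_2_se_v",
      "z", "q_syn", "q_ant", "synergistic", "antagonistic"
    )))
  detail_blocks <- details |>
    dplyr::group_by(.data$drug1, .data$drug2) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      list(drug1 = d$drug1[1], drug2 = d$drug2[1],
           cells = dplyr::select(d, -dplyr::all_of(c("drug1", "drug2"))))
    })

  payload <- list(
    drugs = drugs,
    n_cell_lines = length(unique(calls$cell_line)),
    matrix = matrix_entries,
    details = detail_blocks
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
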