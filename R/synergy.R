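#' Null variance for a pair's residual
#'
#' The null spread of a combination residual is modelled as the DMSO
#' measurement variance on the `W = -log10(V)` scale (pooled over the assay's
#' control wells) plus the squared standard errors of the two solved singlet
#' estimates: `var_null = var_dmso + se_i^2 + se_j^2`.
#'
#' @param var_dmso Unbiased sample variance of the assay's DMSO `W` values.
#' @param se_i,se_j Standard errors of the two singlet estimates.
#' @return The null variance (vectorized over pairs).
#' @export
null_variance <- function(var_dmso, se_i, se_j) {
  if (any(var_dmso < 0)) abort("var_dmso must be non-negative")
  var_dmso + se_i^2 + se_j^2
}

#' DMSO null model for one assay
#'
#' @param assay Per-assay viability tibble.
#' @return List with `var_dmso` (unbiased variance of control-well `W`),
#'   `n_dmso`, and the assay key.
#' @export
dmso_null <- function(assay) {
  w <- assay$w[assay$well_type == "control"]
  if (length(w) < 2) {
    abort("need at least 2 DMSO wells in the assay to estimate a variance")
  }
  list(
    var_dmso = var(w), n_dmso = length(w),
    cell_line = assay$cell_line[1], dose_level = assay$dose_level[1]
  )
}

#' Per-pair synergy Z values, p values and Excess-over-Bliss scores
#'
#' Converts each pair residual into `z = residual / sqrt(var_null)` and
#' one-sided tail probabilities under a standard-normal null:
#' `p_syn = 1 - pnorm(z)` (combination killed more than Bliss predicts) and
#' `p_ant = pnorm(z)`. Also reports the Excess-over-Bliss score
#' `S_ij = V_i * V_j - V_ij` computed two ways: from measured singlet wells
#' (`eob_raw`, `NA` when a singlet was not measured) and from the model
#' estimates (`eob_model`). Pairs with a very low observed combination
#' viability (`V_ij < 0.1`) are flagged (`low_viability`): the log-scale
#' variance may be understated there.
#'
#' @param fit A `bliss_fit` for the assay.
#' @param assay The matching per-assay viability tibble (supplies DMSO wells
#'   and measured singlet wells).
#' @return Tibble with one row per pair: assay key, drugs, `viability`,
#'   `residual`, `var_null`, `z`, `p_syn`, `p_ant`, `eob_raw`, `eob_model`,
#'   `low_viability`.
#' @export
synergy_pvalues <- function(fit, assay) {
  stopifnot(inherits(fit, "bliss_fit"))
  if (fit$cell_line != assay$cell_line[1] ||
      fit$dose_level != assay$dose_level[1]) {
    abort("fit and assay describe different (cell_line, dose_level) assays")
  }
  null <- dmso_null(assay)
  singlet_meas <- assay |>
    dplyr::filter(.data$well_type == "singlet") |>
    dplyr::group_by(.data$drug1) |>
    dplyr::summarise(v_meas = mean(.data$viability), .groups = "drop")
  v_meas <- setNames(singlet_meas$v_meas, singlet_meas$drug1)
  w_hat <- setNames(fit$singlets$w_hat, fit$singlets$drug)
  se <- setNames(fit$singlets$se, fit$singlets$drug)

  fit$pairs |>
    dplyr::mutate(
      cell_line = fit$cell_line, dose_level = fit$dose_level, .before = 1
    ) |>
    dplyr::mutate(
      var_null = unname(null_variance(null$var_dmso,
                                      se[.data$drug1], se[.data$drug2])),
      # floor avoids 0/0 on exactly noiseless assays; any real effect on a
      # degenerate-variance assay still yields an enormous |z|
      z = .data$residual / sqrt(pmax(.data$var_null, 1e-16)),
      p_syn = pnorm(.data$z, lower.tail = FALSE),
      p_ant = pnorm(.data$z),
      eob_raw = unname(v_meas[.data$drug1] * v_meas[.data$drug2]) -
        .data$viability,
      eob_model = unname(10^(-w_hat[.data$drug1]) * 10^(-w_hat[.data$drug2])) -
        .data$viability,
      low_viability = .data$viability < 0.1
    ) |>
    dplyr::select(-dplyr::all_of(c("w_obs", "fitted")))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up adjusted p values (monotone, capped at 1), preserving
#' input order.
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
adjust_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call synergies and antagonisms at an FDR threshold
#'
#' BH correction is applied separately to the synergy-direction and
#' antagonism-direction p value families, each across all pairs of one
#' assay, and calls are made at `q < alpha`.
#'
#' @param calls Output of [synergy_pvalues()] (one or more assays stacked).
#' @param alpha FDR threshold; default 0.05.
#' @return The input with `q_syn`, `q_ant`, `synergistic`, `antagonistic`
#'   columns added.
#' @export
call_synergies <- function(calls, alpha = 0.05) {
  calls |>
    dplyr::group_by(.data$cell_line, .data$dose_level) |>
    dplyr::mutate(
      q_syn = adjust_fdr(.data$p_syn),
      q_ant = adjust_fdr(.data$p_ant),
      synergistic = .data$q_syn < alpha,
      antagonistic = .data$q_ant < alpha
    ) |>
    dplyr::ungroup()
}

#' Synergy inference for every assay of a screen
#'
#' Convenience wrapper: runs [synergy_pvalues()] and [call_synergies()]
#' across all assays.
#'
#' @param viab Output of [compute_viabilities()].
#' @param fits Named list from [fit_all_assays()]; computed if missing.
#' @param alpha FDR threshold; default 0.05.
#' @return Stacked calls tibble for all assays.
#' @export
infer_synergy <- function(viab, fits = NULL, alpha = 0.05) {
  assays <- split_assays(viab)
  if (is.null(fits)) fits <- purrr::map(assays, \(a) solve_singlets(build_design(a)))
  purrr::map2(fits[names(assays)], assays, synergy_pvalues) |>
    purrr::list_rbind() |>
    call_synergies(alpha = alpha)
}

#' Combine synergy calls across the two doses
#'
#' A drug pair counts as synergistic in a cell line when it is called at
#' either dose; a pair observed at only one dose inherits that dose's
#' verdict.
#'
#' @param calls Output of [call_synergies()] / [infer_synergy()] containing
#'   one or both dose levels per cell line.
#' @return Tibble with `cell_line`, `drug1`, `drug2`, `synergy`,
#'   `antagonism`, `n_doses`.
#' @export
combine_doses <- function(calls) {
  calls |>
    dplyr::group_by(.data$cell_line, .data$drug1, .data$drug2) |>
    dplyr::summarise(
      synergy = any(.data$synergistic),
      antagonism = any(.data$antagonistic),
      n_doses = dplyr::n_distinct(.data$dose_level),
      .groups = "drop"
    )
}
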