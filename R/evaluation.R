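#' Agreement between estimated and measured singlet viabilities
#'
#' Pearson correlation, on the viability scale, between the model's singlet
#' estimates and the held-out measured singlet wells of the same assay.
#'
#' @param fit A `bliss_fit`.
#' @param assay The matching per-assay viability tibble.
#' @return The Pearson correlation, or `NA` when fewer than 3 drugs have
#'   measured singlets or either side has zero variance.
#' @export
singlet_agreement <- function(fit, assay) {
  meas <- assay |>
    dplyr::filter(.data$well_type == "singlet") |>
    dplyr::group_by(drug = .data$drug1) |>
    dplyr::summarise(v_meas = mean(.data$viability), .groups = "drop")
  joined <- dplyr::inner_join(fit$singlets, meas, by = "drug")
  if (nrow(joined) < 3) return(NA_real_)
  if (sd(joined$v_hat) == 0 || sd(joined$v_meas) == 0) return(NA_real_)
  cor(joined$v_hat, joined$v_meas)
}

#' Collect measured and estimated singlet values across a screen
#'
#' @param viab Output of [compute_viabilities()].
#' @param fits Named list from [fit_all_assays()]; computed if missing.
#' @return Tibble with `cell_line`, `dose_level`, `drug`, `v_measured`,
#'   `w_measured`, `v_estimated`, `w_hat`, `se`.
#' @export
collect_singlets <- function(viab, fits = NULL) {
  if (is.null(fits)) fits <- fit_all_assays(viab)
  measured <- viab |>
    dplyr::filter(.data$well_type == "singlet") |>
    dplyr::group_by(.data$cell_line, .data$dose_level, drug = .data$drug1) |>
    dplyr::summarise(
      v_measured = mean(.data$viability),
      w_measured = -log10(mean(.data$viability)),
      .groups = "drop"
    )
  estimated <- purrr::map(fits, tidy) |>
    purrr::list_rbind() |>
    dplyr::select(dplyr::all_of(c(
      "cell_line", "dose_level", "drug", "w_hat", "se", "v_hat"
    ))) |>
    dplyr::rename(v_estimated = "v_hat")
  dplyr::full_join(measured, estimated,
                   by = c("cell_line", "dose_level", "drug"))
}

#' Cross-dose correlation of singlet values, per drug
#'
#' For each drug, correlates its singlet viability profile across cell lines
#' between the high and the low dose, and tests the correlation against
#' zero with the exact t transform (`cor.test`). Consistency across doses is
#' the screen's internal proxy for replication: true drug effects should
#' correlate between doses, noise should not.
#'
#' @param singlets Output of [collect_singlets()].
#' @param variant `"estimated"` (model-solved singlets) or `"measured"`
#'   (raw singlet wells).
#' @param min_n Minimum number of cell lines with both doses (default 3);
#'   drugs with fewer are skipped.
#' @return Tibble with `drug`, `n`, `r`, `p`, `significant` (p < 0.05).
#' @export
cross_dose_correlations <- function(singlets,
                                    variant = c("estimated", "measured"),
                                    min_n = 3) {
  variant <- match.arg(variant)
  value_col <- if (variant == "estimated") "v_estimated" else "v_measured"
  wide <- singlets |>
    dplyr::select(dplyr::all_of(c("cell_line", "dose_level", "drug", value_col))) |>
    tidyr::pivot_wider(names_from = "dose_level",
                       values_from = dplyr::all_of(value_col))
  if (!all(c("high", "low") %in% names(wide))) {
    abort("need both 'high' and 'low' dose levels for cross-dose correlations")
  }
  wide |>
    dplyr::filter(!is.na(.data$high), !is.na(.data$low)) |>
    dplyr::group_by(.data$drug) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_n || sd(d$high) == 0 || sd(d$low) == 0) {
        return(tibble::tibble(n = nrow(d), r = NA_real_, p = NA_real_))
      }
      ct <- cor.test(d$high, d$low)
      tibble::tibble(n = nrow(d), r = unname(ct$estimate), p = ct$p.value)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$p) & .data$p < 0.05)
}

#' Compare measured vs estimated cross-dose correlation vectors
#'
#' Paired two-sided t test on the per-drug difference
#' (estimated r - measured r), plus both medians. Degenerate case (all
#' differences zero) reports p = 1.
#'
#' @param measured,estimated Tibbles from [cross_dose_correlations()]
#'   (aligned by `drug`).
#' @return Tibble with `median_r_measured`, `median_r_estimated`,
#'   `n_significant_measured`, `n_significant_estimated`, `n_drugs`,
#'   `p_value`.
#' @export
compare_correlation_vectors <- function(measured, estimated) {
  joined <- dplyr::inner_join(measured, estimated, by = "drug",
                              suffix = c("_meas", "_est")) |>
    dplyr::filter(!is.na(.data$r_meas), !is.na(.data$r_est))
  if (nrow(joined) == 0) abort("no drugs with correlations in both variants")
  diffs <- joined$r_est - joined$r_meas
  p <- if (length(diffs) < 2 || sd(diffs) == 0) 1 else t.test(diffs)$p.value
  tibble::tibble(
    median_r_measured = median(joined$r_meas),
    median_r_estimated = median(joined$r_est),
    n_significant_measured = sum(joined$significant_meas),
    n_significant_estimated = sum(joined$significant_est),
    n_drugs = nrow(joined),
    p_value = p
  )
}

#' Per-drug overlap of synergies between the two doses
#'
#' For each drug, builds a 2x2 table over (partner drug, cell line) units of
#' synergy-called-at-high-dose versus synergy-called-at-low-dose, and tests
#' association with the two-sided Fisher exact test. Drugs whose synergy
#' partners agree between doses gain confidence; disagreement flags either
#' dose-specific biology or noise.
#'
#' @param calls Output of [call_synergies()] / [infer_synergy()] containing
#'   both dose levels.
#' @return Tibble with `drug`, `n_syn_high`, `n_syn_low`, `n_overlap`,
#'   `n_units`, `p`, `significant` (p < 0.05).
#' @export
fisher_overlap_per_drug <- function(calls) {
  long <- dplyr::bind_rows(
    dplyr::transmute(calls, drug = .data$drug1, partner = .data$drug2,
                     cell_line = .data$cell_line,
                     dose_level = .data$dose_level,
                     synergistic = .data$synergistic),
    dplyr::transmute(calls, drug = .data$drug2, partner = .data$drug1,
                     cell_line = .data$cell_line,
                     dose_level = .data$dose_level,
                     synergistic = .data$synergistic)
  )
  wide <- long |>
    tidyr::pivot_wider(names_from = "dose_level",
                       values_from = "synergistic") |>
    dplyr::filter(!is.na(.data$high), !is.na(.data$low))
  wide |>
    dplyr::group_by(.data$drug) |>
    dplyr::group_modify(function(d, key) {
      tab <- table(factor(d$high, c(FALSE, TRUE)),
                   factor(d$low, c(FALSE, TRUE)))
      p <- fisher.test(tab)$p.value
      tibble::tibble(
        n_syn_high = sum(d$high), n_syn_low = sum(d$low),
        n_overlap = sum(d$high & d$low), n_units = nrow(d), p = p
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p < 0.05)
}
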