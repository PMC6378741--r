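#' Build the pairwise Bliss design system for one assay
#'
#' Each combination well contributes one equation `W_i + W_j = W_ij + eps`
#' where `W = -log10(V)`; the unknowns are the per-drug singlet
#' log-viabilities. Singlet wells are deliberately excluded: they are held
#' out for validation and never enter the fit. Duplicate observations of the
#' same pair (e.g. across plates) each contribute an equation.
#'
#' @param assay A per-assay viability tibble (one `(cell_line, dose_level)`;
#'   see [split_assays()]).
#' @return An object of class `bliss_design`: list with `drugs`
#'   (lexicographic), `pairs` (tibble `drug1`, `drug2`, `w_obs`, `viability`),
#'   `incidence` (m x n 0/1 matrix, two ones per row), `m`, `n`, `cell_line`,
#'   `dose_level`.
#' @export
build_design <- function(assay) {
  key <- dplyr::distinct(assay, .data$cell_line, .data$dose_level)
  if (nrow(key) != 1) {
    abort("`assay` must contain exactly one (cell_line, dose_level) assay")
  }
  pairs <- assay |>
    dplyr::filter(.data$well_type == "pair") |>
    dplyr::select(dplyr::all_of(c("drug1", "drug2", "viability", "w"))) |>
    dplyr::rename(w_obs = "w")
  drugs <- sort(unique(c(pairs$drug1, pairs$drug2)))
  n <- length(drugs)
  m <- nrow(pairs)
  if (n < 3) abort("need at least 3 drugs in the pair design")
  g <- igraph::graph_from_data_frame(pairs[, c("drug1", "drug2")],
                                     directed = FALSE,
                                     vertices = drugs)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    parts <- split(names(comp$membership), comp$membership)
    abort(paste0(
      "pair design is disconnected; components: ",
      paste(vapply(parts, \(p) paste(p, collapse = "+"), ""), collapse = " | ")
    ))
  }
  if (m < n) {
    abort(sprintf("under-determined system: %d equations for %d drugs", m, n))
  }
  X <- matrix(0, m, n, dimnames = list(NULL, drugs))
  X[cbind(seq_len(m), match(pairs$drug1, drugs))] <- 1
  X[cbind(seq_len(m), match(pairs$drug2, drugs))] <- 1
  structure(
    list(drugs = drugs, pairs = pairs, incidence = X, m = m, n = n,
         cell_line = key$cell_line, dose_level = key$dose_level),
    class = "bliss_design"
  )
}

#' Solve the singlet log-viabilities by least squares
#'
#' Ordinary least squares with no intercept: minimizes
#' `sum((W_ij - w_i - w_j)^2)` over the per-drug `w`. Residuals keep the sign
#' convention `r_ij = W_ij - (w_i + w_j)`, so a positive residual means the
#' observed combination viability is lower than the Bliss expectation —
#' synergy. R-squared is reported against the mean-model baseline
#' (`TSS = sum((W_ij - mean(W_ij))^2)`).
#'
#' @param design A `bliss_design` (or a per-assay viability tibble, which is
#'   passed through [build_design()] first).
#' @return An object of class `bliss_fit`: list with `singlets` tibble
#'   (`drug`, `w_hat`, `se`, `ci_lo`, `ci_hi`, `v_hat`), `pairs` tibble
#'   (`drug1`, `drug2`, `viability`, `w_obs`, `fitted`, `residual`),
#'   `sigma2_model`, `r_squared`, `m`, `n`, `cell_line`, `dose_level`.
#' @export
#' @examples
#' v <- generate_screen(screen_spec(n_drugs = 6, n_cell_lines = 1,
#'                                  doses = "high", seed = 7))$plates |>
#'   compute_viabilities(polish = FALSE)
#' fit <- solve_singlets(build_design(v))
#' glance(fit)
solve_singlets <- function(design) {
  if (!inherits(design, "bliss_design")) design <- build_design(design)
  X <- design$incidence
  y <- design$pairs$w_obs
  qrX <- qr(X)
  if (qrX$rank < design$n) {
    abort("incidence matrix is rank deficient (this should be impossible for a connected pair design)")
  }
  w_hat <- qr.coef(qrX, y)
  fitted <- drop(X %*% w_hat)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df <- design$m - design$n
  sigma2 <- if (df > 0) rss / df else 0
  xtx_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  r_squared <- if (tss > 0) 1 - rss / tss else if (rss == 0) 1 else NA_real_
  singlets <- tibble::tibble(
    drug = design$drugs,
    w_hat = unname(w_hat),
    se = se,
    ci_lo = unname(w_hat) - 1.96 * se,
    ci_hi = unname(w_hat) + 1.96 * se,
    v_hat = 10^(-unname(w_hat))
  )
  pairs <- design$pairs |>
    dplyr::mutate(fitted = fitted, residual = resid)
  structure(
    list(singlets = singlets, pairs = pairs, sigma2_model = sigma2,
         r_squared = r_squared, m = design$m, n = design$n,
         cell_line = design$cell_line, dose_level = design$dose_level),
    class = "bliss_fit"
  )
}

#' @export
print.bliss_fit <- function(x, ...) {
  cat(sprintf(
    "<bliss_fit> assay (%s, %s): %d pair equations, %d drugs, R^2 = %.3f, sigma2 = %.2e\n",
    x$cell_line, x$dose_level, x$m, x$n, x$r_squared, x$sigma2_model
  ))
  invisible(x)
}

#' Per-drug singlet estimates with confidence intervals
#'
#' @param fit A `bliss_fit`.
#' @return Tibble with `drug`, `w_hat`, `se`, `ci_lo`, `ci_hi` (95% interval
#'   on the W scale) and `v_hat = 10^(-w_hat)` on the viability scale.
#' @export
singlet_estimates <- function(fit) {
  stopifnot(inherits(fit, "bliss_fit"))
  fit$singlets
}

#' Fit the Bliss linear model for every assay in a viability table
#'
#' @param viab Output of [compute_viabilities()].
#' @return Named list of `bliss_fit` objects (names `"<cell_line>.<dose_level>"`).
#' @export
fit_all_assays <- function(viab) {
  purrr::map(split_assays(viab), \(a) solve_singlets(build_design(a)))
}

#' Fit summaries across assays
#'
#' @param fits A list of `bliss_fit` objects (see [fit_all_assays()]).
#' @return Tibble with one row per assay: `cell_line`, `dose_level`, `m`, `n`,
#'   `r_squared`, `sigma2_model`.
#' @export
fit_summary <- function(fits) {
  purrr::map(fits, glance) |> purrr::list_rbind()
}
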