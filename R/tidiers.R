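#' Tidy a Bliss fit
#'
#' One row per drug with the estimated singlet log-viability and its
#' uncertainty, in broom's term/estimate convention.
#'
#' @param x A `bliss_fit`.
#' @param ... Unused.
#' @return Tibble with `cell_line`, `dose_level`, `drug`, `w_hat`, `se`,
#'   `ci_lo`, `ci_hi`, `v_hat`.
#' @exportS3Method generics::tidy
tidy.bliss_fit <- function(x, ...) {
  dplyr::mutate(x$singlets,
    cell_line = x$cell_line, dose_level = x$dose_level,
    .before = 1
  )
}

#' One-row summary of a Bliss fit
#'
#' @param x A `bliss_fit`.
#' @param ... Unused.
#' @return Tibble with `cell_line`, `dose_level`, `m` (equations), `n`
#'   (drugs), `df_residual`, `r_squared`, `sigma2_model`.
#' @exportS3Method generics::glance
glance.bliss_fit <- function(x, ...) {
  tibble::tibble(
    cell_line = x$cell_line, dose_level = x$dose_level,
    m = x$m, n = x$n, df_residual = x$m - x$n,
    r_squared = x$r_squared, sigma2_model = x$sigma2_model
  )
}

#' Per-pair fitted values and residuals of a Bliss fit
#'
#' @param x A `bliss_fit`.
#' @param ... Unused.
#' @return Tibble with one row per combination well: observed and fitted
#'   `W`, and the residual whose positive direction is synergy.
#' @exportS3Method generics::augment
augment.bliss_fit <- function(x, ...) {
  dplyr::mutate(x$pairs,
    cell_line = x$cell_line, dose_level = x$dose_level,
    .before = 1
  )
}
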