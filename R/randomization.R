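#' Permute synergy calls within each cell line
#'
#' For each cell line independently, uniformly permutes the boolean synergy
#' vector over drug pairs, preserving every per-cell-line synergy total
#' exactly. This null keeps each cell line's overall synergy propensity but
#' destroys any association between synergy and particular drug pairs.
#'
#' @param combined Dose-combined calls (see [combine_doses()]).
#' @param seed Integer seed.
#' @return A tibble with the same rows and the `synergy` column permuted
#'   within cell line.
#' @export
permute_within_cell_line <- function(combined, seed) {
  set.seed(seed)
  combined |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::mutate(synergy = sample(.data$synergy)) |>
    dplyr::ungroup()
}

#' Binomial null matrix conserving per-drug synergy marginals
#'
#' Simulates an absolute-synergy-score matrix in which each pair count is
#' drawn `T'_ij ~ Binomial(N, clip(p_i + p_j, 0, 1))`, with per-drug
#' propensities `p_i >= 0` fitted so the expected per-drug totals match the
#' observed ones. This conserves each drug's promiscuity while erasing
#' pair-specific structure. Fitting minimizes `sum_i (E_i - O_i)^2` by
#' coordinate descent (`E_i = sum_k N * clip(p_i + p_k, 0, 1)`,
#' `O_i = sum_k T_ik`), starting from `p_i = O_i / (2 N (n - 1))`.
#'
#' @param T_mat Observed symmetric integer matrix.
#' @param n_cell_lines `N`, the binomial size (number of cell lines).
#' @param seed Integer seed for the draw.
#' @param p Optional pre-fitted propensities (skips the fit; used when
#'   drawing many replicates from one fit).
#' @return Symmetric integer matrix of the same dimensions; the fitted
#'   propensities are attached as attribute `"p"`.
#' @export
binomial_null_matrix <- function(T_mat, n_cell_lines, seed, p = NULL) {
  if (is.null(p)) p <- fit_marginal_propensities(T_mat, n_cell_lines)
  set.seed(seed)
  n <- nrow(T_mat)
  out <- matrix(0L, n, n, dimnames = dimnames(T_mat))
  iu <- which(upper.tri(out), arr.ind = TRUE)
  prob <- pmin(pmax(p[iu[, 1]] + p[iu[, 2]], 0), 1)
  draw <- rbinom(nrow(iu), size = n_cell_lines, prob = prob)
  out[iu] <- draw
  out[iu[, c(2, 1)]] <- draw
  attr(out, "p") <- p
  out
}

#' Fit per-drug propensities for the binomial null
#'
#' @param T_mat Observed symmetric matrix.
#' @param n_cell_lines Binomial size `N`.
#' @param tol Relative-change convergence tolerance (default 1e-8).
#' @param max_sweeps Maximum coordinate-descent sweeps (default 500).
#' @return Numeric vector of propensities `p_i >= 0`, named by drug.
#' @export
fit_marginal_propensities <- function(T_mat, n_cell_lines, tol = 1e-8,
                                      max_sweeps = 500) {
  n <- nrow(T_mat)
  N <- n_cell_lines
  O <- rowSums(T_mat)
  p <- O / (N * (n - 1) * 2)
  objective <- function(pv) {
    P <- pmin(pmax(outer(pv, pv, "+"), 0), 1)
    diag(P) <- 0
    E <- N * rowSums(P)
    sum((E - O)^2)
  }
  obj <- objective(p)
  for (sweep in seq_len(max_sweeps)) {
    for (i in seq_len(n)) {
      f_i <- function(x) {
        pv <- p
        pv[i] <- x
        objective(pv)
      }
      p[i] <- optimize(f_i, interval = c(0, 1), tol = 1e-10)$minimum
    }
    new_obj <- objective(p)
    if (abs(obj - new_obj) <= tol * max(obj, 1e-12)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  if (sweep == max_sweeps && abs(obj) > 1e-6 * sum(O^2)) {
    warn(sprintf("marginal propensity fit stopped at %d sweeps; objective %.3g",
                 max_sweeps, obj))
  }
  setNames(p, rownames(T_mat))
}

#' High-score randomization test
#'
#' Counts pairs whose absolute synergy score exceeds a threshold and compares
#' against the same count in matrices drawn from the marginal-conserving
#' binomial null. The empirical p value uses the add-one rule
#' `(1 + #(null >= observed)) / (1 + n_rand)` and so is never exactly zero.
#'
#' @param T_mat Observed symmetric matrix.
#' @param n_cell_lines Binomial size `N`.
#' @param threshold Score threshold; a pair counts when `T_ij > threshold`
#'   (default 12).
#' @param n_rand Number of null draws (default 1000).
#' @param seed Master seed; per-replicate streams are spawned from it.
#' @return List of class `high_score_test`: `observed_high_count`,
#'   `null_high_counts`, `empirical_p`, `threshold`, `n_rand`, `seed`,
#'   fitted `p`.
#' @export
high_score_test <- function(T_mat, n_cell_lines, threshold = 12,
                            n_rand = 1000, seed = 1) {
  if (n_rand < 1) abort("n_rand must be >= 1")
  observed <- sum(T_mat[upper.tri(T_mat)] > threshold)
  p_fit <- fit_marginal_propensities(T_mat, n_cell_lines)
  seeds <- spawn_seeds(seed, n_rand)
  null_counts <- vapply(seeds, function(s) {
    Tr <- binomial_null_matrix(T_mat, n_cell_lines, seed = s, p = p_fit)
    sum(Tr[upper.tri(Tr)] > threshold)
  }, integer(1))
  structure(
    list(
      observed_high_count = observed,
      null_high_counts = null_counts,
      empirical_p = (1 + sum(null_counts >= observed)) / (1 + n_rand),
      threshold = threshold, n_rand = n_rand, seed = seed, p = p_fit
    ),
    class = "high_score_test"
  )
}

#' @export
print.high_score_test <- function(x, ...) {
  cat(sprintf(
    "<high_score_test> observed %d pairs with T > %d; null mean %.2f; empirical p = %.4g (%d draws)\n",
    x$observed_high_count, x$threshold, mean(x$null_high_counts),
    x$empirical_p, x$n_rand
  ))
  invisible(x)
}
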