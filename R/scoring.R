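#' Absolute synergy score matrix
#'
#' For every drug pair, counts the number of cell lines in which the pair
#' was called synergistic (after dose combining): the absolute synergy score
#' `T_ij`, a symmetric integer matrix with an undefined (zero) diagonal.
#'
#' @param combined Output of [combine_doses()] (the "synergy cube" in long
#'   form), or any tibble with `cell_line`, `drug1`, `drug2`, `synergy`.
#' @param drugs Optional character vector fixing the drug order; defaults to
#'   the sorted union of drugs present.
#' @return Symmetric integer matrix with drug names on both dimensions.
#' @export
absolute_synergy_scores <- function(combined, drugs = NULL) {
  if (is.null(drugs)) drugs <- sort(unique(c(combined$drug1, combined$drug2)))
  n <- length(drugs)
  T_mat <- matrix(0L, n, n, dimnames = list(drugs, drugs))
  counts <- combined |>
    dplyr::group_by(.data$drug1, .data$drug2) |>
    dplyr::summarise(t = sum(.data$synergy), .groups = "drop")
  i <- match(counts$drug1, drugs)
  j <- match(counts$drug2, drugs)
  T_mat[cbind(i, j)] <- as.integer(counts$t)
  T_mat[cbind(j, i)] <- as.integer(counts$t)
  T_mat
}

#' Specificity score matrix
#'
#' Standardizes each pair's absolute synergy score against the synergy
#' profile of each of its two drugs, and takes the minimum:
#' `Sc_ij = min(z_i, z_j)` with
#' `z_i = (T_ij - mean_k(T_ik)) / sd_k(T_ik)` over all partners `k != i`
#' (including `k = j` by default). A pair involving a promiscuous drug — one
#' that synergizes with nearly everything — gets a small score even when
#' `T_ij` is large, so specific synergies rank above broad sensitization.
#' Sample SD (`n - 1` denominator); a zero SD contributes a neutral 0.
#'
#' @param T_mat Symmetric integer matrix from [absolute_synergy_scores()].
#' @param include_self Include `T_ij` itself in drug `i`'s partner set
#'   (default `TRUE`).
#' @return Symmetric numeric matrix of specificity scores, `NA` diagonal.
#' @export
specificity_scores <- function(T_mat, include_self = TRUE) {
  n <- nrow(T_mat)
  if (n < 3) abort("specificity scores need at least 3 drugs")
  if (!isTRUE(all.equal(unname(T_mat), unname(t(T_mat))))) {
    abort("T matrix must be symmetric")
  }
  drugs <- rownames(T_mat)
  Z <- matrix(NA_real_, n, n, dimnames = list(drugs, drugs))
  for (i in seq_len(n)) {
    partners <- setdiff(seq_len(n), i)
    vals <- T_mat[i, partners]
    for (j in partners) {
      ref <- if (include_self) vals else T_mat[i, setdiff(partners, j)]
      s <- sd(ref)
      Z[i, j] <- if (is.na(s) || s == 0) 0 else (T_mat[i, j] - mean(ref)) / s
    }
  }
  Sc <- pmin(Z, t(Z))
  diag(Sc) <- NA_real_
  Sc
}

#' Ranked table of drug combinations
#'
#' One row per pair, ordered by absolute synergy score (descending) with
#' specificity score as tie-break, plus the percentile of the specificity
#' score across all pairs.
#'
#' @param T_mat Absolute synergy score matrix.
#' @param Sc_mat Specificity score matrix (same drug order).
#' @return Tibble with `drug1`, `drug2`, `absolute_score`,
#'   `specificity_score`, `rank`, `specificity_percentile`.
#' @export
rank_combinations <- function(T_mat, Sc_mat) {
  if (!identical(dimnames(T_mat), dimnames(Sc_mat))) {
    abort("T and Sc matrices must share the same drug order")
  }
  drugs <- rownames(T_mat)
  idx <- which(upper.tri(T_mat), arr.ind = TRUE)
  tbl <- tibble::tibble(
    drug1 = drugs[idx[, 1]],
    drug2 = drugs[idx[, 2]],
    absolute_score = T_mat[idx],
    specificity_score = Sc_mat[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$absolute_score),
                   dplyr::desc(.data$specificity_score)) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      specificity_percentile =
        100 * rank(.data$specificity_score, ties.method = "average") /
        dplyr::n()
    )
  tbl
}
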