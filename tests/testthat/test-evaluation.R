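test_that("estimated singlets agree perfectly with held-out noiseless singlets", {
  spec <- screen_spec(n_drugs = 10, n_cell_lines = 1, doses = "high",
                      noise_sd_w = 0, singlet_well_noise_multiplier = 1,
                      row_col_artifact_sd = 0, seed = 14)
  viab <- compute_viabilities(generate_screen(spec)$plates, polish = FALSE)
  fit <- solve_singlets(build_design(viab))
  expect_equal(singlet_agreement(fit, viab), 1, tolerance = 1e-9)
})

test_that("agreement is location-invariant (a constant offset keeps r = 1)", {
  spec <- screen_spec(n_drugs = 8, n_cell_lines = 1, doses = "high",
                      noise_sd_w = 0, singlet_well_noise_multiplier = 1,
                      row_col_artifact_sd = 0, seed = 15)
  viab <- compute_viabilities(generate_screen(spec)$plates, polish = FALSE)
  fit <- solve_singlets(build_design(viab))
  fit$singlets$v_hat <- fit$singlets$v_hat + 0.25
  expect_equal(singlet_agreement(fit, viab), 1, tolerance = 1e-9)
})

test_that("cross-dose correlation testing matches the exact t transform", {
  # r = 0.5 at n = 40: t = r sqrt(n-2)/sqrt(1-r^2) ~ 3.56, p < 0.05
  r <- 0.5
  n <- 40
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p_closed <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  expect_lt(p_closed, 0.05)
  expect_equal(t_stat, 3.559026, tolerance = 1e-6)

  set.seed(10)
  x <- rnorm(n)
  # build y with exact sample correlation r to x
  e <- stats::residuals(stats::lm(rnorm(n) ~ x))
  y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  singlets <- tibble::tibble(
    cell_line = sprintf("cl%02d", 1:n), drug = "d1",
    dose_level = "high", v_estimated = x, v_measured = x
  ) |>
    dplyr::bind_rows(tibble::tibble(
      cell_line = sprintf("cl%02d", 1:n), drug = "d1",
      dose_level = "low", v_estimated = y, v_measured = y
    ))
  res <- cross_dose_correlations(singlets, "estimated")
  expect_equal(res$r, r, tolerance = 1e-10)
  expect_equal(res$p, p_closed, tolerance = 1e-10)
  expect_true(res$significant)

  identical_res <- cross_dose_correlations(
    dplyr::mutate(singlets, v_estimated = rep(x, 2)), "estimated"
  )
  expect_equal(identical_res$r, 1, tolerance = 1e-12)
})

test_that("under independence ~5% of drugs show significant cross-dose r", {
  set.seed(77)
  n_drugs <- 400
  n_lines <- 40
  singlets <- tidyr::expand_grid(
    drug = sprintf("d%03d", seq_len(n_drugs)),
    cell_line = sprintf("cl%02d", seq_len(n_lines)),
    dose_level = c("high", "low")
  ) |>
    dplyr::mutate(v_estimated = rnorm(dplyr::n()), v_measured = 0)
  res <- cross_dose_correlations(singlets, "estimated")
  rate <- mean(res$significant)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("comparing correlation vectors is a paired t test with medians", {
  measured <- tibble::tibble(drug = sprintf("d%d", 1:30),
                             r = seq(0.0, 0.29, by = 0.01),
                             p = 0.5, significant = FALSE)
  identical_p <- compare_correlation_vectors(measured, measured)
  expect_equal(identical_p$p_value, 1)
  set.seed(3)
  estimated <- dplyr::mutate(measured, r = r + 0.3 + rnorm(30, 0, 0.01),
                             significant = TRUE)
  res <- compare_correlation_vectors(measured, estimated)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$median_r_estimated - res$median_r_measured, 0.3,
               tolerance = 0.02)
  expect_equal(res$n_significant_estimated, 30)
})

test_that("fisher overlap p matches the hypergeometric enumeration", {
  # two-sided Fisher p for [[10, 0], [0, 10]] is 2 / C(20, 10)
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  p <- fisher.test(tab)$p.value
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(p, 1e-4)

  # brute-force oracle on small random tables: sum of P(table') <= P(table)
  fisher_oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    x <- tab[1, 1]
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    sum(probs[probs <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
  }
  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) next
    expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-7)
  }
})

test_that("per-drug dose overlap flags drugs with matching synergy sets", {
  set.seed(19)
  pairs <- full_pair_grid(10)
  grid <- tidyr::expand_grid(cell_line = sprintf("cl%d", 1:6), pairs)
  # drug01: identical synergy sets at both doses; others: independent noise
  base <- dplyr::mutate(grid,
    hit = (drug1 == "drug01" | drug2 == "drug01") & runif(dplyr::n()) < 0.4)
  calls <- dplyr::bind_rows(
    dplyr::mutate(base, dose_level = "high",
                  synergistic = hit | runif(dplyr::n()) < 0.05),
    dplyr::mutate(base, dose_level = "low",
                  synergistic = hit | runif(dplyr::n()) < 0.05)
  ) |>
    dplyr::select(-hit)
  rep <- fisher_overlap_per_drug(calls)
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  expect_true(rep$significant[rep$drug == "drug01"])
  d1 <- rep[rep$drug == "drug01", ]
  expect_equal(d1$n_units, 9 * 6)
})
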