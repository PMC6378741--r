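# A small assay with a known planted effect, used across the inference tests.
planted_assay <- function(n = 10, delta = 0.6, noise = 0, seed = 1,
                          dmso_w = rep(0, 8), cell_line = "cl1",
                          dose_level = "high") {
  set.seed(seed)
  pairs <- full_pair_grid(n)
  pairs$w <- ifelse(pairs$drug1 == "drug01" & pairs$drug2 == "drug02",
                    delta, 0) + rnorm(nrow(pairs), 0, noise)
  make_assay(pairs, dmso_w = dmso_w, cell_line = cell_line,
             dose_level = dose_level)
}

test_that("the null variance adds DMSO variance and both singlet se^2", {
  expect_equal(null_variance(0.01, 0.05, 0.05), 0.015)
  expect_error(null_variance(-1e-3, 0.05, 0.05), "non-negative")
  # scaling DMSO W deviations by c multiplies var_dmso by c^2
  w <- c(-0.02, 0.01, 0.03, -0.01, 0.04)
  expect_equal(var(3 * w), 9 * var(w))
})

test_that("an assay needs at least two DMSO wells for a null", {
  assay <- planted_assay(dmso_w = 0)
  expect_error(dmso_null(assay), "at least 2 DMSO")
})

test_that("z and one-sided tails follow the standard normal null", {
  # residual 0.2 against var_null 0.01 is z = 2
  assay <- planted_assay(n = 4, delta = 0.6, dmso_w = c(0, 0, 0, 0))
  fit <- solve_singlets(build_design(assay))
  fit$singlets$se <- sqrt(0.005)  # forces var_null = 0 + 0.005 + 0.005
  calls <- synergy_pvalues(fit, assay)
  hit <- calls[calls$drug1 == "drug01" & calls$drug2 == "drug02", ]
  expect_equal(hit$residual, 0.2, tolerance = 1e-10)
  expect_equal(hit$var_null, 0.01)
  expect_equal(hit$z, 2, tolerance = 1e-9)
  expect_equal(hit$p_syn, 0.02275013, tolerance = 1e-6)
  expect_equal(hit$p_ant, 0.97724987, tolerance = 1e-6)
  expect_equal(calls$p_syn + calls$p_ant, rep(1, nrow(calls)))
})

test_that("a zero residual sits exactly at p = 0.5", {
  assay <- planted_assay(n = 5, delta = 0, dmso_w = c(-0.01, 0, 0.01, 0.02))
  fit <- solve_singlets(build_design(assay))
  calls <- synergy_pvalues(fit, assay)
  expect_equal(calls$p_syn, rep(0.5, nrow(calls)))
})

test_that("excess-over-Bliss uses V_i V_j - V_ij on the viability scale", {
  # Vhat_i = Vhat_j = 0.5, V_ij = 0.1 gives eob_model = 0.15
  pairs <- tibble::tibble(drug1 = c("A", "A", "B"), drug2 = c("B", "C", "C"),
                          w = c(-log10(0.1), -log10(0.05), 0.5))
  assay <- make_assay(pairs, singlet_w = tibble::tibble(
    drug = c("A", "B", "C"), w = c(0.2, 0.3, 0.1)
  ))
  fit <- solve_singlets(build_design(assay))
  fit$singlets$w_hat <- c(-log10(0.5), -log10(0.5), 0.3)
  calls <- synergy_pvalues(fit, assay)
  ab <- calls[calls$drug1 == "A" & calls$drug2 == "B", ]
  expect_equal(ab$eob_model, 0.5 * 0.5 - 0.1, tolerance = 1e-12)
  expect_equal(ab$eob_raw, 10^(-0.2) * 10^(-0.3) - 0.1, tolerance = 1e-12)
  # V_ij = 0.1 sits at the flag boundary (not flagged); V_ij = 0.05 is
  ac <- calls[calls$drug1 == "A" & calls$drug2 == "C", ]
  expect_false(ab$low_viability)
  expect_true(ac$low_viability)
})

test_that("BH adjustment reproduces the step-up worked examples", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("calls are made at q < alpha, never both directions at once", {
  assay <- planted_assay(n = 12, delta = 0.6, noise = 0.02,
                         dmso_w = rnorm(8, 0, 0.02))
  calls <- infer_synergy(assay, alpha = 0.05)
  expect_true(all(calls$q_syn >= calls$p_syn))
  expect_true(all(calls$q_ant >= calls$p_ant))
  expect_false(any(calls$synergistic & calls$antagonistic))
  hit <- calls[calls$drug1 == "drug01" & calls$drug2 == "drug02", ]
  expect_true(hit$synergistic)
  expect_false(any(calls$synergistic[!(calls$drug1 == "drug01" &
                                         calls$drug2 == "drug02")]))
})

test_that("p_syn decreases monotonically in the residual at fixed variance", {
  z <- seq(-3, 3, by = 0.5)
  p <- pnorm(z, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
  assay <- planted_assay(n = 8, delta = 0.4, noise = 0.01,
                         dmso_w = rnorm(8, 0, 0.02), seed = 3)
  calls <- synergy_pvalues(solve_singlets(build_design(assay)), assay)
  ord <- order(calls$residual)
  expect_true(all(diff(calls$p_syn[ord]) <= 0))
})

test_that("noiseless assays yield a ~zero null variance and no calls", {
  assay <- planted_assay(n = 10, delta = 0, noise = 0, dmso_w = rep(0, 8))
  calls <- infer_synergy(assay)
  expect_lt(max(calls$var_null), 1e-12)
  expect_false(any(calls$synergistic | calls$antagonistic))
})

test_that("dose combining is an OR over the available doses", {
  base <- tibble::tibble(
    cell_line = "cl1",
    drug1 = c("A", "A", "B"), drug2 = c("B", "C", "C")
  )
  high <- dplyr::mutate(base, dose_level = "high",
                        synergistic = c(TRUE, FALSE, FALSE),
                        antagonistic = FALSE)
  low <- dplyr::mutate(base[1:2, ], dose_level = "low",
                       synergistic = c(FALSE, FALSE),
                       antagonistic = c(FALSE, TRUE))
  comb <- combine_doses(dplyr::bind_rows(high, low))
  expect_equal(comb$synergy[comb$drug1 == "A" & comb$drug2 == "B"], TRUE)
  expect_equal(comb$synergy[comb$drug1 == "A" & comb$drug2 == "C"], FALSE)
  expect_equal(comb$antagonism[comb$drug1 == "A" & comb$drug2 == "C"], TRUE)
  # pair observed at one dose inherits that dose's verdict
  bc <- comb[comb$drug1 == "B" & comb$drug2 == "C", ]
  expect_equal(bc$n_doses, 1L)
  expect_false(bc$synergy)
})

test_that("inflating assay noise cannot inflate model-based calls", {
  n_calls <- sapply(c(1, 5), function(mult) {
    spec <- screen_spec(n_drugs = 15, n_cell_lines = 1, doses = "high",
                        noise_sd_w = 0.05 * mult,
                        singlet_well_noise_multiplier = 1,
                        row_col_artifact_sd = 0, seed = 21)
    scr <- generate_screen(spec)
    calls <- infer_synergy(compute_viabilities(scr$plates, polish = FALSE))
    sum(calls$synergistic)
  })
  expect_lte(n_calls[2], n_calls[1])
})
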