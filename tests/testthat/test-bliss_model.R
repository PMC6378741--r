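test_that("three drugs with all pairs give the canonical incidence matrix", {
  pairs <- tibble::tibble(
    drug1 = c("A", "A", "B"), drug2 = c("B", "C", "C"),
    w = c(0.30, 0.40, 0.50)
  )
  design <- build_design(make_assay(pairs))
  expect_equal(unname(design$incidence),
               matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1), 3, 3, byrow = TRUE))
  expect_equal(design$drugs, c("A", "B", "C"))
})

test_that("an exactly determined 3-drug system solves in closed form", {
  pairs <- tibble::tibble(
    drug1 = c("A", "A", "B"), drug2 = c("B", "C", "C"),
    w = c(0.30, 0.40, 0.50)
  )
  fit <- solve_singlets(build_design(make_assay(pairs)))
  expect_equal(fit$singlets$w_hat, c(0.10, 0.20, 0.30), tolerance = 1e-12)
  expect_equal(fit$pairs$residual, rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$sigma2_model, 0)
})

test_that("a single planted synergy on a 4-drug full design follows the closed form", {
  pairs <- full_pair_grid(4)
  pairs$w <- ifelse(pairs$drug1 == "drug01" & pairs$drug2 == "drug02", 0.6, 0)
  fit <- solve_singlets(build_design(make_assay(pairs)))
  expect_equal(fit$singlets$w_hat, c(0.2, 0.2, -0.1, -0.1), tolerance = 1e-12)
  r12 <- fit$pairs$residual[fit$pairs$drug1 == "drug01" &
                              fit$pairs$drug2 == "drug02"]
  expect_equal(r12, 0.2, tolerance = 1e-12)
})

test_that("a planted effect leaves residual delta * (1 - h), h = 2/(n-1)", {
  for (n in c(4, 6, 9)) {
    pairs <- full_pair_grid(n)
    delta <- 0.5
    pairs$w <- ifelse(pairs$drug1 == "drug01" & pairs$drug2 == "drug02",
                      delta, 0)
    fit <- solve_singlets(build_design(make_assay(pairs)))
    r12 <- fit$pairs$residual[fit$pairs$drug1 == "drug01" &
                                fit$pairs$drug2 == "drug02"]
    expect_equal(r12, delta * (1 - 2 / (n - 1)), tolerance = 1e-10)
  }
})

test_that("disconnected pair designs are rejected with the components listed", {
  pairs <- tibble::tibble(
    drug1 = c("A", "C"), drug2 = c("B", "D"), w = c(0.1, 0.2)
  )
  expect_error(build_design(make_assay(pairs)), "disconnected")
})

test_that("least squares matches a generic numerical optimizer for n <= 6", {
  set.seed(123)
  for (n in 3:6) {
    pairs <- full_pair_grid(n)
    w_true <- rnorm(n, 0.3, 0.2)
    names(w_true) <- sprintf("drug%02d", seq_len(n))
    pairs$w <- w_true[pairs$drug1] + w_true[pairs$drug2] +
      rnorm(nrow(pairs), 0, 0.05)
    fit <- solve_singlets(build_design(make_assay(pairs)))
    obj <- function(w) {
      names(w) <- names(w_true)
      sum((pairs$w - w[pairs$drug1] - w[pairs$drug2])^2)
    }
    oracle <- optim(rep(0, n), obj, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 5000))
    expect_lt(max(abs(fit$singlets$w_hat - oracle$par)), 1e-6)
  }
})

test_that("noiseless generated screens are recovered exactly", {
  spec <- screen_spec(n_drugs = 12, n_cell_lines = 1, doses = "high",
                      noise_sd_w = 0, singlet_well_noise_multiplier = 1,
                      row_col_artifact_sd = 0, seed = 4)
  scr <- generate_screen(spec)
  fit <- solve_singlets(build_design(
    compute_viabilities(scr$plates, polish = FALSE)
  ))
  truth <- scr$truth$singlets
  expect_lt(max(abs(fit$singlets$w_hat -
                      truth$w_true[match(fit$singlets$drug, truth$drug)])),
            1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(fit$singlets$se), 1e-9)
})

test_that("reported standard errors match the empirical spread of estimates", {
  set.seed(99)
  n <- 20
  pairs <- full_pair_grid(n)
  w_true <- rnorm(n, 0.3, 0.2)
  names(w_true) <- sprintf("drug%02d", seq_len(n))
  mu <- w_true[pairs$drug1] + w_true[pairs$drug2]
  est <- matrix(NA_real_, 200, n)
  se <- matrix(NA_real_, 200, n)
  for (r in 1:200) {
    pairs$w <- mu + rnorm(nrow(pairs), 0, 0.05)
    fit <- solve_singlets(build_design(make_assay(pairs)))
    est[r, ] <- fit$singlets$w_hat
    se[r, ] <- fit$singlets$se
  }
  ratio <- apply(est, 2, sd) / colMeans(se)
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("singlet estimates carry 95% intervals and back-transformed viabilities", {
  pairs <- full_pair_grid(3)
  pairs$w <- c(0.3, 0.4, 0.5)
  fit <- solve_singlets(build_design(make_assay(pairs)))
  est <- singlet_estimates(fit)
  expect_equal(est$ci_lo, est$w_hat - 1.96 * est$se)
  expect_equal(est$ci_hi, est$w_hat + 1.96 * est$se)
  expect_equal(est$v_hat, 10^(-est$w_hat))
})

test_that("tidy, glance and augment expose the fit as tibbles", {
  pairs <- full_pair_grid(5)
  set.seed(1)
  pairs$w <- rnorm(nrow(pairs), 0.5, 0.1)
  fit <- solve_singlets(build_design(make_assay(pairs)))
  td <- tidy(fit)
  gl <- glance(fit)
  au <- augment(fit)
  expect_equal(nrow(td), 5)
  expect_named(gl, c("cell_line", "dose_level", "m", "n", "df_residual",
                     "r_squared", "sigma2_model"))
  expect_equal(nrow(au), 10)
  expect_equal(sum((au$w_obs - au$fitted)^2) / gl$df_residual,
               gl$sigma2_model)
  # RSS/TSS identity behind the R^2 report
  expect_equal(sum(au$residual^2),
               (1 - gl$r_squared) * sum((au$w_obs - mean(au$w_obs))^2))
})
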