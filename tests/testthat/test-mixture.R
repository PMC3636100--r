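test_that("two-groups EM log-likelihood is monotone and beats the truth", {
  set.seed(41)
  n <- 2e4
  lab <- runif(n) < 0.97
  z <- ifelse(lab, rnorm(n), rnorm(n, 0, sqrt(1 + 3)))
  fit <- fit_two_groups(z, n_restarts = 2, seed = 1, tol = 1e-9)
  expect_false(is.unsorted(fit$loglik_trace))
  expect_gte(fit$loglik, two_groups_loglik(z, 0.97, 1, 3))
  expect_equal(fit$pi0, 0.97, tolerance = 0.02)
})

test_that("pure-null z-scores give a boundary or near-unity pi0 fit", {
  set.seed(42)
  z <- rnorm(2e4)
  fit <- fit_two_groups(z, n_restarts = 2, seed = 2)
  expect_true(fit$boundary || fit$pi0 >= 0.99)
})

test_that("local fdr follows the density ratio, symmetric and monotone", {
  fit <- condfdr:::new_two_groups_fit(0.99, 1, 3, NA_real_, 0L, FALSE)
  # direct density arithmetic oracle
  expected0 <- 0.99 * dnorm(0, 0, 1) /
    (0.99 * dnorm(0, 0, 1) + 0.01 * dnorm(0, 0, 2))
  expect_equal(local_fdr(0, fit), expected0)
  z <- seq(-6, 6, by = 0.01)
  expect_equal(local_fdr(z, fit), local_fdr(-z, fit))
  up <- local_fdr(seq(0, 8, by = 0.01), fit)
  expect_true(all(diff(up) <= 1e-12))
  expect_true(all(up > 0 & up <= 1))
  # pi0 = 1: local fdr is identically 1
  null_fit <- condfdr:::new_two_groups_fit(1, 1, 0, NA_real_, 0L, TRUE)
  expect_equal(local_fdr(c(-3, 0, 5), null_fit), rep(1, 3))
})

test_that("fdr cut-points bisect to the grid-scan answer and nest", {
  fit <- condfdr:::new_two_groups_fit(0.99, 1, 4, NA_real_, 0L, FALSE)
  expect_equal(fdr_cutpoint(fit, level = 1), 0)
  c05 <- fdr_cutpoint(fit, 0.05)
  c01 <- fdr_cutpoint(fit, 0.01)
  expect_gte(c01, c05)
  # brute-force grid scan oracle at resolution 1e-4
  zg <- seq(0, 20, by = 1e-4)
  scan <- zg[which(local_fdr(zg, fit) <= 0.05)[1]]
  expect_equal(c05, scan, tolerance = 2e-4)
  # unattainable level is reported as +Inf with a flag
  weak <- condfdr:::new_two_groups_fit(0.5, 1, 0, NA_real_, 0L, TRUE)
  out <- fdr_cutpoint(weak, 0.05)
  expect_true(is.infinite(out))
  expect_true(attr(out, "unattainable"))
})

test_that("effective-n scaling composes and boosts sub-threshold signal", {
  fit <- condfdr:::new_two_groups_fit(0.99, 1, 1.5, NA_real_, 0L, FALSE)
  expect_equal(scale_effective_n(fit, 1)$sigma1_sq, fit$sigma1_sq)
  twice <- scale_effective_n(scale_effective_n(fit, 2), 2)
  expect_equal(twice$sigma1_sq, scale_effective_n(fit, 4)$sigma1_sq)
  # Monte-Carlo: doubling effective n multiplies passing non-null SNPs
  set.seed(43)
  n_nonnull <- 2e5
  base_cut <- fdr_cutpoint(fit, 0.05)
  dbl <- scale_effective_n(fit, 2)
  dbl_cut <- fdr_cutpoint(dbl, 0.05)
  z_base <- rnorm(n_nonnull, 0, sqrt(1 + fit$sigma1_sq))
  z_dbl <- rnorm(n_nonnull, 0, sqrt(1 + dbl$sigma1_sq))
  pass_base <- sum(abs(z_base) >= base_cut)
  pass_dbl <- sum(abs(z_dbl) >= dbl_cut)
  expect_gte(pass_dbl, 10 * max(pass_base, 1))
})

test_that("mixture densities integrate to one", {
  fit <- condfdr:::new_two_groups_fit(0.95, 1.1, 2.5, NA_real_, 0L, FALSE)
  f <- function(z) {
    fit$pi0 * dnorm(z, 0, sqrt(fit$sigma0_sq)) +
      (1 - fit$pi0) * dnorm(z, 0, sqrt(fit$sigma0_sq + fit$sigma1_sq))
  }
  expect_equal(integrate(f, -Inf, Inf, abs.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  fit4 <- condfdr:::new_four_groups_fit(
    c(0.9, 0.04, 0.04, 0.02), c(1, 1.2), c(2, 3), 0.5, NA_real_, 0L, FALSE)
  zg <- seq(-15, 15, by = 0.05)
  grid <- expand.grid(z1 = zg, z2 = zg)
  dens <- 0
  for (k in 1:4) {
    dens <- dens + fit4$pi[k] *
      exp(condfdr:::bvn_logdens(grid$z1, grid$z2, fit4$sigmas[[k]]))
  }
  expect_equal(sum(dens) * 0.05^2, 1, tolerance = 1e-6)
})

test_that("four-groups EM on independent null traits finds almost no signal", {
  set.seed(44)
  n <- 2e4
  z1 <- rnorm(n); z2 <- rnorm(n)
  fit <- fit_four_groups(z1, z2, n_restarts = 2, seed = 3, max_iter = 300)
  expect_lte(sum(fit$pi[2:4]), 0.01)
  expect_false(is.unsorted(fit$loglik_trace))
})

test_that("four-groups EM recovers a pleiotropic scenario at moderate n", {
  prm <- simulation_params(n_snps = 5e4, pi = c(0.95, 0.01, 0.01, 0.03),
                           sigma1_sq = c(4, 4), rho3 = 0.3, seed = 45)
  sim <- simulate_pair(prm)
  fit <- fit_four_groups(sim$trait1$z, sim$trait2$z,
                         init = list(pi = c(0.9, 0.03, 0.03, 0.04),
                                     sigma0_sq = c(1, 1),
                                     sigma1_sq = c(3, 3), rho3 = 0),
                         n_restarts = 1, seed = 4)
  truth_ll <- four_groups_loglik(sim$trait1$z, sim$trait2$z,
                                 c(0.95, 0.01, 0.01, 0.03), c(1, 1),
                                 c(4, 4), 0.3)
  expect_gte(fit$loglik, truth_ll)
  expect_lt(abs(fit$pi[4] - 0.03), 0.01)
  expect_false(is.unsorted(fit$loglik_trace))
})

test_that("conditional local fdr reduces correctly in limiting cases", {
  # trait 1 entirely null: pi1 = pi3 = 0 forces conditional fdr 1
  fit_null1 <- condfdr:::new_four_groups_fit(
    c(0.9, 0, 0.1, 0), c(1, 1), c(2, 2), 0, NA_real_, 0L, FALSE)
  expect_equal(conditional_local_fdr(c(0, 2, 5), c(1, 1, 1), fit_null1),
               rep(1, 3))
  # no pleiotropic/cross component: z2 is uninformative, matches univariate
  fit_ind <- condfdr:::new_four_groups_fit(
    c(0.95, 0.05, 0, 0), c(1, 1), c(3, 0), 0, NA_real_, 0L, FALSE)
  z1 <- seq(-4, 4, by = 0.5)
  uni <- local_fdr(z1, marginal_two_groups(fit_ind, 1))
  for (z2 in c(-2, 0, 3)) {
    expect_equal(conditional_local_fdr(z1, rep(z2, length(z1)), fit_ind),
                 uni, tolerance = 1e-10)
  }
  # with shared non-nullness, larger |z2| lowers the fdr at fixed z1
  fit_pleio <- condfdr:::new_four_groups_fit(
    c(0.95, 0.01, 0.01, 0.03), c(1, 1), c(3, 3), 0, NA_real_, 0L, FALSE)
  z2g <- seq(0, 10, by = 0.05)
  vals <- conditional_local_fdr(rep(2, length(z2g)), z2g, fit_pleio)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("power curves reach 1 and conditioning helps iff pleiotropy", {
  fit_pleio <- condfdr:::new_four_groups_fit(
    c(0.95, 0.005, 0.005, 0.04), c(1, 1), c(3, 3), 0, NA_real_, 0L, FALSE)
  lv <- c(0.01, 0.05, 0.1, 0.25, 0.5, 1)
  un <- power_curve(fit_pleio, "unconditional", levels = lv)
  co <- power_curve(fit_pleio, "conditional", levels = lv)
  expect_equal(un$sensitivity[lv == 1], 1, tolerance = 1e-6)
  expect_equal(co$sensitivity[lv == 1], 1, tolerance = 1e-6)
  expect_true(all(co$sensitivity >= un$sensitivity - 1e-6))
  expect_gt(co$sensitivity[lv == 0.05], un$sensitivity[lv == 0.05])
  # no pleiotropy and independent components: no conditional gain
  fit_ind <- condfdr:::new_four_groups_fit(
    c(0.94, 0.03, 0.03, 0), c(1, 1), c(3, 3), 0, NA_real_, 0L, FALSE)
  un0 <- power_curve(fit_ind, "unconditional", levels = lv)
  co0 <- power_curve(fit_ind, "conditional", levels = lv)
  expect_equal(co0$sensitivity, un0$sensitivity, tolerance = 0.02)
})
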