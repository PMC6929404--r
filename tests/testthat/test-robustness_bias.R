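test_that("leave-one-out is exchangeable and sized correctly", {
  same <- mk_effects(rep(0.2, 4), rep(0.1, 4))
  rows <- leave_one_out(same)
  expect_equal(nrow(rows), 4)
  expect_equal(length(unique(rows$or)), 1)
  expect_equal(length(unique(rows$q)), 1)
  expect_true(all(rows$k == 3))
  expect_error(leave_one_out(mk_effects(c(0, 1), c(1, 1))),
               class = "metasnp_insufficient_studies")

  st <- roster_fixture()
  eff <- build_effects(st, "additive")
  loo <- leave_one_out(eff)
  expect_equal(nrow(loo), 37)
  expect_equal(loo$excluded_label, eff$label)
  expect_true(all(loo$het_df == 35))
})

test_that("removing the largest outlier never increases Q", {
  withr::local_seed(31)
  for (r in 1:30) {
    k <- sample(4:12, 1)
    eff <- mk_effects(rnorm(k, 0, 0.6), runif(k, 0.05, 0.5))
    w <- 1 / eff$se^2
    theta_hat <- sum(w * eff$ln_or) / sum(w)
    worst <- which.max(abs(eff$ln_or - theta_hat))
    q_full <- cochran_q(eff)$q
    q_drop <- cochran_q(eff[-worst, ])$q
    expect_lte(q_drop, q_full + 1e-12)
  }
})

test_that("Egger regression matches an independent least-squares fit", {
  eff <- mk_effects(c(0.2, 0.3, 0.1, 0.4), c(0.1, 0.2, 0.15, 0.3))
  res <- egger_test(eff)
  fit <- summary(lm(I(eff$ln_or / eff$se) ~ I(1 / eff$se)))$coefficients
  expect_equal(res$statistic, fit[1, 1])
  expect_equal(res$se, fit[1, 2])
  expect_equal(res$t_or_z, fit[1, 3])
  expect_equal(res$p, fit[1, 4])
  expect_equal(res$df, 2L)

  withr::local_seed(17)
  for (r in 1:20) {
    k <- sample(4:20, 1)
    eff <- mk_effects(rnorm(k, 0.2, 0.3), runif(k, 0.05, 0.5))
    res <- egger_test(eff)
    fit <- summary(lm(I(eff$ln_or / eff$se) ~ I(1 / eff$se)))$coefficients
    expect_equal(res$statistic, fit[1, 1], tolerance = 1e-10)
    expect_equal(res$p, fit[1, 4], tolerance = 1e-10)
  }
})

test_that("Egger handles the constructed null and the singular case", {
  # equal effects with varying precision lie exactly on a line through the
  # origin in (precision, snd) space: no asymmetry evidence
  eff <- mk_effects(rep(0.3, 5), c(0.1, 0.15, 0.2, 0.3, 0.4))
  res <- egger_test(eff)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  expect_error(egger_test(mk_effects(c(0.1, 0.1, 0.1), rep(0.2, 3))),
               class = "metasnp_degenerate_error")
})

test_that("Begg's statistic reproduces the exact Kendall construction", {
  # perfectly concordant deviates and variances
  eff <- mk_effects(c(0.05, 0.3, 0.8, 1.8), c(0.05, 0.1, 0.2, 0.4))
  res <- begg_test(eff)
  w <- 1 / eff$se^2
  theta_hat <- sum(w * eff$ln_or) / sum(w)
  v <- eff$se^2 - 1 / sum(w)
  t_i <- (eff$ln_or - theta_hat) / sqrt(v)
  expect_equal(res$statistic, cor(t_i, v, method = "kendall"))

  withr::local_seed(41)
  for (r in 1:20) {
    k <- sample(4:15, 1)
    eff <- mk_effects(rnorm(k, 0, 0.4), runif(k, 0.05, 0.5))
    res <- begg_test(eff)
    w <- 1 / eff$se^2
    theta_hat <- sum(w * eff$ln_or) / sum(w)
    v <- eff$se^2 - 1 / sum(w)
    t_i <- (eff$ln_or - theta_hat) / sqrt(v)
    tau <- cor(t_i, v, method = "kendall")
    expect_equal(res$statistic, tau, tolerance = 1e-12)
    # z from the exact variance of Kendall's S with continuity correction
    s <- tau * k * (k - 1) / 2
    z <- sign(s) * (abs(s) - 1) / sqrt(k * (k - 1) * (2 * k + 5) / 18)
    expect_equal(res$t_or_z, z, tolerance = 1e-10)
    expect_equal(res$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  }
})

test_that("a four-study set with S = -2 gives tau = -1/3 and the exact z", {
  # ranks of deviates vs variances chosen so 2 of 6 pairs are concordant
  k <- 4
  var_s <- k * (k - 1) * (2 * k + 5) / 18
  z_expected <- -(2 - 1) / sqrt(var_s)
  found <- FALSE
  withr::local_seed(53)
  for (try in 1:500) {
    eff <- mk_effects(rnorm(k, 0, 0.5), runif(k, 0.05, 0.5))
    res <- begg_test(eff)
    if (isTRUE(all.equal(res$statistic, -1 / 3))) {
      expect_equal(res$t_or_z, z_expected)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("Kendall tau is invariant under monotone transforms", {
  withr::local_seed(61)
  x <- rnorm(12)
  y <- rnorm(12)
  base <- metasnp:::kendall_s(x, y)
  for (f in list(function(z) exp(z), function(z) z^3,
                 function(z) rank(z))) {
    tr <- metasnp:::kendall_s(x, f(y))
    expect_equal(tr$tau, base$tau)
    expect_equal(tr$s, base$s)
  }
})

test_that("bias tests agree with reference implementations on the roster", {
  skip_if_not_installed("metafor")
  eff <- build_effects(roster_fixture(), "additive")
  ref <- metafor::rma(yi = eff$ln_or, sei = eff$se, method = "FE")
  reg <- metafor::regtest(ref, model = "lm")
  res <- egger_test(eff)
  expect_equal(res$t_or_z, as.numeric(reg$zval), tolerance = 1e-6)
  expect_equal(res$p, reg$pval, tolerance = 1e-6)
  rk <- metafor::ranktest(ref)
  expect_equal(begg_test(eff)$statistic, as.numeric(rk$tau),
               tolerance = 1e-10)
})

test_that("funnel coordinates are centred and widen monotonically", {
  eff <- build_effects(roster_fixture(), "additive")
  pooled <- pool_random_dl(eff)
  fd <- funnel_data(eff, pooled)
  expect_equal(nrow(fd), 37)
  expect_true(all(fd$center == pooled$ln_or))
  o <- order(fd$se)
  expect_true(all(diff((fd$funnel_high - fd$funnel_low)[o]) >= 0))

  # a symmetric pair around the pooled value mirrors exactly
  pair <- mk_effects(c(0.1 - 0.05, 0.1 + 0.05), c(0.2, 0.2))
  pfit <- pool_fixed_iv(pair)
  pfd <- funnel_data(pair, pfit)
  expect_equal(pfd$ln_or[1] - pfd$center[1], -(pfd$ln_or[2] - pfd$center[2]))

  single <- mk_effects(pfit$ln_or, 0.3)
  sfd <- funnel_data(single, pfit)
  expect_equal(sfd$ln_or, sfd$center)
})
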