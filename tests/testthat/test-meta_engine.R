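test_that("cochran_q matches hand arithmetic and boundary cases", {
  same <- mk_effects(c(0.4, 0.4), c(0.2, 0.2))
  h <- cochran_q(same)
  expect_equal(h$q, 0)
  expect_equal(h$p, 1)
  expect_equal(h$i_squared, 0)

  two <- mk_effects(c(0, 2), c(1, 1))
  h2 <- cochran_q(two)
  expect_equal(h2$q, 2)
  expect_equal(h2$df, 1L)
  expect_equal(h2$p, pchisq(2, 1, lower.tail = FALSE)) # 0.15729...
  expect_error(cochran_q(mk_effects(0.1, 0.1)),
               class = "metasnp_insufficient_studies")
})

test_that("i_squared follows the printed formula with clamping", {
  expect_equal(i_squared(10, 11), 0)
  for (k in c(2, 5, 11, 37)) {
    expect_equal(i_squared(2 * (k - 1), k), 50)
  }
  expect_equal(i_squared(28.653, 11), 65.1, tolerance = 5e-4)
  expect_equal(i_squared(0, 5), 0)
  withr::local_seed(3)
  q <- runif(100, 0, 50)
  k <- sample(2:20, 100, replace = TRUE)
  i2 <- i_squared(q, k)
  expect_true(all(i2 >= 0 & i2 <= 100))
  expect_error(i_squared(5, 1), class = "metasnp_validation_error")
})

test_that("Q and I2 agree with an independent brute-force oracle", {
  withr::local_seed(99)
  for (r in 1:1000) {
    k <- sample(2:8, 1)
    y <- rnorm(k)
    s <- runif(k, 0.05, 1)
    h <- cochran_q(mk_effects(y, s))
    q_oracle <- pairwise_q(y, s)
    expect_equal(h$q, q_oracle, tolerance = 1e-10)
    expect_equal(h$i_squared, max(0, (q_oracle - (k - 1)) / q_oracle) * 100,
                 tolerance = 1e-8)
  }
})

test_that("inverse-variance fixed pooling has the stated arithmetic", {
  one <- mk_effects(0.25, 0.11)
  f1 <- pool_fixed_iv(one)
  expect_equal(f1$ln_or, 0.25)
  expect_equal(f1$se, 0.11)

  eq <- mk_effects(c(0.1, 0.3), c(0.1, 0.1))
  f2 <- pool_fixed_iv(eq)
  expect_equal(f2$ln_or, 0.2)
  expect_equal(f2$se, 0.1 / sqrt(2))

  withr::local_seed(5)
  eff <- mk_effects(rnorm(6), runif(6, 0.1, 0.5))
  expect_lt(pool_fixed_iv(eff)$se, min(eff$se))
  expect_equal(sum(pool_fixed_iv(eff)$weights), 1, tolerance = 1e-12)
})

test_that("Mantel-Haenszel pooling matches hand arithmetic", {
  t1 <- tibble::tibble(a = 40, b = 40, c = 40, d = 40)
  expect_equal(pool_fixed_mh(t1)$or, 1)

  tab <- tibble::tibble(a = 12, b = 5, c = 4, d = 9)
  rep2 <- dplyr::bind_rows(tab, tab)
  expect_equal(pool_fixed_mh(rep2)$or, with(tab, a * d / (b * c)))

  pair <- tibble::tibble(a = c(10, 6), b = c(5, 6), c = c(4, 3),
                         d = c(8, 9))
  or_hand <- (10 * 8 / 27 + 6 * 9 / 24) / (5 * 4 / 27 + 6 * 3 / 24)
  expect_equal(pool_fixed_mh(pair)$or, or_hand) # 3.4970
  expect_error(pool_fixed_mh(tibble::tibble(a = 0, b = 0, c = 0, d = 5)),
               class = "metasnp_degenerate_error")
})

test_that("MH and IV agree on large homogeneous tables", {
  withr::local_seed(8)
  for (r in 1:20) {
    k <- sample(3:8, 1)
    base <- runif(4, 50, 500)
    tabs <- dplyr::bind_rows(lapply(1:k, function(i) {
      m <- runif(1, 0.8, 1.2)
      tibble::tibble(a = base[1] * m, b = base[2] * m, c = base[3] * m,
                     d = base[4] * m)
    }))
    mh <- pool_fixed_mh(tabs)
    iv <- pool_fixed_iv(mh$effects)
    expect_equal(mh$or, iv$or, tolerance = 0.02)
    expect_equal(mh$se, iv$se, tolerance = 0.02)
  }
})

test_that("DL random effects collapses to fixed when Q <= df", {
  eff <- mk_effects(c(0.10, 0.12, 0.11), c(0.3, 0.25, 0.28))
  dl <- pool_random_dl(eff)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$ln_or, pool_fixed_iv(eff)$ln_or)
  expect_equal(dl$se, pool_fixed_iv(eff)$se)
})

test_that("random-effects pooling is never more precise than fixed", {
  withr::local_seed(21)
  for (r in 1:50) {
    k <- sample(3:15, 1)
    eff <- mk_effects(rnorm(k, 0, 0.5), runif(k, 0.05, 0.6))
    dl <- pool_random_dl(eff)
    fe <- pool_fixed_iv(eff)
    expect_gte(dl$se, fe$se)
    if (dl$tau2 == 0) expect_equal(dl$se, fe$se)
    # permutation invariance
    perm <- sample(k)
    expect_equal(pool_random_dl(eff[perm, ])$ln_or, dl$ln_or)
    expect_equal(pool_random_dl(eff[perm, ])$tau2, dl$tau2)
  }
})

test_that("DL pooling agrees with an independent reference implementation", {
  skip_if_not_installed("metafor")
  withr::local_seed(13)
  for (r in 1:25) {
    k <- sample(3:20, 1)
    eff <- mk_effects(rnorm(k, 0.1, 0.4), runif(k, 0.05, 0.5))
    dl <- pool_random_dl(eff)
    ref <- metafor::rma(yi = eff$ln_or, sei = eff$se, method = "DL")
    expect_equal(dl$ln_or, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(dl$se, ref$se, tolerance = 1e-10)
    expect_equal(dl$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(dl$het$q, ref$QE, tolerance = 1e-10)
    expect_equal(dl$het$i_squared, ref$I2, tolerance = 1e-6)
  }
})

test_that("z_test matches the normal-tail oracle", {
  z0 <- z_test(0, 0.2)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  expect_equal(z_test(1.959964 * 0.1, 0.1)$p, 0.05, tolerance = 1e-6)
  zt <- z_test(0.11333, 0.02272)
  expect_equal(zt$z, 4.988, tolerance = 1e-3)
  expect_equal(zt$p, 6.1e-7, tolerance = 0.02)
})

test_that("the model-selection rule joins both thresholds with AND", {
  expect_equal(select_model(tibble::tibble(p = 0.001, i_squared = 65.1)),
               "random_dl")
  expect_equal(select_model(tibble::tibble(p = 0.5, i_squared = 0)),
               "fixed")
  expect_message(
    m <- select_model(tibble::tibble(p = 0.01, i_squared = 40)),
    "disagree"
  )
  expect_equal(m, "fixed")
})

test_that("subgroup analysis degenerates correctly", {
  st <- roster_fixture()
  ea <- st[st$group == "east_asian", ]
  sub <- subgroup_meta(ea)
  expect_equal(nrow(sub), 2) # the single group and "all"
  expect_equal(sub$or[sub$group == "east_asian"],
               sub$or[sub$group == "all"])

  # mirrored groups return identical results
  twin <- dplyr::bind_rows(
    dplyr::mutate(ea, group = "g1"),
    dplyr::mutate(ea, group = "g2")
  )
  subtwin <- subgroup_meta(twin)
  expect_equal(subtwin$or[subtwin$group == "g1"],
               subtwin$or[subtwin$group == "g2"])
  expect_equal(subtwin$q[subtwin$group == "g1"],
               subtwin$q[subtwin$group == "g2"])
})

test_that("tidy and glance expose the fit components", {
  st <- roster_fixture()
  fit <- pool_random_dl(build_effects(st, "additive"))
  td <- tidy(fit)
  expect_equal(nrow(td), 37)
  expect_equal(sum(td$weight), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$or, exp(gl$ln_or))
  expect_equal(gl$ci_low, exp(gl$ln_or - 1.959964 * gl$se))
  expect_equal(gl$model, "random_dl")
})
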