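#' Leave-one-out sensitivity analysis
#'
#' Re-runs heterogeneity testing and random-effects pooling `k` times, each
#' time omitting one study (tau-squared re-estimated on every subset), to
#' check that no single study drives the pooled estimate.
#'
#' @inheritParams cochran_q
#' @return A tibble with one row per excluded study, in input order:
#'   `excluded_label`, subset size `k`, `q`, `het_df`, `het_p`,
#'   `i_squared`, `tau2`, pooled `or` with 95% CI and meta `p`.
#' @export
leave_one_out <- function(effects) {
  k <- nrow(effects)
  if (k < 3) {
    abort("leave-one-out needs at least 3 studies",
          class = "metasnp_insufficient_studies")
  }
  purrr::map_dfr(seq_len(k), function(i) {
    fit <- pool_random_dl(effects[-i, ])
    tibble(
      excluded_label = effects$label[i], k = k - 1L,
      q = fit$het$q, het_df = fit$het$df, het_p = fit$het$p,
      i_squared = fit$het$i_squared, tau2 = fit$tau2,
      or = fit$or, ci_low = fit$ci_low, ci_high = fit$ci_high, p = fit$p
    )
  })
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Classic formulation: ordinary least squares of the standard normal
#' deviate `ln_or/se` on precision `1/se`; the intercept estimates the
#' asymmetry, tested against a Student t distribution with `k - 2` degrees
#' of freedom. `weighted = TRUE` switches to the weighted variant
#' (regression of `ln_or` on `se` with weights `1/se^2`).
#'
#' @inheritParams cochran_q
#' @param weighted Use the weighted-regression variant (default `FALSE`).
#' @return A one-row tibble: `method`, `statistic` (intercept), `se`,
#'   `t_or_z`, `df` and two-sided `p`.
#' @export
egger_test <- function(effects, weighted = FALSE) {
  k <- nrow(effects)
  if (k < 3) {
    abort("Egger's test needs at least 3 studies",
          class = "metasnp_insufficient_studies")
  }
  if (weighted) {
    wls <- 1 / effects$se^2
    x <- effects$se
    y <- effects$ln_or
  } else {
    wls <- rep(1, k)
    x <- 1 / effects$se
    y <- effects$ln_or / effects$se
  }
  sw <- sum(wls)
  xbar <- sum(wls * x) / sw
  ybar <- sum(wls * y) / sw
  sxx <- sum(wls * (x - xbar)^2)
  if (sxx == 0) {
    abort("singular fit: all precisions identical",
          class = "metasnp_degenerate_error")
  }
  slope <- sum(wls * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  s2 <- sum(wls * resid^2) / (k - 2)
  se_int <- sqrt(s2 * (1 / sw + xbar^2 / sxx))
  # an (numerically) exact linear fit through the origin carries no
  # asymmetry evidence; intercepts below noise level are treated as zero
  exact <- s2 <= .Machine$double.eps * sum(wls * y^2) / (k - 2)
  if (exact && abs(intercept) <= sqrt(.Machine$double.eps) *
        max(1, max(abs(y)))) {
    t_stat <- 0
    p <- 1
    intercept <- 0
  } else if (se_int == 0) {
    t_stat <- sign(intercept) * Inf
    p <- 0
  } else {
    t_stat <- intercept / se_int
    p <- 2 * pt(-abs(t_stat), df = k - 2)
  }
  tibble(method = "egger", statistic = intercept, se = se_int,
         t_or_z = t_stat, df = k - 2L, p = p)
}

#' Begg-Mazumdar rank-correlation test for funnel-plot asymmetry
#'
#' Standardises each effect against the fixed-effect mean using the
#' variance of the deviation, `v_i = se_i^2 - 1/sum(w)`, then measures the
#' Kendall correlation between the standardised deviates and `v_i`. The
#' normal deviate uses the exact variance of Kendall's S,
#' `k (k-1) (2k+5) / 18` (with the tie adjustment when ranks tie), and a
#' continuity correction.
#'
#' @inheritParams cochran_q
#' @return A one-row tibble: `method`, `statistic` (Kendall tau), `se` of
#'   S, `t_or_z`, `df` (`NA`) and two-sided `p`.
#' @export
begg_test <- function(effects) {
  k <- nrow(effects)
  if (k < 3) {
    abort("Begg's test needs at least 3 studies",
          class = "metasnp_insufficient_studies")
  }
  w <- 1 / effects$se^2
  theta_hat <- sum(w * effects$ln_or) / sum(w)
  v <- effects$se^2 - 1 / sum(w)
  if (any(v <= 0)) {
    warn("non-positive deviation variance; falling back to v_i = se_i^2")
    v <- effects$se^2
  }
  t_i <- (effects$ln_or - theta_hat) / sqrt(v)
  kt <- kendall_s(t_i, v)
  z <- if (kt$s == 0) 0 else sign(kt$s) * (abs(kt$s) - 1) / sqrt(kt$var_s)
  tibble(method = "begg", statistic = kt$tau, se = sqrt(kt$var_s),
         t_or_z = z, df = NA_integer_, p = 2 * pnorm(-abs(z)))
}

# Kendall S = concordant - discordant pairs, its tie-adjusted variance, and
# tau (tau-b when ties are present).
kendall_s <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(x[(i + 1):n] - x[i]) * sign(y[(i + 1):n] - y[i]))
  }
  tie_term <- function(z) {
    t <- table(z)
    t <- t[t > 1]
    c(v = sum(t * (t - 1) * (2 * t + 5)),
      p1 = sum(t * (t - 1)), p2 = sum(t * (t - 1) * (t - 2)))
  }
  tx <- tie_term(x)
  ty <- tie_term(y)
  if (tx[["p1"]] > 0 || ty[["p1"]] > 0) {
    inform("ties present; using the tie-adjusted Kendall variance")
  }
  var_s <- (n * (n - 1) * (2 * n + 5) - tx[["v"]] - ty[["v"]]) / 18 +
    tx[["p2"]] * ty[["p2"]] / (9 * n * (n - 1) * (n - 2)) +
    tx[["p1"]] * ty[["p1"]] / (2 * n * (n - 1))
  n0 <- n * (n - 1) / 2
  tau <- s / sqrt((n0 - tx[["p1"]] / 2) * (n0 - ty[["p1"]] / 2))
  list(s = s, var_s = var_s, tau = tau)
}

#' Funnel-plot coordinates
#'
#' Per-study points (`ln_or`, `se`) plus the pseudo 95% confidence funnel
#' centred on the pooled estimate: at each study's standard error the
#' bounds are `pooled ln_or -/+ 1.959964 * se`. Plotted with the standard
#' error axis reversed (largest at the bottom), the bounds form the
#' familiar inverted funnel.
#'
#' @inheritParams cochran_q
#' @param pooled A `meta_pool` object giving the funnel centre.
#' @return A tibble with `label`, `ln_or`, `se`, `center`, `funnel_low`,
#'   `funnel_high`.
#' @export
funnel_data <- function(effects, pooled) {
  tibble(
    label = effects$label,
    ln_or = effects$ln_or,
    se = effects$se,
    center = pooled$ln_or,
    funnel_low = pooled$ln_or - Z975 * effects$se,
    funnel_high = pooled$ln_or + Z975 * effects$se
  )
}
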