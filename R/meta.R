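#' Cochran's Q heterogeneity test
#'
#' With inverse-variance weights `w_i = 1/se_i^2` and the fixed-effect mean
#' `theta_hat = sum(w * theta) / sum(w)`,
#' `Q = sum(w * (theta - theta_hat)^2)`, referred to a chi-square
#' distribution with `k - 1` degrees of freedom.
#'
#' @param effects A tibble of effect estimates with columns `ln_or` and
#'   `se` (see [build_effects()]).
#' @return A one-row tibble with `q`, `df`, `p` and `i_squared`.
#' @export
cochran_q <- function(effects) {
  k <- nrow(effects)
  if (k < 2) {
    abort("heterogeneity testing needs at least 2 studies",
          class = "metasnp_insufficient_studies")
  }
  w <- 1 / effects$se^2
  theta_hat <- sum(w * effects$ln_or) / sum(w)
  q <- sum(w * (effects$ln_or - theta_hat)^2)
  tibble(
    q = q, df = k - 1L,
    p = pchisq(q, df = k - 1, lower.tail = FALSE),
    i_squared = i_squared(q, k)
  )
}

#' I-squared heterogeneity statistic
#'
#' `I^2 = (Q - (k - 1)) / Q * 100`, clamped to zero whenever `Q <= k - 1`
#' (and by convention when `Q = 0`): the percentage of total variation in
#' study effects attributable to between-study heterogeneity.
#'
#' @param q Cochran's Q statistic (>= 0).
#' @param k Number of studies (>= 2).
#' @return A percentage in \[0, 100\].
#' @export
i_squared <- function(q, k) {
  if (any(k < 2) || any(q < 0)) {
    abort("i_squared needs q >= 0 and k >= 2",
          class = "metasnp_validation_error")
  }
  ifelse(q <= 0, 0, pmax(0, (q - (k - 1)) / q) * 100)
}

#' Z test for a pooled log odds ratio
#'
#' @param ln_or Log odds ratio.
#' @param se Its standard error (> 0).
#' @return A tibble with `z = ln_or / se` and the two-sided normal `p`.
#' @export
z_test <- function(ln_or, se) {
  if (any(se <= 0)) {
    abort("se must be positive", class = "metasnp_validation_error")
  }
  z <- ln_or / se
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

new_meta_pool <- function(model, effects, ln_or, se, tau2, weights, het) {
  zt <- z_test(ln_or, se)
  structure(
    list(
      model = model, k = nrow(effects),
      ln_or = ln_or, se = se,
      or = exp(ln_or),
      ci_low = exp(ln_or - Z975 * se),
      ci_high = exp(ln_or + Z975 * se),
      z = zt$z, p = zt$p, tau2 = tau2,
      weights = weights / sum(weights),
      effects = effects, het = het
    ),
    class = "meta_pool"
  )
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Pools log odds ratios with weights `w_i = 1/se_i^2`; the pooled standard
#' error is `1/sqrt(sum(w))`.
#'
#' @inheritParams cochran_q
#' @return A `meta_pool` object; see [glance.meta_pool()] and
#'   [tidy.meta_pool()].
#' @export
pool_fixed_iv <- function(effects) {
  if (nrow(effects) < 1) {
    abort("pooling needs at least 1 study",
          class = "metasnp_insufficient_studies")
  }
  w <- 1 / effects$se^2
  het <- if (nrow(effects) >= 2) cochran_q(effects) else NULL
  new_meta_pool(
    "fixed_iv", effects,
    ln_or = sum(w * effects$ln_or) / sum(w),
    se = 1 / sqrt(sum(w)),
    tau2 = 0, weights = w, het = het
  )
}

#' Mantel-Haenszel fixed-effect pooling of 2x2 tables
#'
#' `OR_MH = sum(a*d/T) / sum(b*c/T)` over tables with totals `T`; the
#' variance of `log(OR_MH)` uses the Robins-Breslow-Greenland estimator.
#' Heterogeneity is assessed on the per-table Woolf log odds ratios.
#'
#' @param tables A tibble of 2x2 tables, one row per study, with columns
#'   `a`, `b`, `c`, `d` (see [contrast_table()]) and optionally `label`,
#'   `group`.
#' @param correction Continuity correction for the per-table effects used
#'   in the heterogeneity test (the MH estimate itself uses raw cells).
#' @return A `meta_pool` object.
#' @export
pool_fixed_mh <- function(tables, correction = 0.5) {
  k <- nrow(tables)
  if (k < 1) {
    abort("pooling needs at least 1 study",
          class = "metasnp_insufficient_studies")
  }
  a <- tables$a; b <- tables$b; cc <- tables$c; d <- tables$d
  tt <- a + b + cc + d
  if (all(a * d == 0) && all(b * cc == 0)) {
    abort("all tables are degenerate", class = "metasnp_degenerate_error")
  }
  R <- a * d / tt
  S <- b * cc / tt
  P <- (a + d) / tt
  Q <- (b + cc) / tt
  sumR <- sum(R); sumS <- sum(S)
  var_ln <- sum(P * R) / (2 * sumR^2) +
    sum(P * S + Q * R) / (2 * sumR * sumS) +
    sum(Q * S) / (2 * sumS^2)
  lab <- if ("label" %in% names(tables)) tables$label else
    rep(NA_character_, k)
  grp <- if ("group" %in% names(tables)) tables$group else
    rep(NA_character_, k)
  effects <- dplyr::bind_rows(purrr::map(seq_len(k), function(i) {
    effect_from_table(tables[i, ], correction,
                      label = lab[i], group = grp[i])
  }))
  het <- if (k >= 2) cochran_q(effects) else NULL
  new_meta_pool(
    "fixed_mh", effects,
    ln_or = log(sumR / sumS),
    se = sqrt(var_ln),
    tau2 = 0, weights = S, het = het
  )
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w_i = 1/se_i^2`, then re-weighting by
#' `w*_i = 1/(se_i^2 + tau2)`. When `Q <= k - 1` the estimate collapses to
#' the inverse-variance fixed-effect result.
#'
#' @inheritParams cochran_q
#' @return A `meta_pool` object.
#' @export
pool_random_dl <- function(effects) {
  if (nrow(effects) < 2) {
    abort("random-effects pooling needs at least 2 studies",
          class = "metasnp_insufficient_studies")
  }
  het <- cochran_q(effects)
  w <- 1 / effects$se^2
  tau2 <- max(0, (het$q - het$df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (effects$se^2 + tau2)
  new_meta_pool(
    "random_dl", effects,
    ln_or = sum(ws * effects$ln_or) / sum(ws),
    se = 1 / sqrt(sum(ws)),
    tau2 = tau2, weights = ws, het = het
  )
}

#' Heterogeneity-driven model selection
#'
#' Selects the random-effects model when the Q-test p-value falls below
#' `p_threshold` AND I-squared exceeds `i2_threshold`, otherwise the
#' fixed-effect model. When only one indicator fires, the two heterogeneity
#' flags disagree; a message notes the discordance (some practitioners
#' declare heterogeneity on either indicator alone).
#'
#' @param het A heterogeneity result from [cochran_q()].
#' @param p_threshold,i2_threshold Decision thresholds (defaults 0.05 and
#'   50).
#' @return `"random_dl"` or `"fixed"`.
#' @export
select_model <- function(het, p_threshold = 0.05, i2_threshold = 50) {
  sig_p <- het$p < p_threshold
  sig_i2 <- het$i_squared > i2_threshold
  if (xor(sig_p, sig_i2)) {
    inform(sprintf(
      "heterogeneity indicators disagree (p = %.3g, I2 = %.1f%%); pooling with the fixed-effect model under the AND rule",
      het$p, het$i_squared
    ))
  }
  if (sig_p && sig_i2) "random_dl" else "fixed"
}

#' Meta-analysis of an effect set with automatic model choice
#'
#' Runs [cochran_q()], applies [select_model()] and pools with
#' [pool_random_dl()] or [pool_fixed_iv()] accordingly. With `model`
#' other than `"auto"` the stated model is forced.
#'
#' @inheritParams cochran_q
#' @param model `"auto"`, `"fixed_iv"` or `"random_dl"`.
#' @inheritParams select_model
#' @return A `meta_pool` object.
#' @export
meta_analyze <- function(effects, model = c("auto", "fixed_iv", "random_dl"),
                         p_threshold = 0.05, i2_threshold = 50) {
  model <- match.arg(model)
  if (model == "auto") {
    het <- cochran_q(effects)
    model <- if (select_model(het, p_threshold, i2_threshold) == "random_dl")
      "random_dl" else "fixed_iv"
  }
  switch(model,
    fixed_iv  = pool_fixed_iv(effects),
    random_dl = pool_random_dl(effects)
  )
}

#' Subgroup meta-analysis
#'
#' Builds effects per genetic contrast, then pools within each level of the
#' grouping column (model chosen per group by [select_model()]) and across
#' all studies. Groups with fewer than two studies are reported with the
#' single-study estimate and no heterogeneity test.
#'
#' @inheritParams build_effects
#' @param group_col Name of the grouping column (default `"group"`).
#' @inheritParams select_model
#' @return A tibble with one row per group plus an `"all"` row: study count
#'   `k`, heterogeneity (`q`, `het_df`, `het_p`, `i_squared`), `tau2`, the
#'   model used, pooled `or` with 95% CI, `z` and `p`, and the fitted
#'   `meta_pool` object in the `fit` list-column.
#' @export
subgroup_meta <- function(studies,
                          model = c("additive", "dominant", "recessive"),
                          group_col = "group",
                          policy = c("genotype_first", "reconstruct_only",
                                     "genotype_only"),
                          maf_interpretation = c("combined", "control"),
                          p_threshold = 0.05, i2_threshold = 50,
                          correction = 0.5) {
  if (!group_col %in% names(studies)) {
    abort(paste0("grouping column '", group_col, "' not found"),
          class = "metasnp_schema_error")
  }
  studies$group <- studies[[group_col]]
  effects <- build_effects(studies, model, policy = policy,
                           maf_interpretation = maf_interpretation,
                           correction = correction)
  groups <- unique(effects$group)
  subsets <- c(setNames(purrr::map(groups, ~ effects[effects$group == .x, ]),
                        groups),
               list(all = effects))
  rows <- purrr::imap(subsets, function(eff, name) {
    if (nrow(eff) < 2) {
      warn(paste0("group '", name, "' has fewer than 2 studies; ",
                  "reporting the single-study estimate"))
      fit <- pool_fixed_iv(eff)
      het <- tibble(q = NA_real_, df = NA_integer_, p = NA_real_,
                    i_squared = NA_real_)
    } else {
      het <- cochran_q(eff)
      fit <- meta_analyze(eff, p_threshold = p_threshold,
                          i2_threshold = i2_threshold)
    }
    tibble(
      group = name, k = nrow(eff),
      q = het$q, het_df = het$df, het_p = het$p, i_squared = het$i_squared,
      tau2 = fit$tau2, model = fit$model,
      or = fit$or, ci_low = fit$ci_low, ci_high = fit$ci_high,
      z = fit$z, p = fit$p, fit = list(fit)
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf("Meta-analysis (%s) of %d studies\n", x$model, x$k))
  cat(sprintf("  OR %.4f (95%% CI %.4f-%.4f), Z = %.3f, p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$z, x$p))
  if (!is.null(x$het)) {
    cat(sprintf("  Q = %.3f (df = %d, p = %.3g), I2 = %.1f%%, tau2 = %.4g\n",
                x$het$q, x$het$df, x$het$p, x$het$i_squared, x$tau2))
  }
  invisible(x)
}

#' Per-study components of a pooled fit
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A tibble with one row per study: `label`, `group`, `ln_or`,
#'   `se`, `or`, the 95% CI and the normalised pooling `weight`.
#' @export
tidy.meta_pool <- function(x, ...) {
  tibble(
    label = x$effects$label, group = x$effects$group,
    ln_or = x$effects$ln_or, se = x$effects$se,
    or = exp(x$effects$ln_or),
    ci_low = exp(x$effects$ln_or - Z975 * x$effects$se),
    ci_high = exp(x$effects$ln_or + Z975 * x$effects$se),
    weight = x$weights
  )
}

#' One-row summary of a pooled fit
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A one-row tibble: model, `k`, pooled `or` with CI, `z`, `p`,
#'   `tau2` and the heterogeneity columns.
#' @export
glance.meta_pool <- function(x, ...) {
  tibble(
    model = x$model, k = x$k,
    ln_or = x$ln_or, se = x$se,
    or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
    z = x$z, p = x$p, tau2 = x$tau2,
    q = if (is.null(x$het)) NA_real_ else x$het$q,
    het_df = if (is.null(x$het)) NA_integer_ else x$het$df,
    het_p = if (is.null(x$het)) NA_real_ else x$het$p,
    i_squared = if (is.null(x$het)) NA_real_ else x$het$i_squared
  )
}
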