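# Shared fixtures and independent oracles used across the suite.

mk_effects <- function(ln_or, se, label = NULL, group = "g") {
  tibble::tibble(
    label = label %||% sprintf("s%02d", seq_along(ln_or)),
    group = group,
    ln_or = ln_or, se = se,
    source = "summary_ci", correction_applied = FALSE
  )
}

# Cochran's Q via the pairwise identity
#   Q = sum_{i<j} w_i w_j (y_i - y_j)^2 / sum(w),
# an algebraically different route from the deviation-from-the-mean form.
pairwise_q <- function(y, s) {
  w <- 1 / s^2
  q <- 0
  for (i in seq_along(y)[-1]) {
    for (j in seq_len(i - 1)) {
      q <- q + w[i] * w[j] * (y[i] - y[j])^2
    }
  }
  q / sum(w)
}

# Welch t recomputed from first principles.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

roster_fixture <- function() rs744373_studies()

genotype_fixture <- function() {
  read_genotype_table(system.file("extdata", "synthetic_genotype_counts.csv",
                                  package = "metasnp", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
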