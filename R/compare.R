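#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t statistic
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided Student t
#' p-value, computed via [stats::t.test()]. When both samples are constant
#' with equal means the comparison is reported as `t = 0`, `p = 1` rather
#' than an error.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @param variable Label recorded in the result.
#' @return A one-row tibble: `variable`, `mean_a`, `mean_b`, `t`, `df`
#'   (fractional), `p`.
#' @export
welch_t <- function(x, y, variable = NA_character_) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each sample needs at least 2 values",
          class = "metasnp_validation_error")
  }
  res <- tryCatch(
    t.test(x, y, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # both samples essentially constant
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble(variable = variable, mean_a = mean(x), mean_b = mean(y),
                    t = 0, df = NA_real_, p = 1))
    }
    abort("t-test failed: constant samples with unequal means",
          class = "metasnp_degenerate_error")
  }
  tibble(
    variable = variable,
    mean_a = unname(res$estimate[1]), mean_b = unname(res$estimate[2]),
    t = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value
  )
}

#' Compare study-level MAF and OR distributions between two groups
#'
#' Welch t-tests of the per-study minor-allele frequencies and odds ratios
#' between two levels of the grouping column, treating studies as units
#' (no size weighting). The difference is taken as `group_a - group_b`.
#'
#' @param studies A study roster tibble.
#' @param group_a,group_b Levels of `group_col` to compare.
#' @param variables Roster columns to compare (default `maf` and `or`).
#' @param group_col Name of the grouping column.
#' @return A tibble with one row per compared variable.
#' @export
compare_groups <- function(studies, group_a = "east_asian",
                           group_b = "caucasian",
                           variables = c("maf", "or"),
                           group_col = "group") {
  g <- studies[[group_col]]
  purrr::map_dfr(variables, function(v) {
    welch_t(studies[[v]][g == group_a], studies[[v]][g == group_b],
            variable = v)
  })
}
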