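#' Build a 2x2 contrast table from genotype counts
#'
#' Collapses per-arm genotype counts of a biallelic variant (CC, CT, TT,
#' with C the effect allele) into the 2x2 table of a genetic contrast:
#' * `additive`: C alleles versus T alleles (allele counts, totals `2N`);
#' * `dominant`: CC+CT carriers versus TT (person counts);
#' * `recessive`: CC versus CT+TT (person counts).
#'
#' @param genotype_case,genotype_control Numeric vectors `c(cc, ct, tt)` of
#'   non-negative genotype counts for the case and control arms.
#' @param model One of `"additive"`, `"dominant"`, `"recessive"`.
#' @return A one-row tibble with cells `a` (exposed cases), `b` (unexposed
#'   cases), `c` (exposed controls), `d` (unexposed controls) and
#'   `correction_applied = FALSE`.
#' @export
contrast_table <- function(genotype_case, genotype_control,
                           model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  for (g in list(genotype_case, genotype_control)) {
    if (length(g) != 3 || any(is.na(g)) || any(g < 0)) {
      abort("genotype counts must be three non-negative numbers (cc, ct, tt)",
            class = "metasnp_validation_error")
    }
  }
  cell <- function(g) {
    switch(model,
      additive  = c(2 * g[[1]] + g[[2]], 2 * g[[3]] + g[[2]]),
      dominant  = c(g[[1]] + g[[2]], g[[3]]),
      recessive = c(g[[1]], g[[2]] + g[[3]])
    )
  }
  ca <- cell(genotype_case)
  co <- cell(genotype_control)
  if (sum(ca) == 0 || sum(co) == 0) {
    abort("degenerate table: an arm has no observations",
          class = "metasnp_degenerate_error")
  }
  tibble(a = ca[1], b = ca[2], c = co[1], d = co[2],
         correction_applied = FALSE)
}

#' Recover case and control allele frequencies from summary data
#'
#' Given arm sizes, a combined (case + control) effect-allele frequency and
#' an allelic odds ratio, finds the unique pair of arm-level allele
#' frequencies consistent with both. The control frequency solves
#' `(n_case * p_case + n_control * p_control) / (n_case + n_control) = maf`
#' with `p_case = or * p_control / (1 - p_control + or * p_control)`; the
#' left-hand side is strictly increasing in `p_control`, so the root is
#' isolated by bisection in (0, 1) to absolute tolerance 1e-12.
#'
#' With `maf_interpretation = "control"` the `maf` value is taken as the
#' control-arm frequency directly and only `p_case` is derived.
#'
#' @param n_case,n_control Arm sizes in persons.
#' @param maf Effect-allele frequency in (0, 1).
#' @param or Allelic odds ratio (> 0).
#' @param maf_interpretation `"combined"` (default) or `"control"`.
#' @return A tibble with columns `p_case` and `p_control` (one row per
#'   input element; the function is vectorised).
#' @export
reconstruct_frequencies <- function(n_case, n_control, maf, or,
                                    maf_interpretation = c("combined",
                                                           "control")) {
  maf_interpretation <- match.arg(maf_interpretation)
  if (any(maf <= 0 | maf >= 1)) {
    abort("maf must lie strictly between 0 and 1",
          class = "metasnp_validation_error")
  }
  if (any(or <= 0)) {
    abort("or must be positive", class = "metasnp_validation_error")
  }
  n <- max(length(n_case), length(n_control), length(maf), length(or))
  args <- tibble(n_case = rep_len(n_case, n), n_control = rep_len(n_control, n),
                 maf = rep_len(maf, n), or = rep_len(or, n))
  case_freq <- function(p0, or) or * p0 / (1 - p0 + or * p0)
  p_control <- purrr::pmap_dbl(args, function(n_case, n_control, maf, or) {
    if (maf_interpretation == "control" || or == 1) {
      return(maf)
    }
    f <- function(p0) {
      (n_case * case_freq(p0, or) + n_control * p0) / (n_case + n_control) -
        maf
    }
    uniroot(f, interval = c(1e-15, 1 - 1e-15), tol = 1e-12)$root
  })
  tibble(p_case = case_freq(p_control, args$or), p_control = p_control)
}

#' Log odds ratio and standard error from a 2x2 table
#'
#' Woolf estimator: `ln_or = log(a*d / (b*c))`,
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. When any cell is zero the
#' Haldane-Anscombe continuity correction adds `correction` (default 0.5)
#' to all four cells first. Cells may be fractional (reconstructed tables
#' are not rounded).
#'
#' @param table A one-row data frame (or list) with cells `a`, `b`, `c`, `d`.
#' @param correction Value added to every cell when a zero cell occurs; set
#'   to `NULL` to disable the correction.
#' @param label,group,source Provenance carried into the estimate.
#' @return A one-row tibble with `label`, `group`, `ln_or`, `se`, `source`,
#'   `correction_applied`.
#' @export
effect_from_table <- function(table, correction = 0.5,
                              label = NA_character_, group = NA_character_,
                              source = "genotype_counts") {
  cells <- c(table$a, table$b, table$c, table$d)
  if (length(cells) != 4 || any(is.na(cells)) || any(cells < 0)) {
    abort("table must have non-negative cells a, b, c, d",
          class = "metasnp_validation_error")
  }
  applied <- FALSE
  if (any(cells == 0)) {
    if (is.null(correction)) {
      abort("table has zero cells and the continuity correction is disabled",
            class = "metasnp_degenerate_error")
    }
    cells <- cells + correction
    applied <- TRUE
  }
  tibble(
    label = label, group = group,
    ln_or = log(cells[1] * cells[4] / (cells[2] * cells[3])),
    se = sqrt(sum(1 / cells)),
    source = source, correction_applied = applied
  )
}

#' Log odds ratio and standard error from a reported OR and 95% CI
#'
#' `ln_or = log(or)`; `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param or Reported odds ratio.
#' @param ci_low,ci_high 95% confidence limits, with
#'   `ci_low < or < ci_high`.
#' @inheritParams effect_from_table
#' @return A one-row tibble as in [effect_from_table()], `source =
#'   "summary_ci"`.
#' @export
effect_from_summary <- function(or, ci_low, ci_high,
                                label = NA_character_,
                                group = NA_character_) {
  if (any(!(ci_low < or & or < ci_high)) || any(ci_low <= 0)) {
    abort("confidence limits must satisfy 0 < ci_low < or < ci_high",
          class = "metasnp_validation_error")
  }
  tibble(
    label = label, group = group,
    ln_or = log(or),
    se = (log(ci_high) - log(ci_low)) / (2 * Z975),
    source = "summary_ci", correction_applied = FALSE
  )
}

#' Per-study effect estimates for a study roster
#'
#' Turns every usable study of a roster into a log odds ratio with standard
#' error under the requested genetic contrast. Studies with genotype counts
#' use the counts (under `policy = "genotype_first"`); summary-level studies
#' are reconstructed from `(n_case, n_control, maf, or)` into a fractional
#' allele table (additive model only). Dominant and recessive contrasts
#' require genotype counts; rows lacking them are dropped with a message.
#'
#' @param studies A study roster tibble (see [read_study_table()]).
#' @param model Genetic contrast: `"additive"`, `"dominant"` or
#'   `"recessive"`.
#' @param policy `"genotype_first"` (use counts where available, reconstruct
#'   otherwise), `"reconstruct_only"` or `"genotype_only"`.
#' @param maf_interpretation Passed to [reconstruct_frequencies()].
#' @param correction Continuity correction passed to [effect_from_table()].
#' @return A tibble of effect estimates, one row per usable study, in
#'   roster order.
#' @export
build_effects <- function(studies,
                          model = c("additive", "dominant", "recessive"),
                          policy = c("genotype_first", "reconstruct_only",
                                     "genotype_only"),
                          maf_interpretation = c("combined", "control"),
                          correction = 0.5) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  maf_interpretation <- match.arg(maf_interpretation)
  if (nrow(studies) == 0) {
    abort("no studies supplied", class = "metasnp_pipeline_error")
  }
  counts_ok <- has_genotype_counts(studies)
  use_counts <- switch(policy,
    genotype_first   = counts_ok,
    genotype_only    = counts_ok,
    reconstruct_only = rep(FALSE, nrow(studies))
  )
  if (model != "additive") {
    if (!any(counts_ok) || policy == "reconstruct_only") {
      abort(
        paste0("the ", model, " contrast requires genotype count columns (",
               paste(GENO_COLS, collapse = ", "), ")"),
        class = "metasnp_pipeline_error"
      )
    }
    use_counts <- counts_ok
  }
  usable <- if (model == "additive" && policy != "genotype_only") {
    rep(TRUE, nrow(studies))
  } else {
    use_counts
  }
  if (!all(usable)) {
    inform(paste0("dropping ", sum(!usable),
                  " study(ies) without genotype counts"))
  }
  if (!any(usable)) {
    abort("no usable studies for the requested contrast",
          class = "metasnp_pipeline_error")
  }
  rows <- purrr::map(which(usable), function(i) {
    st <- studies[i, ]
    if (use_counts[i]) {
      tab <- contrast_table(
        c(st$cc_case, st$ct_case, st$tt_case),
        c(st$cc_control, st$ct_control, st$tt_control),
        model
      )
      effect_from_table(tab, correction, label = st$label, group = st$group,
                        source = "genotype_counts")
    } else {
      fr <- reconstruct_frequencies(st$n_case, st$n_control, st$maf, st$or,
                                    maf_interpretation)
      tab <- tibble(
        a = 2 * st$n_case * fr$p_case,
        b = 2 * st$n_case * (1 - fr$p_case),
        c = 2 * st$n_control * fr$p_control,
        d = 2 * st$n_control * (1 - fr$p_control)
      )
      effect_from_table(tab, correction, label = st$label, group = st$group,
                        source = "reconstructed")
    }
  })
  dplyr::bind_rows(rows)
}
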