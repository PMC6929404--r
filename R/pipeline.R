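#' Run the full association meta-analysis pipeline
#'
#' One call from roster to results: per-study effects under each requested
#' genetic contrast, subgroup and overall pooling with the
#' heterogeneity-driven model choice, leave-one-out sensitivity analysis,
#' Begg and Egger publication-bias tests, funnel coordinates, and the
#' between-group comparison of study-level MAF and OR values. The additive
#' analysis of the bundled roster reproduces the package's reference
#' results.
#'
#' @param studies A study roster tibble, or `NULL` to read from `path`.
#' @param path Path to a roster file (see [read_study_table()]).
#' @param models Genetic contrasts to run (subset of `"additive"`,
#'   `"dominant"`, `"recessive"`).
#' @param group_col Grouping column for subgroup analysis and comparisons.
#' @inheritParams build_effects
#' @inheritParams select_model
#' @param bias_alpha Significance level for the publication-bias calls
#'   (default 0.01).
#' @param compare Logical: run the between-group MAF/OR comparison
#'   (requires exactly two group levels).
#' @param out_dir Optional directory; when given, every result table is
#'   written there as CSV along with a JSON run manifest.
#' @return A list of tibbles: `meta` (per contrast x group),
#'   `sensitivity`, `bias`, `comparison`, `funnel`, `effects` and the
#'   `manifest` list.
#' @export
run_pipeline <- function(studies = NULL, path = NULL,
                         models = "additive", group_col = "group",
                         policy = c("genotype_first", "reconstruct_only",
                                    "genotype_only"),
                         maf_interpretation = c("combined", "control"),
                         correction = 0.5,
                         p_threshold = 0.05, i2_threshold = 50,
                         bias_alpha = 0.01, compare = TRUE,
                         out_dir = NULL) {
  policy <- match.arg(policy)
  maf_interpretation <- match.arg(maf_interpretation)
  models <- match.arg(models, c("additive", "dominant", "recessive"),
                      several.ok = TRUE)
  if (is.null(studies)) {
    if (is.null(path)) {
      abort("supply either 'studies' or 'path'",
            class = "metasnp_validation_error")
    }
    studies <- read_study_table(path)
  }

  per_model <- purrr::map(setNames(models, models), function(m) {
    meta <- subgroup_meta(studies, m, group_col = group_col, policy = policy,
                          maf_interpretation = maf_interpretation,
                          p_threshold = p_threshold,
                          i2_threshold = i2_threshold,
                          correction = correction)
    effects <- meta$fit[[which(meta$group == "all")]]$effects
    pooled <- pool_random_dl(effects)
    list(
      meta = dplyr::mutate(dplyr::select(meta, -"fit"), contrast = m,
                           .before = 1),
      effects = dplyr::mutate(effects, contrast = m, .before = 1),
      sensitivity = dplyr::mutate(leave_one_out(effects), contrast = m,
                                  .before = 1),
      bias = dplyr::mutate(
        dplyr::bind_rows(begg_test(effects), egger_test(effects)),
        contrast = m, significant = .data$p < bias_alpha, .before = 1
      ),
      funnel = dplyr::mutate(funnel_data(effects, pooled), contrast = m,
                             .before = 1)
    )
  })

  bundle <- list(
    meta = purrr::map_dfr(per_model, "meta"),
    effects = purrr::map_dfr(per_model, "effects"),
    sensitivity = purrr::map_dfr(per_model, "sensitivity"),
    bias = purrr::map_dfr(per_model, "bias"),
    funnel = purrr::map_dfr(per_model, "funnel")
  )
  if (compare) {
    lv <- unique(studies[[group_col]])
    if (length(lv) == 2) {
      bundle$comparison <- compare_groups(studies, lv[1], lv[2],
                                          group_col = group_col)
    } else {
      inform("skipping group comparison: need exactly 2 group levels")
    }
  }
  bundle$manifest <- list(
    n_studies = nrow(studies),
    models = models, policy = policy,
    maf_interpretation = maf_interpretation,
    correction = correction,
    thresholds = list(het_p = p_threshold, i2 = i2_threshold,
                      bias_alpha = bias_alpha),
    package_version = as.character(utils::packageVersion("metasnp"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(bundle), "manifest")) {
      if (!is.null(bundle[[nm]]) && nrow(bundle[[nm]]) > 0) {
        write_results_table(bundle[[nm]], file.path(out_dir,
                                                    paste0(nm, ".csv")))
      }
    }
    jsonlite::write_json(bundle$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}
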