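ROSTER_COLS <- c("label", "group", "n_case", "n_control", "maf", "or")
GENO_COLS <- c("cc_case", "ct_case", "tt_case",
               "cc_control", "ct_control", "tt_control")

#' Read a study roster table
#'
#' Reads a delimited table with one row per case-control study. Required
#' columns are `label`, `group`, `n_case`, `n_control`, `maf` (frequency of
#' the effect allele) and `or` (the study's reported odds ratio for the
#' effect allele). Optional genotype-count columns (`cc_case`, `ct_case`,
#' `tt_case`, `cc_control`, `ct_control`, `tt_control`) and free-text columns
#' (e.g. `population`, `platform`) are carried through. Row order is
#' preserved exactly as read; labels need not be unique (multi-cohort
#' articles contribute several rows under one label).
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter: `","` (default) or `"\t"`.
#' @return A tibble with one validated row per study, in file order, with a
#'   `"source"` attribute recording the path.
#' @export
read_study_table <- function(path, delim = c(",", "\t")) {
  delim <- match.arg(delim)
  raw <- read_delim_chr(path, delim)
  missing <- setdiff(ROSTER_COLS, names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("roster is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "metasnp_schema_error"
    )
  }
  out <- validate_roster(raw, require_counts = FALSE)
  attr(out, "source") <- path
  out
}

#' Read a genotype-count study table
#'
#' Like [read_study_table()] but requires per-arm genotype counts
#' (`cc_*`, `ct_*`, `tt_*` for cases and controls). Sample sizes, the
#' combined minor-allele frequency and the allelic odds ratio are derived
#' from the counts when the corresponding columns are absent, so the roster
#' summary is always self-consistent with the counts it summarises.
#'
#' @inheritParams read_study_table
#' @return A tibble with one validated row per study, genotype counts
#'   populated.
#' @export
read_genotype_table <- function(path, delim = c(",", "\t")) {
  delim <- match.arg(delim)
  raw <- read_delim_chr(path, delim)
  missing <- setdiff(c("label", "group", GENO_COLS), names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("genotype table is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "metasnp_schema_error"
    )
  }
  for (col in GENO_COLS) {
    raw[[col]] <- parse_num(raw[[col]], col)
  }
  cases <- raw$cc_case + raw$ct_case + raw$tt_case
  ctrls <- raw$cc_control + raw$ct_control + raw$tt_control
  if (!"n_case" %in% names(raw)) raw$n_case <- cases
  if (!"n_control" %in% names(raw)) raw$n_control <- ctrls
  if (!"maf" %in% names(raw) || !"or" %in% names(raw)) {
    a <- 2 * raw$cc_case + raw$ct_case
    b <- 2 * raw$tt_case + raw$ct_case
    c_ <- 2 * raw$cc_control + raw$ct_control
    d <- 2 * raw$tt_control + raw$ct_control
    if (!"maf" %in% names(raw)) raw$maf <- (a + c_) / (a + b + c_ + d)
    if (!"or" %in% names(raw)) raw$or <- (a * d) / (b * c_)
  }
  out <- validate_roster(raw, require_counts = TRUE)
  attr(out, "source") <- path
  out
}

#' The bundled rs744373 study roster
#'
#' A transcription of the characteristics table of 37 case-control studies
#' (from 19 articles; 22,395 Alzheimer's disease cases and 48,773 controls)
#' of the BIN1 upstream variant rs744373, with the study label, population,
#' ethnicity group (`east_asian` or `caucasian`), arm sizes, the frequency
#' of allele C and the reported odds ratio.
#'
#' @return A 37-row tibble in the original table order.
#' @export
rs744373_studies <- function() {
  read_study_table(
    system.file("extdata", "rs744373_studies.csv",
                package = "metasnp", mustWork = TRUE)
  )
}

#' Write a results table
#'
#' Writes any non-empty tabular result as delimited text with a header.
#' Numbers are serialised at full (round-trip) precision, so reading the
#' file back reproduces the original values exactly.
#'
#' @param results A data frame with at least one row.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("'results' must be a data frame with at least one row",
          class = "metasnp_validation_error")
  }
  out <- results
  dbl <- vapply(out, is.double, logical(1))
  # 17 significant digits guarantee an exact binary round trip
  out[dbl] <- lapply(out[dbl], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  readr::write_csv(out, path)
  invisible(path)
}

# -- internal ----------------------------------------------------------------

read_delim_chr <- function(path, delim) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "metasnp_io_error")
  }
  readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
}

parse_num <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    abort(
      paste0("column '", col, "' is not numeric in row(s) ",
             paste(bad, collapse = ", ")),
      class = "metasnp_validation_error"
    )
  }
  out
}

fail_rows <- function(bad, what) {
  if (length(bad) > 0) {
    abort(
      paste0(what, " in row(s) ", paste(bad, collapse = ", ")),
      class = "metasnp_validation_error"
    )
  }
}

validate_roster <- function(raw, require_counts = FALSE) {
  out <- raw
  for (col in intersect(c("n_case", "n_control", "maf", "or", GENO_COLS),
                        names(out))) {
    out[[col]] <- parse_num(out[[col]], col)
  }
  if (nrow(out) == 0) {
    return(as_tibble(out))
  }
  fail_rows(which(is.na(out$label) | out$label == ""), "missing study label")
  fail_rows(which(is.na(out$n_case) | out$n_case <= 0 |
                    out$n_case != round(out$n_case)),
            "n_case must be a positive integer")
  fail_rows(which(is.na(out$n_control) | out$n_control <= 0 |
                    out$n_control != round(out$n_control)),
            "n_control must be a positive integer")
  fail_rows(which(is.na(out$maf) | out$maf <= 0 | out$maf >= 1),
            "maf must lie strictly between 0 and 1")
  fail_rows(which(is.na(out$or) | out$or <= 0),
            "or must be a positive number")
  if (all(GENO_COLS %in% names(out))) {
    counts <- as.matrix(out[GENO_COLS])
    has <- rowSums(is.na(counts)) == 0
    if (require_counts) {
      fail_rows(which(!has), "missing genotype count")
    }
    fail_rows(which(has & apply(counts < 0, 1, any)),
              "negative genotype count")
    case_sum <- rowSums(counts[, 1:3, drop = FALSE])
    ctrl_sum <- rowSums(counts[, 4:6, drop = FALSE])
    fail_rows(which(has & (case_sum > out$n_case | ctrl_sum > out$n_control)),
              "genotype counts exceed the declared sample size")
  } else if (require_counts) {
    abort("genotype count columns are required",
          class = "metasnp_schema_error")
  }
  as_tibble(out)
}

has_genotype_counts <- function(studies) {
  if (!all(GENO_COLS %in% names(studies))) {
    return(rep(FALSE, nrow(studies)))
  }
  rowSums(is.na(as.matrix(studies[GENO_COLS]))) == 0
}
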