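#' Meta-analysis catalogues
#'
#' A catalogue bundles the summary rows of a set of meta-analyses (one row
#' per pooled effect: effect measure, effect size, 95% CI, significance
#' marker, subfield label, number of included studies) with an optional
#' table of per-study design records (group sizes and, for binary outcome
#' measures, the control-group base rate). Study records are what the power
#' calculations consume; the meta-analysis rows supply the assumed
#' population effect.
#'
#' @param records data.frame with columns `label`, `n_studies`, `measure`
#'   (one of `"d"`, `"or"`, `"rr"`), `effect`, `ci_low`, `ci_high`,
#'   `significant` (logical or 0/1), `subfield`.
#' @param studies optional data.frame with columns `meta_label`,
#'   `n_group1`, `n_group2`, `base_rate` (`NA` for Cohen's-d studies).
#' @return An object of class `"catalogue"`: a list with elements
#'   `records` and `studies`.
#' @seealso [builtin_catalogue()], [read_catalogue()], [validate_catalogue()]
#' @export
catalogue <- function(records, studies = NULL) {
  req <- c("label", "n_studies", "measure", "effect", "ci_low", "ci_high",
           "significant", "subfield")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop_domain("catalogue records are missing column(s): ",
                paste(miss, collapse = ", "))
  records <- as.data.frame(records)[req]
  records$label <- as.character(records$label)
  records$measure <- as.character(records$measure)
  records$subfield <- as.character(records$subfield)
  records$significant <- as.logical(records$significant)
  for (col in c("n_studies", "effect", "ci_low", "ci_high"))
    records[[col]] <- as.numeric(records[[col]])

  if (anyDuplicated(records$label))
    stop_domain("catalogue labels must be unique")
  if (any(!records$measure %in% c("d", "or", "rr")))
    stop_domain("`measure` must be one of 'd', 'or', 'rr'")
  if (any(records$n_studies < 1 | records$n_studies != round(records$n_studies)))
    stop_domain("`n_studies` must be a positive integer")
  if (any(records$measure != "d" & records$effect <= 0))
    stop_domain("ratio effect sizes must be positive")
  # normalize CI ordering (ranges printed high-to-low are legitimate input)
  swap <- records$ci_low > records$ci_high
  if (any(swap)) {
    tmp <- records$ci_low[swap]
    records$ci_low[swap] <- records$ci_high[swap]
    records$ci_high[swap] <- tmp
  }

  if (!is.null(studies)) {
    sreq <- c("meta_label", "n_group1", "n_group2", "base_rate")
    smiss <- setdiff(sreq, names(studies))
    if (length(smiss))
      stop_domain("study records are missing column(s): ",
                  paste(smiss, collapse = ", "))
    studies <- as.data.frame(studies)[sreq]
    studies$meta_label <- as.character(studies$meta_label)
    for (col in c("n_group1", "n_group2", "base_rate"))
      studies[[col]] <- as.numeric(studies[[col]])
    bad <- !studies$meta_label %in% records$label
    if (any(bad))
      stop_domain("study records reference unknown meta-analyses: ",
                  paste(unique(studies$meta_label[bad]), collapse = ", "))
    if (any(studies$n_group1 < 1 | studies$n_group2 < 1))
      stop_domain("group sizes must be >= 1")
    meas <- records$measure[match(studies$meta_label, records$label)]
    binary <- meas %in% c("or", "rr")
    if (any(binary & !is.finite(studies$base_rate)))
      stop_domain("binary-outcome studies require a base rate")
    if (any(binary & (studies$base_rate <= 0 | studies$base_rate >= 1)))
      stop_domain("base rates must lie in (0, 1)")
    if (any(!binary & is.finite(studies$base_rate)))
      stop_domain("Cohen's-d studies must not carry a base rate")
  }

  structure(list(records = records, studies = studies), class = "catalogue")
}

#' @export
print.catalogue <- function(x, ...) {
  cat(sprintf("Meta-analysis catalogue: %d meta-analyses, %d studies counted",
              nrow(x$records), sum(x$records$n_studies)))
  cat(sprintf("\n  per-study design records: %s\n",
              if (is.null(x$studies)) "none" else nrow(x$studies)))
  tot <- subfield_totals(x)
  cat("  studies per subfield: ",
      paste(sprintf("%s %d", names(tot), tot), collapse = ", "), "\n", sep = "")
  cat(sprintf("  null (non-significant) meta-analyses: %d\n",
              sum(!x$records$significant)))
  invisible(x)
}

# Table of 49 neuroscience meta-analyses (730 primary studies). Effect sizes,
# CIs, significance markers and subfield labels are carried verbatim from the
# source catalogue, including its internal inconsistencies (two rows whose CI
# is on a scale that cannot match the reported Cohen's d; one row whose CI
# touches the null while marked significant). validate_catalogue() reports
# these, but they are never altered. The one publication split into cohort
# and case-control arms contributes two records.
builtin_rows <- function() {
  rows <- rbind(
    list("MA01", 13, "d",  -1.11, -1.25, -0.97, TRUE,  "psychology"),
    list("MA02", 18, "or",  1.47,  1.22,  1.77, TRUE,  "genetic"),
    list("MA03",  6, "d",  -1.20,  1.60,  8.00, TRUE,  "treatment"),
    list("MA04", 21, "d",   0.41,  0.17,  0.65, TRUE,  "neurochemistry"),
    list("MA05", 11, "d",  -0.51,  0.83,  1.08, TRUE,  "psychology"),
    list("MA06", 56, "d",  -0.19, -0.29, -0.10, TRUE,  "psychology"),
    list("MA07",  6, "or",  0.98,  0.86,  1.12, FALSE, "genetic"),
    list("MA08", 12, "or",  0.60,  0.52,  0.69, TRUE,  "miscellaneous"),
    list("MA09", 11, "or",  0.67,  0.43,  1.04, FALSE, "treatment"),
    list("MA10", 14, "or",  2.12,  1.59,  2.78, TRUE,  "psychology"),
    list("MA11", 14, "or",  0.80,  0.70,  0.92, TRUE,  "treatment"),
    list("MA12",  4, "or",  1.20,  1.04,  1.40, TRUE,  "genetic"),
    list("MA13", 17, "d",  -0.59, -0.93, -0.26, TRUE,  "neurochemistry"),
    list("MA14", 14, "or",  1.35,  1.06,  1.72, TRUE,  "genetic"),
    list("MA15", 13, "d",  -0.13, -0.55,  0.29, FALSE, "treatment"),
    list("MA16", 27, "or",  1.13,  1.05,  1.21, TRUE,  "genetic"),
    list("MA17",  8, "or",  1.05,  0.92,  1.19, FALSE, "treatment"),
    list("MA18", 12, "or",  1.04,  0.88,  1.22, FALSE, "genetic"),
    list("MA19",  6, "or",  0.89,  0.82,  0.96, TRUE,  "genetic"),
    list("MA20", 57, "d",   0.58,  0.51,  0.64, TRUE,  "psychology"),
    list("MA21",  5, "rr",  1.67,  1.23,  2.26, TRUE,  "treatment"),
    list("MA22",  6, "or",  1.12,  1.00,  1.26, TRUE,  "genetic"),
    list("MA23", 14, "d",  -0.40, -0.62, -0.19, TRUE,  "imaging"),
    list("MA24", 10, "d",  -0.51, -0.73, -0.28, TRUE,  "psychology"),
    list("MA25",  7, "or",  0.86,  0.79,  0.95, TRUE,  "treatment"),
    list("MA26", 36, "or",  1.26,  1.09,  1.46, TRUE,  "genetic"),
    list("MA27", 22, "d",   0.92,  0.44,  1.39, TRUE,  "treatment"),
    list("MA28",  5, "or",  2.06,  1.33,  3.19, TRUE,  "miscellaneous"),
    list("MA29",  8, "d",   0.43,  0.06,  0.80, TRUE,  "imaging"),
    list("MA30", 11, "d",   0.89,  0.75,  1.02, TRUE,  "psychology"),
    list("MA31",  2, "rr",  1.23,  1.08,  1.52, TRUE,  "treatment"),
    list("MA32", 12, "d",   0.15,  0.04,  0.26, TRUE,  "neurochemistry"),
    list("MA33",  6, "or",  1.93,  1.55,  2.41, TRUE,  "genetic"),
    list("MA34",  4, "d",   1.26,  0.95,  1.57, TRUE,  "treatment"),
    list("MA35", 11, "or",  1.98,  1.33,  2.94, TRUE,  "imaging"),
    list("MA36",  8, "d",   0.37,  0.20,  0.53, TRUE,  "treatment"),
    list("MA37", 24, "or",  0.83,  0.74,  0.93, TRUE,  "treatment"),
    list("MA38", 10, "rr",  0.68,  0.60,  0.77, TRUE,  "treatment"),
    list("MA39", 53, "d",  -0.14, -0.21, -0.07, TRUE,  "genetic"),
    list("MA40", 26, "d",  -1.41, -1.76, -1.05, TRUE,  "psychology"),
    list("MA41", 24, "d",  -0.60, -0.83, -0.37, TRUE,  "imaging"),
    # APOE e4 / multiple sclerosis: OR exactly 1.00; CI carried at the
    # three-decimal precision reported in the source's text (0.861-1.156).
    list("MA42", 20, "or",  1.00,  0.861, 1.156, FALSE, "genetic"),
    list("MA43_cohort",      14, "rr", 1.38, 1.18, 1.61, TRUE, "miscellaneous"),
    list("MA43_casecontrol",  7, "or", 2.48, 1.93, 3.19, TRUE, "miscellaneous"),
    list("MA44",  3, "d",   0.67,  0.43,  0.92, TRUE,  "treatment"),
    list("MA45", 14, "or",  4.98,  3.97,  6.23, TRUE,  "genetic"),
    list("MA46",  8, "rr",  1.07,  0.91,  1.27, FALSE, "treatment"),
    list("MA47", 12, "or",  1.27,  1.01,  1.59, TRUE,  "genetic"),
    list("MA48",  8, "d",   0.84,  0.18,  1.49, TRUE,  "imaging")
  )
  data.frame(
    label = unlist(rows[, 1]),
    n_studies = unlist(rows[, 2]),
    measure = unlist(rows[, 3]),
    effect = unlist(rows[, 4]),
    ci_low = unlist(rows[, 5]),
    ci_high = unlist(rows[, 6]),
    significant = unlist(rows[, 7]),
    subfield = unlist(rows[, 8]),
    stringsAsFactors = FALSE
  )
}

#' Built-in catalogue of 49 neuroscience meta-analyses
#'
#' Returns the packaged catalogue: 49 meta-analyses spanning 730 primary
#' studies, classified into six methodological subfields (candidate gene
#' association, psychology, treatment trials, neuroimaging, neurochemistry,
#' miscellaneous). Seven of the 49 pooled effects are not significantly
#' different from the null. No per-study design records are attached: the
#' primary studies' group sizes and base rates are not part of the published
#' summary table, so power on the real data requires a user-supplied studies
#' file (or use [generate_catalogue()] for a synthetic analogue).
#'
#' The rows are preserved exactly as published, including internal
#' inconsistencies; see [validate_catalogue()].
#'
#' @return A [catalogue] with 49 records and no studies.
#' @examples
#' cat49 <- builtin_catalogue()
#' nrow(cat49$records)        # 49
#' sum(cat49$records$n_studies)  # 730
#' @export
builtin_catalogue <- function() {
  catalogue(builtin_rows())
}

#' Read / write catalogues as CSV
#'
#' The records file schema (UTF-8, header row) is
#' `label, n_studies, measure, effect, ci_low, ci_high, significant, subfield`
#' with `measure` one of `d|or|rr` and `significant` coded `0|1`. The
#' optional studies file schema is
#' `meta_label, n_group1, n_group2, base_rate` with `base_rate` left blank
#' for Cohen's-d studies. [write_catalogue()] emits the identical dialect, so
#' write followed by read is the identity.
#'
#' @param records_file path to the records CSV.
#' @param studies_file optional path to the studies CSV.
#' @return A [catalogue].
#' @export
read_catalogue <- function(records_file, studies_file = NULL) {
  rec <- utils::read.csv(records_file, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("label", "n_studies", "measure", "effect", "ci_low", "ci_high",
           "significant", "subfield")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stop_domain("catalogue file is missing column(s): ",
                paste(miss, collapse = ", "))
  for (col in c("n_studies", "effect", "ci_low", "ci_high", "significant")) {
    val <- suppressWarnings(as.numeric(rec[[col]]))
    bad <- which(!is.finite(val))
    if (length(bad))
      stop_domain(sprintf("non-numeric value in column '%s' at data row %d",
                          col, bad[1]))
    rec[[col]] <- val
  }
  rec$significant <- rec$significant != 0
  studies <- NULL
  if (!is.null(studies_file)) {
    studies <- utils::read.csv(studies_file, stringsAsFactors = FALSE)
    studies$base_rate <- suppressWarnings(as.numeric(studies$base_rate))
  }
  catalogue(rec, studies)
}

#' @rdname read_catalogue
#' @param x a [catalogue].
#' @export
write_catalogue <- function(x, records_file, studies_file = NULL) {
  stopifnot(inherits(x, "catalogue"))
  rec <- x$records
  rec$significant <- as.integer(rec$significant)
  utils::write.csv(rec, records_file, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(studies_file)) {
    if (is.null(x$studies))
      stop_domain("catalogue has no study records to write")
    utils::write.csv(x$studies, studies_file, row.names = FALSE,
                     quote = FALSE, na = "")
  }
  invisible(x)
}

#' Consistency report for a catalogue
#'
#' Flags (without ever altering the data):
#' \describe{
#'   \item{significance_mismatch}{the printed CI excludes the null value
#'     (0 for Cohen's d, 1 for ratio measures) while the row is marked
#'     non-significant, or includes it while marked significant;}
#'   \item{scale_mismatch}{the reported effect size lies outside its own CI,
#'     indicating the CI was printed on a different scale or with the wrong
#'     sign;}
#'   \item{study_count_mismatch}{attached study records do not sum to the
#'     row's `n_studies`.}
#' }
#' Significance is always taken from the printed marker, never recomputed:
#' the report documents disagreements but the marker column stays
#' authoritative everywhere else in the package.
#'
#' @param x a [catalogue].
#' @return An object of class `"catalogue_validation"`: list with a
#'   data.frame `issues` (`label`, `kind`, `message`) and a named integer
#'   vector `counts`. Zero rows in `issues` means every check passed.
#' @export
validate_catalogue <- function(x) {
  stopifnot(inherits(x, "catalogue"))
  rec <- x$records
  issues <- data.frame(label = character(), kind = character(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(label, kind, message)
    rbind(issues, data.frame(label = label, kind = kind, message = message,
                             stringsAsFactors = FALSE))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    null_value <- if (r$measure == "d") 0 else 1
    if (r$effect < r$ci_low || r$effect > r$ci_high) {
      issues <- add(r$label, "scale_mismatch",
                    sprintf("effect %.3g outside its CI [%.3g, %.3g]",
                            r$effect, r$ci_low, r$ci_high))
      next  # CI scale unusable; significance check would be meaningless
    }
    excludes_null <- r$ci_low > null_value || r$ci_high < null_value
    if (excludes_null && !r$significant)
      issues <- add(r$label, "significance_mismatch",
                    "CI excludes the null but row is marked non-significant")
    if (!excludes_null && r$significant)
      issues <- add(r$label, "significance_mismatch",
                    "CI includes the null but row is marked significant")
  }
  if (!is.null(x$studies)) {
    cnt <- table(x$studies$meta_label)
    for (i in seq_len(nrow(rec))) {
      have <- if (rec$label[i] %in% names(cnt)) cnt[[rec$label[i]]] else 0L
      if (have != rec$n_studies[i])
        issues <- add(rec$label[i], "study_count_mismatch",
                      sprintf("%d study records attached but n_studies = %d",
                              have, rec$n_studies[i]))
    }
  }
  kinds <- c("significance_mismatch", "scale_mismatch", "study_count_mismatch")
  counts <- vapply(kinds, function(k) sum(issues$kind == k), integer(1))
  structure(list(issues = issues, counts = counts),
            class = "catalogue_validation")
}

#' @export
print.catalogue_validation <- function(x, ...) {
  if (nrow(x$issues) == 0) {
    cat("Catalogue validation: all checks passed\n")
  } else {
    cat(sprintf("Catalogue validation: %d issue(s)\n", nrow(x$issues)))
    print(x$issues, row.names = FALSE)
  }
  invisible(x)
}

#' Null meta-analyses and their complement
#'
#' Subsets a catalogue to the meta-analyses whose pooled effect is marked
#' non-significant ("null meta-analyses"), or, with `complement = TRUE`, to
#' the significant ones. Attached study records are subset along with their
#' meta-analyses, so the two calls partition the catalogue.
#'
#' @param x a [catalogue].
#' @param complement return the significant meta-analyses instead.
#' @return A [catalogue].
#' @export
null_meta_analyses <- function(x, complement = FALSE) {
  stopifnot(inherits(x, "catalogue"))
  keep <- if (complement) x$records$significant else !x$records$significant
  rec <- x$records[keep, , drop = FALSE]
  studies <- x$studies
  if (!is.null(studies))
    studies <- studies[studies$meta_label %in% rec$label, , drop = FALSE]
  catalogue(rec, studies)
}

#' Study counts per subfield
#'
#' @param x a [catalogue].
#' @return Named integer vector of per-subfield sums of `n_studies`; the
#'   values always sum to the catalogue total.
#' @export
subfield_totals <- function(x) {
  stopifnot(inherits(x, "catalogue"))
  tot <- tapply(x$records$n_studies, x$records$subfield, sum)
  out <- as.integer(tot)
  names(out) <- names(tot)
  sort(out, decreasing = TRUE)
}
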