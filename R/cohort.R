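# Clinical cohort fixture: loading, validation and descriptive summaries.

.cohort_levels <- list(
  menopause = c("premenopausal", "postmenopausal"),
  histotype = c("endometrioid G1", "endometrioid G2", "endometrioid G3",
                "serous", "mucinous", "dedifferentiated", "carcinosarcoma"),
  figo = c("IA", "IB", "II", "III", "IV"),
  grade_class = c("HG", "LG"),
  myometrial_invasion = c("none", "lt50", "gt50"),
  lvi = c("yes", "no", "unknown")
)

# low grade = endometrioid G1/G2 and mucinous; everything else (endometrioid
# G3 and the non-endometrioid histologies) is treated as high grade
.lg_histotypes <- c("endometrioid G1", "endometrioid G2", "mucinous")

#' Path to the packaged clinical cohort table
#'
#' @return File path of the tab-delimited 36-patient cohort fixture.
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "cohort_table2.tsv", package = "ecangio",
              mustWork = TRUE)
}

#' Load a clinical cohort table
#'
#' Reads a tab-delimited table of patient records (sample id, age,
#' menopausal status, histotype, FIGO stage, grade class, depth of
#' myometrial invasion, lymphovascular invasion) and validates every
#' categorical field against the known category sets. The grade class is
#' cross-checked against the histotype: low grade comprises endometrioid
#' G1-G2 and mucinous carcinomas, high grade comprises endometrioid G3 and
#' the non-endometrioid histologies.
#'
#' @param path path to a TSV file; defaults to the packaged cohort fixture.
#' @return A data.frame with one validated row per patient.
#' @export
load_cohort <- function(path = cohort_fixture_path()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("cohort table is empty: ", path)
  required <- c("sample_id", "age", "menopause", "histotype", "figo",
                "grade_class", "myometrial_invasion", "lvi")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "))
  }
  df$age <- suppressWarnings(as.integer(df$age))
  if (any(is.na(df$age)) || any(df$age <= 0L)) {
    stop("age must be a positive integer in every row")
  }
  for (col in names(.cohort_levels)) {
    bad <- which(!df[[col]] %in% .cohort_levels[[col]])
    if (length(bad)) {
      stop(sprintf("unknown %s value '%s' in row %d", col, df[[col]][bad[1]],
                   bad[1]))
    }
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  derived <- ifelse(df$histotype %in% .lg_histotypes, "LG", "HG")
  mism <- which(derived != df$grade_class)
  if (length(mism)) {
    stop(sprintf("grade_class inconsistent with histotype in row %d", mism[1]))
  }
  df
}

#' Summarise a clinical cohort
#'
#' Computes the descriptive statistics reported for the cohort: mean and
#' sample (n-1) standard deviation of age, and per-category counts with
#' percentages for menopausal status, histotype group (endometrioid vs
#' other), FIGO stage, grade class, depth of myometrial invasion, and
#' lymphovascular invasion. Percentages use the full cohort size as the
#' denominator; records with unknown LVI stay in the denominator.
#'
#' @param records data.frame from [load_cohort()].
#' @return A list with `n`, `mean_age`, `sd_age`, and a named list of
#'   count/percentage tables per stratifier.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0L) stop("empty cohort")
  n <- nrow(records)
  count_pct <- function(values, levels) {
    cnt <- vapply(levels, function(l) sum(values == l), integer(1))
    data.frame(category = levels, count = cnt,
               pct = round(100 * cnt / n, 1), row.names = NULL)
  }
  histo_group <- ifelse(grepl("^endometrioid", records$histotype),
                        "endometrioid", "other")
  list(
    n = n,
    mean_age = round(mean(records$age), 1),
    sd_age = if (n == 1L) 0 else round(stats::sd(records$age), 1),
    menopause = count_pct(records$menopause, .cohort_levels$menopause),
    histotype_group = count_pct(histo_group, c("endometrioid", "other")),
    grade_class = count_pct(records$grade_class, c("LG", "HG")),
    figo = count_pct(records$figo, .cohort_levels$figo),
    myometrial_invasion = count_pct(records$myometrial_invasion,
                                    .cohort_levels$myometrial_invasion),
    lvi = count_pct(records$lvi, .cohort_levels$lvi)
  )
}
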