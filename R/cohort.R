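#' Load the 86-patient OSCC cohort table
#'
#' Reads and validates the cohort of 86 oral squamous cell carcinoma patients
#' who received preoperative chemotherapy and/or radiotherapy: 18 learning
#' cases (9 resistant, 9 sensitive) and 68 test cases (25 resistant, 43
#' sensitive). Each record carries the immunohistochemistry measurements
#' (`g7s_percent`, the galectin-7 stained-area measure on the printed 0-100
#' scale, and `g7nl_grade`, the ordinal nuclear-staining grade 0/1/2), the
#' published linear prediction score, the therapy regimen code and the RECIST
#' response.
#'
#' Response code "NC" (no change, the older WHO nomenclature) is normalized
#' to RECIST "SD" on load. The resistant group (R) contains SD/PD responders,
#' the sensitive group (S) contains PR/CR responders; this consistency is
#' validated. Numeric columns accept both the ASCII hyphen and the Unicode
#' minus sign (U+2212).
#'
#' @param path Path to a delimited cohort table. `NULL` (default) loads the
#'   packaged fixture.
#' @return A `data.frame` with one row per patient, sorted by `patient_no`,
#'   with columns `patient_no`, `cohort` ("learning"/"test"), `group`
#'   ("R"/"S"), `sex`, `age`, `primary_site`, `differentiation`, `t_stage`,
#'   `n_stage`, `stage`, `g7s_percent`, `g7nl_grade`, `prediction_score`,
#'   `regimen`, `response`.
#' @seealso [load_peptide_table()], [recover_published_model()]
#' @examples
#' cohort <- load_cohort_table()
#' table(cohort$cohort, cohort$group)
#' @export
load_cohort_table <- function(path = NULL) {
  if (is.null(path)) path <- g7_extdata("table1_cohort.csv")
  d <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                colClasses = "character")

  required <- c("patient_no", "cohort", "group", "sex", "age", "primary_site",
                "differentiation", "t_stage", "n_stage", "stage",
                "g7s_percent", "g7nl_grade", "prediction_score", "regimen",
                "response")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("cohort table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  num <- function(x) as.numeric(gsub("−", "-", trimws(x)))
  d$patient_no <- num(d$patient_no)
  d$age <- num(d$age)
  d$g7s_percent <- num(d$g7s_percent)
  d$g7nl_grade <- num(d$g7nl_grade)
  d$prediction_score <- num(d$prediction_score)
  d$response <- ifelse(trimws(d$response) == "NC", "SD", trimws(d$response))
  d$cohort <- tolower(trimws(d$cohort))
  d$group <- trimws(d$group)

  bad_row <- function(i, field, why) {
    stop(sprintf("cohort table schema error: row %s (patient %s), field '%s': %s",
                 i, d$patient_no[i], field, why), call. = FALSE)
  }
  for (i in seq_len(nrow(d))) {
    if (is.na(d$patient_no[i])) bad_row(i, "patient_no", "not a number")
    if (!d$cohort[i] %in% c("learning", "test"))
      bad_row(i, "cohort", paste0("unknown cohort '", d$cohort[i], "'"))
    if (!d$group[i] %in% c("R", "S"))
      bad_row(i, "group", paste0("unknown group '", d$group[i], "'"))
    if (!d$response[i] %in% c("CR", "PR", "SD", "PD"))
      bad_row(i, "response", paste0("unknown response code '", d$response[i], "'"))
    if (is.na(d$g7nl_grade[i]) || !d$g7nl_grade[i] %in% c(0, 1, 2))
      bad_row(i, "g7nl_grade", "must be 0, 1 or 2")
    if (is.na(d$g7s_percent[i]) || d$g7s_percent[i] < 0 || d$g7s_percent[i] > 100)
      bad_row(i, "g7s_percent", "must lie in [0, 100]")
    if (is.na(d$prediction_score[i])) bad_row(i, "prediction_score", "not a number")
    ok <- if (d$group[i] == "R") d$response[i] %in% c("SD", "PD")
          else d$response[i] %in% c("PR", "CR")
    if (!ok) bad_row(i, "response",
                     paste0("response '", d$response[i],
                            "' inconsistent with group ", d$group[i]))
  }
  d$g7nl_grade <- as.integer(d$g7nl_grade)
  d <- d[order(d$patient_no), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Load the table of 20 differential peptide peaks
#'
#' Reads and validates the 20 LC-MS peptide peaks that survived the full
#' selection funnel (intensity lower in the resistant group, R/S ratio
#' at most 0.5), with their m/z, retention time, charge, UniProt annotation,
#' Mascot identification score, peptide sequence and per-group intensity
#' mean +/- SD. On load, every row is checked for consistency between the
#' printed R/S ratio and the printed group means: `round(r_mean / s_mean, 2)`
#' must equal `ratio_rs`.
#'
#' @param path Path to a delimited peptide table; `NULL` (default) loads the
#'   packaged fixture.
#' @return A `data.frame` with columns `peak_id`, `mz`, `rt_min`, `charge`,
#'   `ratio_rs`, `accession`, `protein`, `mascot_score`, `peptide_seq`,
#'   `r_mean`, `r_sd`, `s_mean`, `s_sd`.
#' @examples
#' peptides <- load_peptide_table()
#' subset(peptides, protein == "Galectin-7")
#' @export
load_peptide_table <- function(path = NULL) {
  if (is.null(path)) path <- g7_extdata("table2_peptides.csv")
  d <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("peak_id", "mz", "rt_min", "charge", "ratio_rs", "accession",
                "protein", "mascot_score", "peptide_seq",
                "r_mean", "r_sd", "s_mean", "s_sd")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("peptide table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(round(d$r_mean / d$s_mean, 2) != d$ratio_rs)
  if (length(bad))
    stop("peptide table validation error: R/S ratio inconsistent with group ",
         "means for peak id(s) ", paste(d$peak_id[bad], collapse = ", "),
         call. = FALSE)
  d
}
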