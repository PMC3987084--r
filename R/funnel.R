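#' Staged marker-selection funnel over peak statistics
#'
#' Applies the four screening stages used to narrow differential LC-MS peaks
#' down to candidate resistance markers:
#'
#' 1. `differential`: Mann-Whitney `p_value < p_max` and `auc_sym > auc_min`;
#' 2. `identified`: Mascot identification score `> mascot_min` (peaks without
#'    an annotation fail this stage);
#' 3. `non_abundant`: protein description does not contain (case-insensitive)
#'    any of the excluded abundant-protein families;
#' 4. `suppressed_in_R`: R/S intensity ratio `<= ratio_max` (peaks with an
#'    undefined ratio, `mean_S = 0`, fail).
#'
#' Stages are applied in order, so survivors at each stage are a subset of
#' the previous stage's survivors.
#'
#' @param stats `data.frame` from [compute_peak_statistics()].
#' @param annotations `data.frame` with columns `peak_id`, `mascot_score`,
#'   `protein`; may cover only a subset of peaks.
#' @param p_max,auc_min,mascot_min,ratio_max Stage thresholds; defaults
#'   P < 0.05, AUC > 0.7, Mascot > 50, ratio <= 0.5.
#' @param excluded_proteins Case-insensitive substrings that disqualify a
#'   protein at stage 3.
#' @return An object of class `funnel_report`: list with `input_n`, `params`
#'   and `stages`, each stage holding `name`, `survivors` (peak ids) and `n`.
#' @export
funnel_filter <- function(stats, annotations,
                          p_max = 0.05, auc_min = 0.7,
                          mascot_min = 50, ratio_max = 0.5,
                          excluded_proteins = c("keratin", "fibrinogen",
                                                "collagen", "histone")) {
  stopifnot(is.data.frame(stats), all(c("peak_id", "p_value", "auc_sym",
                                        "ratio_rs") %in% names(stats)))
  ann <- annotations
  mascot <- setNames(rep(NA_real_, nrow(stats)), stats$peak_id)
  protein <- setNames(rep(NA_character_, nrow(stats)), stats$peak_id)
  if (!is.null(ann) && nrow(ann)) {
    idx <- match(ann$peak_id, stats$peak_id)
    keep <- !is.na(idx)
    mascot[idx[keep]] <- ann$mascot_score[keep]
    protein[idx[keep]] <- ann$protein[keep]
  }

  s1 <- stats$peak_id[stats$p_value < p_max & stats$auc_sym > auc_min]
  in1 <- stats$peak_id %in% s1
  s2 <- stats$peak_id[in1 & !is.na(mascot) & mascot > mascot_min]
  in2 <- stats$peak_id %in% s2
  excl <- rep(FALSE, nrow(stats))
  for (pat in excluded_proteins)
    excl <- excl | grepl(pat, protein, ignore.case = TRUE, fixed = FALSE)
  s3 <- stats$peak_id[in2 & !excl]
  in3 <- stats$peak_id %in% s3
  s4 <- stats$peak_id[in3 & !is.na(stats$ratio_rs) & stats$ratio_rs <= ratio_max]

  structure(list(
    input_n = nrow(stats),
    params = list(p_max = p_max, auc_min = auc_min, mascot_min = mascot_min,
                  ratio_max = ratio_max, excluded_proteins = excluded_proteins),
    stages = list(
      list(name = "differential",   survivors = s1, n = length(s1)),
      list(name = "identified",     survivors = s2, n = length(s2)),
      list(name = "non_abundant",   survivors = s3, n = length(s3)),
      list(name = "suppressed_in_R", survivors = s4, n = length(s4)))),
    class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("funnel_report: %d input peaks\n", x$input_n))
  for (s in x$stages)
    cat(sprintf("  %-16s %6d survivors\n", s$name, s$n))
  invisible(x)
}

#' Surviving peak ids at a funnel stage
#'
#' @param report A `funnel_report`.
#' @param stage Stage name or index; defaults to the final stage.
#' @return Integer vector of surviving peak ids.
#' @export
funnel_survivors <- function(report, stage = length(report$stages)) {
  stopifnot(inherits(report, "funnel_report"))
  if (is.character(stage))
    stage <- match(stage, vapply(report$stages, `[[`, "", "name"))
  if (is.na(stage) || stage < 1 || stage > length(report$stages))
    stop("unknown funnel stage", call. = FALSE)
  report$stages[[stage]]$survivors
}

#' Serialize a funnel report to JSON
#'
#' @param report A `funnel_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_funnel_report <- function(report, path) {
  stopifnot(inherits(report, "funnel_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
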