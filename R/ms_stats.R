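#' Per-peak group statistics: Mann-Whitney P, ROC AUC and R/S ratio
#'
#' For every peak, compares intensities between the resistant (R) and
#' sensitive (S) groups. The two-sided Mann-Whitney U test is exact
#' (enumeration) when both groups have at most 12 samples and there are no
#' tied intensities, and otherwise uses the normal approximation with tie
#' correction. The AUC is the probability that a random S intensity exceeds
#' a random R intensity (ties count 1/2); `auc_sym = max(auc, 1 - auc)` is
#' the direction-free version used by the screening funnel so markers
#' elevated in either group are eligible. The R/S ratio is
#' `mean_R / mean_S`, flagged undefined when `mean_S` is 0.
#'
#' @param matrix A `peak_matrix` with `sample_groups` labels ("R"/"S").
#' @param test `"mann_whitney"` (default) or `"t_test"` for Welch's t-test
#'   p-values (the screening statistic stays rank-based by default).
#' @return `data.frame` with one row per peak: `peak_id`, `p_value`, `auc`,
#'   `auc_sym`, `ratio_rs`, `ratio_defined`, `r_mean`, `r_sd`, `s_mean`,
#'   `s_sd`.
#' @export
compute_peak_statistics <- function(matrix, test = c("mann_whitney", "t_test")) {
  stopifnot(inherits(matrix, "peak_matrix"))
  test <- match.arg(test)
  g <- matrix$sample_groups
  if (is.null(g)) stop("peak matrix carries no sample group labels", call. = FALSE)
  if (!all(g %in% c("R", "S")))
    stop("sample groups must be 'R' or 'S'", call. = FALSE)
  r_cols <- names(g)[g == "R"]
  s_cols <- names(g)[g == "S"]
  if (length(r_cols) < 2 || length(s_cols) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)
  m <- matrix$intensities

  one <- function(i) {
    xr <- m[i, r_cols]
    xs <- m[i, s_cols]
    p <- if (test == "t_test") {
      if (sd(xr) == 0 && sd(xs) == 0) 1 else t.test(xs, xr)$p.value
    } else {
      exact <- length(xr) <= 12 && length(xs) <= 12 &&
        !anyDuplicated(c(xr, xs))
      suppressWarnings(
        wilcox.test(xs, xr, exact = exact, correct = !exact)$p.value)
    }
    a <- auc_s_over_r(xr, xs)
    c(p_value = unname(p), auc = a, auc_sym = max(a, 1 - a),
      r_mean = mean(xr), r_sd = sd(xr), s_mean = mean(xs), s_sd = sd(xs))
  }
  st <- t(vapply(seq_len(nrow(m)), one, numeric(7)))
  out <- data.frame(peak_id = matrix$peak_meta$peak_id, st)
  out$ratio_defined <- out$s_mean > 0
  out$ratio_rs <- ifelse(out$ratio_defined, out$r_mean / out$s_mean, NA_real_)
  out$p_value[is.nan(out$p_value)] <- 1 # all-constant peak: no evidence
  rownames(out) <- NULL
  out
}

# AUC = P(S > R) + P(S = R)/2, via the rank-sum identity
auc_s_over_r <- function(xr, xs) {
  r <- rank(c(xs, xr))
  u_s <- sum(r[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
  u_s / (length(xs) * length(xr))
}
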