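#' Construct a G7PS discriminant model
#'
#' The galectin-7 prediction score is the linear combination
#' `G7PS = intercept + coef_g7s * G7S + coef_g7nl * G7NL`, with G7S on the
#' printed percent-like 0-100 scale and G7NL the ordinal grade 0/1/2.
#' Scores below 0 predict treatment resistance; scores at or above 0 predict
#' sensitivity.
#'
#' @param intercept,coef_g7s,coef_g7nl Model coefficients.
#' @param source `"fitted_lda"` or `"recovered_ols"`.
#' @param training_n Number of records the model was derived from.
#' @return Object of class `g7ps_model`.
#' @export
g7ps_model <- function(intercept, coef_g7s, coef_g7nl,
                       source = c("fitted_lda", "recovered_ols"),
                       training_n = NA_integer_) {
  source <- match.arg(source)
  stopifnot(is.finite(intercept), is.finite(coef_g7s), is.finite(coef_g7nl))
  structure(list(intercept = intercept, coef_g7s = coef_g7s,
                 coef_g7nl = coef_g7nl, source = source,
                 training_n = training_n),
            class = "g7ps_model")
}

#' @export
print.g7ps_model <- function(x, ...) {
  cat(sprintf("G7PS model (%s, n = %s):\n  score = %.4f + %.4f * G7S %+.4f * G7NL\n",
              x$source, x$training_n, x$intercept, x$coef_g7s, x$coef_g7nl))
  cat("  score < 0 predicts resistance; score >= 0 predicts sensitivity\n")
  invisible(x)
}

#' Evaluate the G7PS for given staining measurements
#'
#' @param model A `g7ps_model`.
#' @param g7s_percent G7S on the 0-100 percent scale (multiply an IHC
#'   fraction by 100 at this boundary).
#' @param g7nl_grade Ordinal grade in `{0, 1, 2}`.
#' @return Numeric score vector (G7PS).
#' @export
g7ps_score <- function(model, g7s_percent, g7nl_grade) {
  stopifnot(inherits(model, "g7ps_model"))
  if (any(is.na(g7s_percent)) || any(g7s_percent < 0 | g7s_percent > 100))
    stop("g7s_percent must lie in [0, 100]", call. = FALSE)
  if (any(is.na(g7nl_grade)) || any(!g7nl_grade %in% c(0, 1, 2)))
    stop("g7nl_grade must be 0, 1 or 2", call. = FALSE)
  model$intercept + model$coef_g7s * g7s_percent + model$coef_g7nl * g7nl_grade
}

#' Classify G7PS scores at the zero boundary
#'
#' @param score Numeric G7PS values.
#' @return Character vector, `"resistant"` for `score < 0`, else
#'   `"sensitive"` (a score of exactly 0 predicts sensitivity).
#' @export
classify_g7ps <- function(score) {
  ifelse(score < 0, "resistant", "sensitive")
}

#' Recover the published G7PS coefficients from the cohort table
#'
#' The published formula is recovered from the data rather than transcribed:
#' ordinary least squares of the printed prediction scores on
#' (`g7s_percent`, `g7nl_grade`) over the cohort records. On the packaged
#' 86-patient table the fit is essentially exact (all residuals below 0.03,
#' the rounding precision of the printed scores), and the intercept is
#' pinned at -1.97 by the three patients with G7S = 0 and G7NL = 0.
#'
#' @param cohort `data.frame` from [load_cohort_table()] (or any table with
#'   `g7s_percent`, `g7nl_grade`, `prediction_score`).
#' @return A `g7ps_model` with `source = "recovered_ols"` and the fit
#'   residuals in attribute `"residuals"`.
#' @export
recover_published_model <- function(cohort) {
  stopifnot(all(c("g7s_percent", "g7nl_grade", "prediction_score") %in%
                  names(cohort)))
  if (nrow(cohort) < 3)
    stop("need at least 3 records to recover the model", call. = FALSE)
  fit <- lm(prediction_score ~ g7s_percent + g7nl_grade, data = cohort)
  if (fit$rank < 3)
    stop("rank-deficient design: predictors do not span (G7S, G7NL)",
         call. = FALSE)
  b <- coef(fit)
  m <- g7ps_model(b[["(Intercept)"]], b[["g7s_percent"]], b[["g7nl_grade"]],
                  source = "recovered_ols", training_n = nrow(cohort))
  attr(m, "residuals") <- unname(resid(fit))
  m
}

#' Fit a two-group Fisher linear discriminant on (G7S, G7NL)
#'
#' Fisher's linear discriminant with equal priors and pooled within-group
#' covariance on the features (`g7s_percent`, `g7nl_grade`). The score is
#' calibrated so the decision boundary (the midpoint of the two group mean
#' scores) sits at 0 and group S scores positive, matching the G7PS
#' convention that negative scores predict resistance.
#'
#' @param learning Cohort records with a `group` column ("R"/"S").
#' @return A `g7ps_model` with `source = "fitted_lda"`.
#' @export
fit_discriminant <- function(learning) {
  stopifnot(all(c("g7s_percent", "g7nl_grade", "group") %in% names(learning)))
  grp <- learning$group
  if (!all(c("R", "S") %in% grp))
    stop("both groups must be present in the learning set", call. = FALSE)
  x <- cbind(g7s = learning$g7s_percent, g7nl = learning$g7nl_grade)
  xr <- x[grp == "R", , drop = FALSE]
  xs <- x[grp == "S", , drop = FALSE]
  mu_r <- colMeans(xr)
  mu_s <- colMeans(xs)
  sp <- (crossprod(scale(xr, scale = FALSE)) +
           crossprod(scale(xs, scale = FALSE))) / (nrow(x) - 2)
  if (abs(det(sp)) < 1e-10 * max(1, prod(diag(sp))))
    stop("singular pooled within-group covariance; jitter the features or ",
         "drop a collinear one", call. = FALSE)
  w <- solve(sp, mu_s - mu_r)       # points toward group S
  b0 <- -sum(w * (mu_s + mu_r) / 2) # zero boundary at the midpoint
  g7ps_model(b0, w[["g7s"]], w[["g7nl"]], source = "fitted_lda",
             training_n = nrow(x))
}

#' Confusion-matrix evaluation of resistance predictions
#'
#' Resistance is the positive class: sensitivity = TP / (TP + FN) over true
#' group-R records, specificity = TN / (TN + FP) over true group-S records.
#'
#' @param predicted Character vector, `"resistant"` / `"sensitive"` (e.g.
#'   from [classify_g7ps()]).
#' @param truth Character vector of true groups, `"R"` / `"S"`.
#' @param cutoff The operating cutoff the predictions used (recorded in the
#'   summary; default 0, the G7PS boundary).
#' @return Object of class `g7ps_performance`: list with `tp`, `fn`, `tn`,
#'   `fp`, `sensitivity`, `specificity` (proportions; `NA` flagged when a
#'   truth class is absent) and `cutoff`.
#' @export
evaluate_predictions <- function(predicted, truth, cutoff = 0) {
  if (!length(predicted)) stop("no predictions to evaluate", call. = FALSE)
  stopifnot(length(predicted) == length(truth),
            all(predicted %in% c("resistant", "sensitive")),
            all(truth %in% c("R", "S")))
  tp <- sum(predicted == "resistant" & truth == "R")
  fn <- sum(predicted == "sensitive" & truth == "R")
  tn <- sum(predicted == "sensitive" & truth == "S")
  fp <- sum(predicted == "resistant" & truth == "S")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens)) warning("no true resistant records; sensitivity undefined")
  if (is.na(spec)) warning("no true sensitive records; specificity undefined")
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec, cutoff = cutoff),
            class = "g7ps_performance")
}

#' @export
print.g7ps_performance <- function(x, ...) {
  cat(sprintf("confusion (resistant = positive): TP %d  FN %d  TN %d  FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  (cutoff %g)\n",
              100 * x$sensitivity, 100 * x$specificity, x$cutoff))
  invisible(x)
}

#' Youden-optimal operating cutoff for a single marker
#'
#' Evaluates every midpoint between adjacent distinct sorted marker values
#' (plus -Inf and +Inf) and picks the cutoff maximizing
#' sensitivity + specificity. With `direction = "low_predicts_R"` a value
#' below the cutoff predicts resistance. Ties are broken toward higher
#' specificity, then toward the lower cutoff. The returned cutoff is the
#' midpoint of the two bracketing observed values.
#'
#' @param values Numeric marker values (e.g. G7S fractions).
#' @param labels True groups, `"R"` / `"S"`.
#' @param direction `"low_predicts_R"` (default) or `"high_predicts_R"`.
#' @return List with `cutoff`, `sensitivity`, `specificity` (proportions).
#' @export
optimal_cutoff <- function(values, labels,
                           direction = c("low_predicts_R", "high_predicts_R")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels), all(labels %in% c("R", "S")))
  if (!all(c("R", "S") %in% labels))
    stop("both labels must be present", call. = FALSE)
  v <- sort(unique(values))
  if (length(v) < 2) {
    warning("constant marker values; returning a degenerate cutoff")
    cands <- c(-Inf, Inf)
  } else {
    cands <- c(-Inf, (head(v, -1) + tail(v, -1)) / 2, Inf)
  }
  is_r <- labels == "R"
  best <- NULL
  for (cut in cands) {
    pred_r <- if (direction == "low_predicts_R") values < cut else values > cut
    sens <- mean(pred_r[is_r])
    spec <- mean(!pred_r[!is_r])
    cand <- c(youden = sens + spec, spec = spec, cut = cut,
              sens = sens)
    if (is.null(best) ||
        cand["youden"] > best["youden"] + 1e-12 ||
        (abs(cand["youden"] - best["youden"]) <= 1e-12 &&
         (cand["spec"] > best["spec"] + 1e-12 ||
          (abs(cand["spec"] - best["spec"]) <= 1e-12 &&
           cand["cut"] < best["cut"]))))
      best <- cand
  }
  list(cutoff = unname(best["cut"]), sensitivity = unname(best["sens"]),
       specificity = unname(best["spec"]))
}

#' Serialize a G7PS model to JSON
#'
#' @param model A `g7ps_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_g7ps_model <- function(model, path) {
  stopifnot(inherits(model, "g7ps_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a G7PS model from JSON
#'
#' @param path JSON file written by [write_g7ps_model()].
#' @return A `g7ps_model`.
#' @export
read_g7ps_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g7ps_model(x$intercept, x$coef_g7s, x$coef_g7nl, source = x$source,
             training_n = x$training_n)
}
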