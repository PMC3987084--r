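#' Kaplan-Meier product-limit estimator
#'
#' Product-limit estimate of the survival function with Greenwood variance,
#' implemented from first principles. At tied times, events are handled
#' before censorings (subjects censored at an event time still count as at
#' risk for that event).
#'
#' @param time Positive follow-up times (months).
#' @param event Logical (or 0/1): `TRUE` for an observed event (e.g.
#'   disease-specific death), `FALSE` for censoring.
#' @return Object of class `km_curve`: `data.frame` with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `greenwood_var`), plus attribute `"n"`.
#' @examples
#' km <- kaplan_meier(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
#' km$surv
#' @export
kaplan_meier <- function(time, event) {
  event <- as.logical(event)
  if (length(time) == 0) stop("no survival records", call. = FALSE)
  if (any(is.na(time)) || any(time <= 0))
    stop("survival times must be positive", call. = FALSE)
  stopifnot(length(time) == length(event), !any(is.na(event)))
  ut <- sort(unique(time[event]))
  n <- length(time)
  surv <- 1
  gw_sum <- 0
  rows <- lapply(ut, function(t0) {
    n_risk <- sum(time >= t0)
    d <- sum(time == t0 & event)
    cns <- sum(time == t0 & !event)
    surv <<- surv * (1 - d / n_risk)
    gw_sum <<- gw_sum + if (n_risk > d) d / (n_risk * (n_risk - d)) else 0
    data.frame(time = t0, n_risk = n_risk, n_event = d, n_censor = cns,
               surv = surv, greenwood_var = surv^2 * gw_sum)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(), n_risk = integer(), n_event = integer(),
               n_censor = integer(), surv = numeric(),
               greenwood_var = numeric())
  structure(out, class = c("km_curve", "data.frame"), n = n)
}

#' Two-group log-rank test
#'
#' Standard (Mantel-Cox) log-rank statistic with 1 degree of freedom: at
#' each distinct event time the observed number of events in group A is
#' compared with its hypergeometric expectation given the risk sets, and
#' the squared standardized sum is referred to the chi-square upper tail.
#'
#' @param time,event Survival times and event indicators for all subjects.
#' @param group Two-level group labels (factor or character).
#' @return List with `chi_square`, `p_value`, `observed` and `expected`
#'   per-group event counts.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0)) stop("survival times must be positive", call. = FALSE)
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  if (!any(event)) {
    warning("no events; log-rank statistic is 0")
    return(list(chi_square = 0, p_value = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  ut <- sort(unique(time[event]))
  o1 <- e1 <- v <- 0
  obs <- c(0, 0)
  for (t0 in ut) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(time == t0 & event)
    d1 <- sum(time == t0 & event & g == levels(g)[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    obs <- obs + c(d1, d - d1)
  }
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE),
       observed = setNames(obs, levels(g)),
       expected = setNames(c(e1, sum(obs) - e1), levels(g)))
}

#' Survival probability at five years
#'
#' Reads the Kaplan-Meier estimate at 60 months: the last estimated value
#' at or before `t`, or 1 if no event occurred by then.
#'
#' @param curve A `km_curve`.
#' @param t Time in months (default 60 = 5 years).
#' @return Estimated survival probability at `t`.
#' @export
five_year_survival <- function(curve, t = 60) {
  stopifnot(inherits(curve, "km_curve"))
  before <- curve$time <= t
  if (!any(before)) 1 else curve$surv[max(which(before))]
}

#' Export a Kaplan-Meier curve as TSV
#'
#' @param curve A `km_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  write.table(as.data.frame(curve), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
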