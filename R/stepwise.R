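#' Stepwise discriminant marker selection by Wilks' lambda
#'
#' Forward-backward stepwise selection of peaks that jointly discriminate
#' the R and S groups, minimizing Wilks' lambda (the ratio of within-group
#' to total generalized variance). At each step the candidate with the
#' largest partial F-to-enter is added if it reaches `f_enter`; then any
#' entered variable whose partial F-to-remove falls below `f_remove` is
#' dropped (smallest first). Ties are broken toward the smaller peak id.
#' The defaults 3.84 / 2.71 are the conventional stepwise thresholds (the
#' 5% and 10% chi-square critical values with 1 df).
#'
#' Partial F for moving between nested variable sets of sizes p and p+1
#' (g groups, n samples):
#' `F = ((n - g - p) / (g - 1)) * (lambda_p / lambda_{p+1} - 1)`.
#'
#' Candidates whose addition makes the within-group scatter matrix singular
#' are skipped with a warning.
#'
#' @param matrix A `peak_matrix` with group labels.
#' @param candidate_ids Peak ids eligible for selection (default: all).
#' @param f_enter,f_remove F-to-enter and F-to-remove thresholds; `f_remove`
#'   must be below `f_enter` to prevent cycling.
#' @param max_steps Maximum number of enter/remove sweeps (default 50).
#' @return Integer vector of selected peak ids in entry order, with the
#'   final Wilks' lambda as attribute `"wilks_lambda"`.
#' @export
stepwise_discriminant_select <- function(matrix, candidate_ids = NULL,
                                         f_enter = 3.84, f_remove = 2.71,
                                         max_steps = 50) {
  stopifnot(inherits(matrix, "peak_matrix"))
  if (f_remove >= f_enter)
    stop("f_remove must be smaller than f_enter", call. = FALSE)
  g <- matrix$sample_groups
  if (is.null(g)) stop("peak matrix carries no sample group labels", call. = FALSE)
  ids <- matrix$peak_meta$peak_id
  if (is.null(candidate_ids)) candidate_ids <- ids
  if (!all(candidate_ids %in% ids))
    stop("candidate ids not present in the peak matrix", call. = FALSE)
  candidate_ids <- sort(candidate_ids)

  x <- t(matrix$intensities[match(candidate_ids, ids), , drop = FALSE])
  colnames(x) <- as.character(candidate_ids)
  grp <- factor(g[rownames(x)])
  n <- nrow(x); ng <- nlevels(grp)
  if (ng < 2) stop("both groups must be present", call. = FALSE)

  # within-group and total SSCP over all candidates, subset as needed
  xc_tot <- scale(x, center = TRUE, scale = FALSE)
  t_sscp <- crossprod(xc_tot)
  w_sscp <- matrix(0, ncol(x), ncol(x))
  for (lv in levels(grp)) {
    xg <- x[grp == lv, , drop = FALSE]
    xg <- scale(xg, center = TRUE, scale = FALSE)
    w_sscp <- w_sscp + crossprod(xg)
  }

  wilks <- function(set) {
    if (!length(set)) return(1)
    dw <- det(w_sscp[set, set, drop = FALSE])
    dt <- det(t_sscp[set, set, drop = FALSE])
    if (!is.finite(dw) || !is.finite(dt) || dt <= 0) return(NA_real_)
    if (dw < 0) dw <- 0
    dw / dt
  }

  entered <- integer(0) # column indices, in entry order
  lambda <- 1
  warned_singular <- character(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    p <- length(entered)
    pool <- setdiff(seq_along(candidate_ids), entered)
    if (length(pool) && n - ng - p > 0) {
      f_add <- vapply(pool, function(j) {
        lam_new <- wilks(c(entered, j))
        if (is.na(lam_new) || lam_new <= .Machine$double.eps^0.9)
          return(NA_real_)
        ((n - ng - p) / (ng - 1)) * (lambda / lam_new - 1)
      }, numeric(1))
      singular <- pool[is.na(f_add)]
      if (length(singular)) {
        fresh <- setdiff(as.character(candidate_ids[singular]), warned_singular)
        if (length(fresh)) {
          warning("candidate peak(s) skipped, singular within-group scatter: ",
                  paste(fresh, collapse = ", "))
          warned_singular <- c(warned_singular, fresh)
        }
      }
      ok <- which(!is.na(f_add))
      if (length(ok)) {
        best <- ok[order(-f_add[ok], candidate_ids[pool[ok]])][1]
        if (f_add[best] >= f_enter) {
          entered <- c(entered, pool[best])
          lambda <- wilks(entered)
          changed <- TRUE
        }
      }
    }
    # backward sweep: drop weakest entered variable while below f_remove
    repeat {
      p <- length(entered)
      if (p == 0) break
      f_rm <- vapply(seq_along(entered), function(k) {
        lam_without <- wilks(entered[-k])
        ((n - ng - p + 1) / (ng - 1)) * (lam_without / lambda - 1)
      }, numeric(1))
      worst <- order(f_rm, candidate_ids[entered])[1]
      if (f_rm[worst] < f_remove) {
        entered <- entered[-worst]
        lambda <- wilks(entered)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  structure(candidate_ids[entered], wilks_lambda = lambda)
}
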