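#' Align peak observations across LC-MS runs into a peak-by-sample matrix
#'
#' Greedy centroid clustering of peak observations from multiple runs.
#' Observations are processed in descending intensity order (ties broken
#' deterministically by m/z, retention time, sample and replicate, so the
#' result is invariant to the input row order). Each observation joins the
#' nearest existing cluster whose intensity-weighted centroid lies within
#' `mz_tol` in m/z and `rt_tol` in retention time and whose charge matches;
#' otherwise it seeds a new cluster. After clustering, serial peak ids are
#' assigned in descending cluster total intensity, and duplicate runs of the
#' same sample within a cluster are averaged into one column entry. A missing
#' observation (sample never seen in a cluster) is encoded as intensity 0,
#' i.e. a detection failure, not `NA`.
#'
#' @param observations `data.frame` with columns `sample_id`, `replicate`,
#'   `mz`, `rt_min`, `charge`, `intensity`.
#' @param mz_tol,rt_tol Alignment tolerances (+/- m/z units, +/- minutes).
#'   Defaults 0.5 m/z and 0.4 min.
#' @param sample_groups Optional named character vector mapping sample id to
#'   group label ("R"/"S"); required later by [compute_peak_statistics()].
#' @return An object of class `peak_matrix`: a list with `peak_meta`
#'   (`data.frame` of `peak_id`, consensus `mz`, `rt_min`, `charge`,
#'   `n_obs`), `intensities` (peaks x samples numeric matrix),
#'   `sample_groups`, `normalized` flag, and attribute-like element
#'   `assignment` giving the assigned peak id for every input row.
#' @examples
#' obs <- data.frame(sample_id = c("a", "b"), replicate = 1,
#'                   mz = c(619.8, 619.9), rt_min = c(43.9, 44.0),
#'                   charge = 2, intensity = c(100, 90))
#' align_peaks(obs)$peak_meta
#' @export
align_peaks <- function(observations, mz_tol = 0.5, rt_tol = 0.4,
                        sample_groups = NULL) {
  if (mz_tol <= 0 || rt_tol <= 0)
    stop("alignment tolerances must be positive", call. = FALSE)
  req <- c("sample_id", "replicate", "mz", "rt_min", "charge", "intensity")
  if (nrow(observations) == 0 || length(observations) == 0) {
    return(new_peak_matrix(
      peak_meta = data.frame(peak_id = integer(), mz = numeric(),
                             rt_min = numeric(), charge = integer(),
                             n_obs = integer()),
      intensities = matrix(numeric(), 0, 0),
      sample_groups = sample_groups, assignment = integer()))
  }
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols))
    stop("observations missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(observations$intensity < 0))
    stop("intensities must be nonnegative", call. = FALSE)

  ord <- order(-observations$intensity, observations$mz, observations$rt_min,
               observations$sample_id, observations$replicate)
  mz <- observations$mz[ord]
  rt <- observations$rt_min[ord]
  ch <- observations$charge[ord]
  it <- observations$intensity[ord]
  n <- length(mz)

  # cluster state: weighted centroids, per-charge index for vectorized lookup
  c_mz <- numeric(n); c_rt <- numeric(n); c_wt <- numeric(n)
  c_tot <- numeric(n); c_ch <- integer(n)
  k <- 0L
  member <- integer(n) # cluster index per (sorted) observation
  by_charge <- list()  # charge -> integer vector of cluster indices

  for (i in seq_len(n)) {
    key <- as.character(ch[i])
    cand <- by_charge[[key]]
    j <- 0L
    if (length(cand)) {
      dmz <- abs(mz[i] - c_mz[cand])
      drt <- abs(rt[i] - c_rt[cand])
      ok <- dmz <= mz_tol & drt <= rt_tol
      if (any(ok)) {
        score <- dmz[ok] / mz_tol + drt[ok] / rt_tol
        j <- cand[ok][which.min(score)]
      }
    }
    if (j == 0L) {
      k <- k + 1L
      j <- k
      c_ch[j] <- ch[i]
      by_charge[[key]] <- c(cand, j)
    }
    # intensity-weighted running centroid; weight floor keeps zero-intensity
    # observations from producing 0/0
    w <- max(it[i], .Machine$double.eps)
    c_mz[j] <- (c_mz[j] * c_wt[j] + mz[i] * w) / (c_wt[j] + w)
    c_rt[j] <- (c_rt[j] * c_wt[j] + rt[i] * w) / (c_wt[j] + w)
    c_wt[j] <- c_wt[j] + w
    c_tot[j] <- c_tot[j] + it[i]
    member[i] <- j
  }

  # serial ids in descending cluster total intensity (ties: centroid m/z)
  rank_order <- order(-c_tot[seq_len(k)], c_mz[seq_len(k)], c_rt[seq_len(k)])
  new_id <- integer(k)
  new_id[rank_order] <- seq_len(k)
  peak_of_obs <- new_id[member]

  samples <- sort(unique(as.character(observations$sample_id)))
  intens <- matrix(0, nrow = k, ncol = length(samples),
                   dimnames = list(seq_len(k), samples))
  counts <- matrix(0L, nrow = k, ncol = length(samples))
  sid <- match(as.character(observations$sample_id)[ord], samples)
  for (i in seq_len(n)) {
    p <- peak_of_obs[i]
    intens[p, sid[i]] <- intens[p, sid[i]] + it[i]
    counts[p, sid[i]] <- counts[p, sid[i]] + 1L
  }
  nz <- counts > 0
  intens[nz] <- intens[nz] / counts[nz]

  meta <- data.frame(peak_id = seq_len(k),
                     mz = c_mz[seq_len(k)][rank_order],
                     rt_min = c_rt[seq_len(k)][rank_order],
                     charge = c_ch[seq_len(k)][rank_order],
                     n_obs = tabulate(peak_of_obs, k))

  assignment <- integer(n)
  assignment[ord] <- peak_of_obs
  new_peak_matrix(meta, intens, sample_groups, assignment)
}

new_peak_matrix <- function(peak_meta, intensities, sample_groups = NULL,
                            assignment = NULL, normalized = FALSE) {
  if (!is.null(sample_groups) && ncol(intensities) > 0) {
    missing_grp <- setdiff(colnames(intensities), names(sample_groups))
    if (length(missing_grp))
      stop("sample_groups lacks label(s) for: ",
           paste(missing_grp, collapse = ", "), call. = FALSE)
    sample_groups <- sample_groups[colnames(intensities)]
  }
  structure(list(peak_meta = peak_meta, intensities = intensities,
                 sample_groups = sample_groups, normalized = normalized,
                 assignment = assignment),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d peaks x %d samples (%s)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (isTRUE(x$normalized)) "normalized" else "raw"))
  if (!is.null(x$sample_groups))
    print(table(group = x$sample_groups))
  invisible(x)
}

#' Median-scale normalization of a peak matrix
#'
#' Rescales each sample column so that its median intensity, computed over
#' the peaks detected in every sample (no zero entries in the row), equals
#' the grand median of that fully-detected submatrix. Columns that are all
#' zero, or when no peak is detected in all samples, are left at scale 1
#' with a warning.
#'
#' @param matrix A `peak_matrix` from [align_peaks()].
#' @return The matrix with rescaled intensities and `normalized = TRUE`;
#'   the per-sample scale factors are stored in `$scale_factors`.
#' @export
normalize_intensities <- function(matrix) {
  stopifnot(inherits(matrix, "peak_matrix"))
  m <- matrix$intensities
  scales <- rep(1, ncol(m))
  names(scales) <- colnames(m)
  if (nrow(m) && ncol(m)) {
    full <- rowSums(m == 0) == 0
    if (!any(full)) {
      warning("no peak detected in all samples; intensities left unscaled")
    } else {
      sub <- m[full, , drop = FALSE]
      grand <- median(sub)
      col_med <- apply(sub, 2, median)
      zero_cols <- col_med <= 0
      if (any(zero_cols))
        warning("column(s) with zero median left unscaled: ",
                paste(colnames(m)[zero_cols], collapse = ", "))
      scales[!zero_cols] <- grand / col_med[!zero_cols]
      m <- sweep(m, 2, scales, `*`)
    }
  }
  out <- matrix
  out$intensities <- m
  out$normalized <- TRUE
  out$scale_factors <- scales
  out
}
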