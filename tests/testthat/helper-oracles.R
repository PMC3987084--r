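# Build a peak_matrix directly from an intensity matrix (rows = peaks).
make_peak_matrix <- function(m, groups = NULL) {
  rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  meta <- data.frame(peak_id = as.integer(rownames(m)),
                     mz = 400 + seq_len(nrow(m)) * 5,
                     rt_min = seq_len(nrow(m)), charge = 2L,
                     n_obs = ncol(m))
  g7ps:::new_peak_matrix(meta, m, sample_groups = groups)
}

two_group_matrix <- function(m, n_r = NULL) {
  if (is.null(n_r)) n_r <- ncol(m) / 2
  colnames(m) <- c(paste0("R", seq_len(n_r)), paste0("S", seq_len(ncol(m) - n_r)))
  groups <- setNames(rep(c("R", "S"), c(n_r, ncol(m) - n_r)), colnames(m))
  make_peak_matrix(m, groups)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of labelings.
mw_exact_p_enum <- function(x_r, x_s) {
  all_v <- c(x_s, x_r)
  n_s <- length(x_s)
  u_of <- function(idx) {
    s <- all_v[idx]; r <- all_v[-idx]
    sum(outer(s, r, ">")) + 0.5 * sum(outer(s, r, "=="))
  }
  u_obs <- u_of(seq_len(n_s))
  us <- combn(length(all_v), n_s, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exhaustive-search oracle for the Youden-optimal cutoff (low predicts R).
cutoff_oracle <- function(values, labels) {
  v <- sort(unique(values))
  cands <- c(-Inf, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2, Inf)
  rows <- t(sapply(cands, function(cut) {
    pred_r <- values < cut
    c(cut = cut, sens = mean(pred_r[labels == "R"]),
      spec = mean(!pred_r[labels == "S"]))
  }))
  rows <- as.data.frame(rows)
  rows$youden <- rows$sens + rows$spec
  rows <- rows[order(-rows$youden, -rows$spec, rows$cut), ]
  rows[1, ]
}

# Empirical group means per true peak of a generated dataset.
true_peak_ratios <- function(sim) {
  obs <- sim$observations
  grp <- sim$truth$sample_groups[obs$sample_id]
  r <- tapply(obs$intensity[grp == "R"], sim$truth$obs_peak[grp == "R"], mean)
  s <- tapply(obs$intensity[grp == "S"], sim$truth$obs_peak[grp == "S"], mean)
  unname(r / s)
}

# Map true peak index -> aligned peak id using the generator's bookkeeping.
truth_to_aligned <- function(sim, pm) {
  tapply(pm$assignment, sim$truth$obs_peak, function(x) x[1])
}
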