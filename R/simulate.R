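#' Simulate a two-group label-free LC-MS peak dataset
#'
#' Emulates the structure of the discovery experiment: two groups of
#' patients (default 9 resistant + 9 sensitive), each sample measured in
#' duplicate runs, peaks with lognormal intensities. Informative peaks are
#' suppressed in the resistant group (`mean_R = ratio_rs * mean_S`),
#' mirroring the 0.25-0.5 R/S ratios of the published differential
#' peptides; the remaining peaks share a common mean in both groups.
#' Per-peak base positions are drawn with m/z in `[400, 1600]` and
#' retention time in `[0, 60]` minutes and resampled until peaks of the same
#' charge are separated by more than 1.2 m/z or 1.0 min, so every true peak
#' is a resolvable species; each observation adds Gaussian m/z and RT
#' jitter.
#'
#' @param n_per_group Samples per group (default 9).
#' @param n_peaks Total number of true peaks.
#' @param n_informative Number of peaks suppressed in group R.
#' @param ratio_rs True R/S mean ratio of informative peaks (default 0.4).
#' @param cv Lognormal coefficient of variation of intensities (default 0.5).
#' @param mz_jitter,rt_jitter Per-observation jitter SDs (default 0.1 m/z,
#'   0.08 min).
#' @param duplicate_runs Runs per sample (default 2).
#' @param seed Integer seed; the dataset is a pure function of the
#'   parameters and the seed.
#' @return List with `observations` (`data.frame`: `sample_id`, `replicate`,
#'   `mz`, `rt_min`, `charge`, `intensity`) and `truth` (list: `seed`,
#'   `sample_groups`, `peaks` data.frame with true per-peak means, ratios
#'   and informative flags, and `obs_peak`, the true peak index of every
#'   observation row).
#' @export
generate_peak_dataset <- function(n_per_group = 9, n_peaks, n_informative,
                                  ratio_rs = 0.4, cv = 0.5,
                                  mz_jitter = 0.1, rt_jitter = 0.08,
                                  duplicate_runs = 2, seed = 1) {
  if (n_informative > n_peaks)
    stop("n_informative must not exceed n_peaks", call. = FALSE)
  if (ratio_rs <= 0 || ratio_rs > 1)
    stop("ratio_rs must lie in (0, 1]", call. = FALSE)
  if (cv <= 0 || n_per_group < 2 || duplicate_runs < 1)
    stop("invalid generator parameters", call. = FALSE)
  set.seed(seed)

  # resolvable base positions: same-charge peaks separated in (m/z, RT)
  mz <- runif(n_peaks, 400, 1600)
  rt <- runif(n_peaks, 0, 60)
  charge <- sample(1:3, n_peaks, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  repeat {
    clash <- rep(FALSE, n_peaks)
    for (i in seq_len(n_peaks)) {
      same <- charge == charge[i]
      same[i] <- FALSE
      if (any(same & abs(mz - mz[i]) <= 1.2 & abs(rt - rt[i]) <= 1.0))
        clash[i] <- TRUE
    }
    if (!any(clash)) break
    mz[clash] <- runif(sum(clash), 400, 1600)
    rt[clash] <- runif(sum(clash), 0, 60)
  }

  s_mean <- rlnorm(n_peaks, meanlog = log(1500), sdlog = 1)
  informative <- rep(FALSE, n_peaks)
  if (n_informative > 0)
    informative[sample.int(n_peaks, n_informative)] <- TRUE
  r_mean <- ifelse(informative, ratio_rs * s_mean, s_mean)

  samples <- c(paste0("R", seq_len(n_per_group)),
               paste0("S", seq_len(n_per_group)))
  groups <- setNames(rep(c("R", "S"), each = n_per_group), samples)

  sdlog <- sqrt(log(1 + cv^2))
  grid <- expand.grid(peak = seq_len(n_peaks), sample = samples,
                      replicate = seq_len(duplicate_runs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(groups[grid$sample] == "R", r_mean[grid$peak],
               s_mean[grid$peak])
  obs <- data.frame(
    sample_id = grid$sample,
    replicate = grid$replicate,
    mz = mz[grid$peak] + rnorm(nrow(grid), 0, mz_jitter),
    rt_min = pmax(0, rt[grid$peak] + rnorm(nrow(grid), 0, rt_jitter)),
    charge = charge[grid$peak],
    intensity = rlnorm(nrow(grid), meanlog = log(mu) - sdlog^2 / 2,
                       sdlog = sdlog))
  truth <- list(
    seed = seed,
    sample_groups = groups,
    peaks = data.frame(true_peak = seq_len(n_peaks), mz = mz, rt_min = rt,
                       charge = charge, s_mean = s_mean, r_mean = r_mean,
                       ratio_rs = r_mean / s_mean, informative = informative),
    obs_peak = grid$peak)
  list(observations = obs, truth = truth)
}

#' Simulate a DAB-stained tissue image with known ground truth
#'
#' Paints a synthetic hematoxylin + DAB immunohistochemistry image: an
#' elliptical tissue region on a white background, elliptical nuclei inside
#' it, and DAB staining allocated pixel by pixel to hit a target
#' stained-area fraction (`target_g7s`) and a target nuclear share of the
#' staining (`target_g7n`). Unstained tissue receives a hematoxylin
#' counterstain (nuclei darker than cytoplasm) and Gaussian pixel noise is
#' added. Nucleus sizes scale with the requested nuclear staining budget so
#' dense nuclear staining remains feasible; if the realized nucleus area
#' still cannot accommodate the requested nuclear stained pixels, an error
#' names the violated constraint.
#'
#' @param target_g7s Target stained-area fraction of the tissue, in `[0, 1]`.
#' @param target_g7n Target fraction of stained pixels inside nuclei.
#' @param n_nuclei Number of nuclei (default 150).
#' @param size Image size in pixels, `c(height, width)` (default 512 x 512).
#' @param noise_sd Gaussian noise SD on the 8-bit scale (default 4).
#' @param seed Integer seed.
#' @return List with `image` (RGB array in `[0, 255]`), `masks`
#'   (`tissue_mask`, `nuclei_mask` logical matrices) and `truth` (targets,
#'   realized pixel counts, seed).
#' @export
generate_ihc_image <- function(target_g7s, target_g7n, n_nuclei = 150,
                               size = c(512, 512), noise_sd = 4, seed = 1) {
  if (target_g7s < 0 || target_g7s > 1 || target_g7n < 0 || target_g7n > 1)
    stop("targets must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  h <- size[1]; w <- size[2]
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  tissue <- ((yy - h / 2) / (0.45 * h))^2 + ((xx - w / 2) / (0.45 * w))^2 <= 1
  tissue_px <- sum(tissue)

  stained_total <- round(target_g7s * tissue_px)
  stained_nuclear <- round(target_g7n * stained_total)

  # nucleus radius sized for the requested nuclear staining budget,
  # inflating for random-placement overlap (Poisson coverage)
  need_frac <- stained_nuclear / tissue_px
  cover <- min(0.80, max(0.12, 1.3 * need_frac))
  if (1.3 * need_frac > 0.80)
    stop("infeasible targets: nuclear stained area (target_g7s * target_g7n = ",
         signif(target_g7s * target_g7n, 3),
         " of tissue) exceeds the attainable nucleus coverage", call. = FALSE)
  lambda <- -log(1 - cover)
  r0 <- sqrt(lambda * tissue_px / (n_nuclei * pi))
  nuclei <- matrix(FALSE, h, w)
  inside <- which(tissue)
  centers <- inside[sample.int(length(inside), n_nuclei, replace = TRUE)]
  cy <- (centers - 1) %% h + 1
  cx <- (centers - 1) %/% h + 1
  for (i in seq_len(n_nuclei)) {
    a <- r0 * runif(1, 0.75, 1.25)
    b <- r0 * runif(1, 0.75, 1.25)
    th <- runif(1, 0, pi)
    dy <- yy - cy[i]; dx <- xx - cx[i]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    nuclei <- nuclei | ((u / a)^2 + (v / b)^2 <= 1)
  }
  nuclei <- nuclei & tissue

  if (stained_nuclear > sum(nuclei))
    stop("infeasible targets: target_g7n demands ", stained_nuclear,
         " nuclear stained pixels but only ", sum(nuclei),
         " nucleus pixels are available", call. = FALSE)
  extra_needed <- stained_total - stained_nuclear
  cyto <- tissue & !nuclei
  if (extra_needed > sum(cyto))
    stop("infeasible targets: extranuclear stained area exceeds the ",
         "available cytoplasmic pixels", call. = FALSE)

  stained <- matrix(FALSE, h, w)
  if (stained_nuclear > 0)
    stained[sample(which(nuclei), stained_nuclear)] <- TRUE
  if (extra_needed > 0)
    stained[sample(which(cyto), extra_needed)] <- TRUE

  # optical densities per pixel: DAB on stained, hematoxylin counterstain
  m <- g7_stain_matrix()
  n_px <- h * w
  od_h <- numeric(n_px); od_d <- numeric(n_px)
  od_h[tissue & !nuclei] <- 0.25
  od_h[nuclei] <- 0.60
  od_d[stained] <- pmax(0.5, rnorm(sum(stained), 1.0, 0.15))
  od_h[stained] <- od_h[stained] * 0.4 # chromogen partly masks counterstain
  od_rgb <- outer(od_h, m["hematoxylin", ]) + outer(od_d, m["dab", ])
  img <- 256 * 10^(-od_rgb) - 1
  img <- img + rnorm(length(img), 0, noise_sd)
  img <- array(pmin(255, pmax(0, img)), dim = c(h, w, 3))

  list(image = img,
       masks = list(tissue_mask = tissue, nuclei_mask = nuclei),
       truth = list(seed = seed, target_g7s = target_g7s,
                    target_g7n = target_g7n,
                    tissue_pixels = tissue_px,
                    stained_pixels = stained_total,
                    stained_nuclear_pixels = stained_nuclear,
                    nuclei_pixels = sum(nuclei)))
}

#' Simulate a two-stratum survival cohort calibrated by 5-year survival
#'
#' Exponential disease-specific event times per stratum, with the rate
#' chosen so that the true survival at 60 months equals the requested
#' 5-year value: `lambda = -log(s5) / 60`. A fraction `censor_rate` of
#' subjects receives an independent uniform censoring time on `(0, 120)`
#' months; everyone else is administratively censored at 120 months.
#'
#' @param n Number of subjects.
#' @param resistant_fraction Fraction in the predicted-resistant stratum.
#' @param s5_resistant,s5_sensitive True 5-year survival per stratum
#'   (defaults 0.752 and 0.999; an exact 1.0 has no exponential rate, hence
#'   the 0.001 offset).
#' @param censor_rate Fraction of subjects subject to early uniform
#'   censoring (default 0.2).
#' @param seed Integer seed.
#' @return List with `records` (`data.frame`: `subject_id`, `time`, `event`,
#'   `stratum`) and `truth` (rates, targets, seed).
#' @export
generate_survival_cohort <- function(n, resistant_fraction,
                                     s5_resistant = 0.752,
                                     s5_sensitive = 0.999,
                                     censor_rate = 0.2, seed = 1) {
  if (s5_resistant <= 0 || s5_resistant > 1 ||
      s5_sensitive <= 0 || s5_sensitive > 1)
    stop("5-year survival fractions must lie in (0, 1]", call. = FALSE)
  if (s5_resistant == 1 || s5_sensitive == 1)
    stop("an exact 5-year survival of 1 has no exponential rate; ",
         "use a value just below 1", call. = FALSE)
  if (resistant_fraction < 0 || resistant_fraction > 1 ||
      censor_rate < 0 || censor_rate > 1 || n < 1)
    stop("invalid generator parameters", call. = FALSE)
  set.seed(seed)
  follow_max <- 120
  n_r <- round(n * resistant_fraction)
  stratum <- c(rep("predicted_resistant", n_r),
               rep("predicted_sensitive", n - n_r))
  lam <- ifelse(stratum == "predicted_resistant",
                -log(s5_resistant) / 60, -log(s5_sensitive) / 60)
  t_event <- rexp(n, rate = lam)
  censored_early <- runif(n) < censor_rate
  c_time <- ifelse(censored_early, runif(n, 0, follow_max), follow_max)
  time <- pmin(t_event, c_time)
  records <- data.frame(subject_id = seq_len(n),
                        time = pmax(time, .Machine$double.eps),
                        event = t_event <= c_time,
                        stratum = stratum)
  truth <- list(seed = seed, n = n, resistant_fraction = resistant_fraction,
                s5_resistant = s5_resistant, s5_sensitive = s5_sensitive,
                rate_resistant = -log(s5_resistant) / 60,
                rate_sensitive = -log(s5_sensitive) / 60,
                censor_rate = censor_rate, follow_max = follow_max)
  list(records = records, truth = truth)
}

#' Write / read a generator truth object as JSON
#'
#' Truth objects accompany every generated dataset so downstream recovery
#' can be scored; these helpers round-trip them losslessly through JSON.
#'
#' @param truth Truth list from a generator.
#' @param path JSON path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the truth list.
#' @export
write_truth <- function(truth, path) {
  # named atomic vectors become JSON objects so names survive; 17 significant
  # digits round-trip doubles exactly
  enc <- lapply(truth, function(e)
    if (is.atomic(e) && !is.null(names(e))) as.list(e) else e)
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
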