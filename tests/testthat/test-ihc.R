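test_that("DAB separation of a pure white image is essentially zero", {
  img <- array(255, dim = c(8, 8, 3))
  expect_true(all(separate_dab(img) <= 0.01))
})

test_that("DAB separation rejects non-RGB input", {
  expect_error(separate_dab(matrix(0, 4, 4)), "RGB")
  expect_error(separate_dab(array(0, c(4, 4, 4))), "RGB")
})

test_that("DAB-colored disks are detected only inside the disks", {
  m <- g7ps:::g7_stain_matrix()
  img <- array(255, dim = c(64, 64, 3))
  disk <- (row(matrix(0, 64, 64)) - 20)^2 + (col(matrix(0, 64, 64)) - 20)^2 <= 100
  dab_rgb <- 256 * 10^(-1.0 * m["dab", ]) - 1
  for (k in 1:3) {
    ch <- img[, , k]
    ch[disk] <- dab_rgb[k]
    img[, , k] <- ch
  }
  dab <- separate_dab(img)
  thr <- g7ps:::otsu_threshold(dab)
  expect_true(all(dab[disk] > thr))
  expect_true(all(dab[!disk] < thr))
})

test_that("hematoxylin-only pixels fall below the Otsu threshold of a mixed image", {
  m <- g7ps:::g7_stain_matrix()
  hema_rgb <- 256 * 10^(-0.8 * m["hematoxylin", ]) - 1
  dab_rgb <- 256 * 10^(-0.9 * m["dab", ]) - 1
  img <- array(0, dim = c(10, 10, 3))
  mixed <- col(matrix(0, 10, 10)) <= 5 # left half hematoxylin, right DAB
  for (k in 1:3) img[, , k] <- ifelse(mixed, hema_rgb[k], dab_rgb[k])
  dab <- separate_dab(img)
  thr <- g7ps:::otsu_threshold(dab)
  expect_true(all(dab[mixed] < thr))
  expect_true(all(dab[!mixed] > thr))
})

test_that("G7S is 1 for fully stained and 0 for unstained tissue", {
  tissue <- matrix(TRUE, 6, 6)
  stained <- matrix(0.8, 6, 6)
  expect_equal(compute_g7s(stained, tissue, threshold = 0.15)$g7s_fraction, 1)
  unstained <- matrix(0.05, 6, 6)
  expect_equal(compute_g7s(unstained, tissue, threshold = 0.15)$g7s_fraction, 0)
  expect_error(compute_g7s(stained, matrix(FALSE, 6, 6)), "empty")
  expect_error(compute_g7s(stained, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("G7N covers the all-nuclear and no-nuclear extremes", {
  dab <- matrix(0, 8, 8)
  dab[3:6, 3:6] <- 1
  tissue <- matrix(TRUE, 8, 8)
  nuclei <- matrix(FALSE, 8, 8)
  expect_equal(compute_g7n(dab, tissue, nuclei, 0.5)$g7n_fraction, 0)
  nuclei[3:6, 3:6] <- TRUE
  expect_equal(compute_g7n(dab, tissue, nuclei, 0.5)$g7n_fraction, 1)
  # no stained pixels at all: fraction 0, not NaN
  expect_equal(compute_g7n(dab * 0, tissue, nuclei, 0.5)$g7n_fraction, 0)
  # nuclei outside tissue are rejected
  expect_error(compute_g7n(dab, matrix(FALSE, 8, 8), nuclei, 0.5), "contained")
})

test_that("G7NL grading applies the published cuts with closed grade-1 bounds", {
  expect_equal(grade_g7nl(0.042), 0L) # sensitive-group median G7N
  expect_equal(grade_g7nl(0.549), 2L) # resistant-group median G7N
  expect_equal(grade_g7nl(c(0.15, 0.40)), c(1L, 1L))
  expect_equal(grade_g7nl(c(0, 0.149, 0.401, 1)), c(0L, 0L, 2L, 2L))
  expect_error(grade_g7nl(1.2), "\\[0, 1\\]")
  expect_error(grade_g7nl(-0.1), "\\[0, 1\\]")
})

test_that("synthetic images are recovered at the group-median targets", {
  sim <- generate_ihc_image(0.455, 0.55, seed = 5)
  mm <- measure_ihc(sim$image, sim$masks$tissue_mask, sim$masks$nuclei_mask)
  expect_equal(mm$g7s_fraction, 0.455, tolerance = 0.02 / 0.455)
  expect_lt(abs(mm$g7n_fraction - 0.55), 0.03)
  expect_equal(mm$g7nl_grade, 2L)

  sim2 <- generate_ihc_image(0.666, 0.042, seed = 9, size = c(256, 256))
  mm2 <- measure_ihc(sim2$image, sim2$masks$tissue_mask, sim2$masks$nuclei_mask)
  expect_lt(abs(mm2$g7s_fraction - 0.666), 0.02)
  expect_lt(abs(mm2$g7n_fraction - 0.042), 0.03)
  expect_equal(mm2$g7nl_grade, 0L)
})

test_that("fractions are invariant under rotation and horizontal flip", {
  sim <- generate_ihc_image(0.4, 0.42, seed = 9, size = c(128, 128),
                            n_nuclei = 60)
  base <- measure_ihc(sim$image, sim$masks$tissue_mask, sim$masks$nuclei_mask)
  rot90 <- function(m) t(m[nrow(m):1, ])
  img_rot <- array(0, dim = c(dim(sim$image)[2], dim(sim$image)[1], 3))
  for (k in 1:3) img_rot[, , k] <- rot90(sim$image[, , k])
  m_rot <- measure_ihc(img_rot, rot90(sim$masks$tissue_mask),
                       rot90(sim$masks$nuclei_mask))
  expect_equal(m_rot$g7s_fraction, base$g7s_fraction)
  expect_equal(m_rot$g7n_fraction, base$g7n_fraction)

  flip <- function(m) m[, ncol(m):1]
  img_fl <- sim$image[, dim(sim$image)[2]:1, , drop = FALSE]
  m_fl <- measure_ihc(img_fl, flip(sim$masks$tissue_mask),
                      flip(sim$masks$nuclei_mask))
  expect_equal(m_fl$g7s_fraction, base$g7s_fraction)
  expect_equal(m_fl$g7n_fraction, base$g7n_fraction)
})

test_that("raising the fixed DAB threshold never increases G7S", {
  sim <- generate_ihc_image(0.5, 0.3, seed = 3, size = c(128, 128),
                            n_nuclei = 60)
  dab <- separate_dab(sim$image)
  fr <- vapply(seq(0, 1.5, by = 0.1), function(th)
    compute_g7s(dab, sim$masks$tissue_mask, threshold = th)$g7s_fraction,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("generator targets are recovered across the (G7S, G7N) grid", {
  cells <- expand.grid(g7s = seq(0.1, 0.8, by = 0.1),
                       g7n = c(0.05, 0.25, 0.55))
  err_s <- err_n <- numeric(0)
  grade_ok <- logical(0)
  for (i in seq_len(nrow(cells))) {
    for (s in 1:3) {
      sim <- generate_ihc_image(cells$g7s[i], cells$g7n[i],
                                size = c(160, 160), n_nuclei = 80,
                                seed = 100 * i + s)
      mm <- measure_ihc(sim$image, sim$masks$tissue_mask,
                        sim$masks$nuclei_mask)
      err_s <- c(err_s, abs(mm$g7s_fraction - cells$g7s[i]))
      err_n <- c(err_n, abs(mm$g7n_fraction - cells$g7n[i]))
      # grade recovery, judged away from the 0.15/0.40 boundaries
      if (min(abs(cells$g7n[i] - c(0.15, 0.40))) > 0.02)
        grade_ok <- c(grade_ok, mm$g7nl_grade == grade_g7nl(cells$g7n[i]))
    }
  }
  expect_lte(mean(err_s), 0.03)
  expect_lte(mean(err_n), 0.03)
  expect_gte(mean(grade_ok), 0.95)
})

test_that("images and masks round-trip through PNG files", {
  sim <- generate_ihc_image(0.3, 0.2, seed = 7, size = c(64, 64),
                            n_nuclei = 20)
  tmp_img <- withr::local_tempfile(fileext = ".png")
  tmp_mask <- withr::local_tempfile(fileext = ".png")
  write_ihc_image(sim$image, tmp_img)
  back <- read_ihc_image(tmp_img)
  expect_equal(dim(back), dim(sim$image))
  expect_lte(max(abs(back - sim$image)), 0.5) # 8-bit quantization only
  write_mask(sim$masks$nuclei_mask, tmp_mask)
  expect_identical(read_mask(tmp_mask), sim$masks$nuclei_mask)
})
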