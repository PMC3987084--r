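cohort <- load_cohort_table()
learning <- cohort[cohort$cohort == "learning", ]
test_cases <- cohort[cohort$cohort == "test", ]

test_that("the published model is recovered from the cohort by least squares", {
  model <- recover_published_model(cohort)
  expect_equal(model$source, "recovered_ols")
  # pinned by the three patients with G7S = 0, G7NL = 0 (score -1.97)
  expect_equal(round(model$intercept, 2), -1.97)
  expect_lt(max(abs(attr(model, "residuals"))), 0.03)
  # printed-score spot checks
  expect_equal(g7ps_score(model, 0, 0), -1.97, tolerance = 0.01)
  expect_equal(g7ps_score(model, 83.3, 0), 2.87, tolerance = 0.02 / 2.87)
  expect_gt(model$coef_g7s, 0)
  expect_lt(model$coef_g7nl, 0)
})

test_that("model recovery matches a plane exactly and rejects deficient designs", {
  plane <- data.frame(g7s_percent = c(0, 10, 0, 20),
                      g7nl_grade = c(0, 0, 1, 2))
  plane$prediction_score <- 1.5 + 0.2 * plane$g7s_percent - 0.7 * plane$g7nl_grade
  m <- recover_published_model(plane)
  expect_equal(c(m$intercept, m$coef_g7s, m$coef_g7nl), c(1.5, 0.2, -0.7),
               tolerance = 1e-9)
  flat <- data.frame(g7s_percent = c(1, 1, 1), g7nl_grade = c(0, 1, 2),
                     prediction_score = 1:3)
  expect_error(recover_published_model(flat), "rank-deficient")
  expect_error(recover_published_model(plane[1:2, ]), "at least 3")
})

test_that("scores are affine in G7S and validate their inputs", {
  m <- g7ps_model(-2, 0.05, -1.2, source = "recovered_ols")
  expect_equal(g7ps_score(m, 50, 1) - g7ps_score(m, 30, 1), 0.05 * 20)
  expect_equal(g7ps_score(g7ps_model(0, 0, 0, "fitted_lda"), 77, 2), 0)
  expect_error(g7ps_score(m, 101, 0), "\\[0, 100\\]")
  expect_error(g7ps_score(m, 50, 3), "0, 1 or 2")
})

test_that("zero-boundary classification reproduces the published confusion counts", {
  model <- recover_published_model(cohort)
  pred_l <- classify_g7ps(g7ps_score(model, learning$g7s_percent,
                                     learning$g7nl_grade))
  perf_l <- evaluate_predictions(pred_l, learning$group)
  expect_equal(c(perf_l$tp, perf_l$fn, perf_l$fp, perf_l$tn), c(9, 0, 1, 8))
  expect_equal(round(100 * perf_l$sensitivity, 1), 100)
  expect_equal(round(100 * perf_l$specificity, 1), 88.9)

  pred_t <- classify_g7ps(g7ps_score(model, test_cases$g7s_percent,
                                     test_cases$g7nl_grade))
  perf_t <- evaluate_predictions(pred_t, test_cases$group)
  expect_equal(c(perf_t$tp, perf_t$fn, perf_t$fp, perf_t$tn), c(24, 1, 26, 17))
  expect_equal(round(100 * perf_t$sensitivity, 1), 96.0)
  expect_equal(round(100 * perf_t$specificity, 1), 39.5)

  # threshold consistency: predicted resistant iff score < 0, score 0 sensitive
  sc <- g7ps_score(model, cohort$g7s_percent, cohort$g7nl_grade)
  expect_identical(classify_g7ps(sc) == "resistant", sc < 0)
  expect_equal(classify_g7ps(0), "sensitive")
})

test_that("the fitted discriminant agrees in sign and learning-set confusion", {
  model <- fit_discriminant(learning)
  expect_equal(model$source, "fitted_lda")
  expect_gt(model$coef_g7s, 0)
  expect_lt(model$coef_g7nl, 0)
  pred <- classify_g7ps(g7ps_score(model, learning$g7s_percent,
                                   learning$g7nl_grade))
  perf <- evaluate_predictions(pred, learning$group)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 8 / 9)
  # sign pattern matches the OLS-recovered model
  rec <- recover_published_model(cohort)
  expect_equal(sign(c(model$coef_g7s, model$coef_g7nl)),
               sign(c(rec$coef_g7s, rec$coef_g7nl)))
})

test_that("fitted discriminant direction matches the MASS::lda reference", {
  ld <- MASS::lda(group ~ g7s_percent + g7nl_grade, data = learning)
  model <- fit_discriminant(learning)
  w_ref <- ld$scaling[, 1]
  # MASS points toward the second level (S); coefficients are proportional
  ratio <- unname(c(model$coef_g7s, model$coef_g7nl) / w_ref)
  expect_equal(ratio[1], ratio[2], tolerance = 1e-8)
  expect_gt(ratio[1], 0)
})

test_that("group centroids score symmetrically about the fitted boundary", {
  set.seed(2)
  pts <- data.frame(
    g7s_percent = c(rnorm(20, 30, 3), rnorm(20, 60, 3)),
    g7nl_grade = c(sample(1:2, 20, TRUE), sample(0:1, 20, TRUE)),
    group = rep(c("R", "S"), each = 20))
  m <- fit_discriminant(pts)
  at <- function(sub) m$intercept + m$coef_g7s * mean(sub$g7s_percent) +
    m$coef_g7nl * mean(sub$g7nl_grade)
  mu_r <- at(pts[pts$group == "R", ])
  mu_s <- at(pts[pts$group == "S", ])
  expect_equal(mu_r, -mu_s, tolerance = 1e-9)
  expect_gt(mu_s, 0)
})

test_that("degenerate discriminant inputs raise errors", {
  dup <- data.frame(g7s_percent = c(1, 2, 3, 4),
                    g7nl_grade = c(1, 2, 3, 4) * 2, # collinear with g7s
                    group = c("R", "R", "S", "S"))
  expect_error(fit_discriminant(dup), "singular")
  one_grp <- data.frame(g7s_percent = 1:4, g7nl_grade = c(0, 1, 0, 1),
                        group = "R")
  expect_error(fit_discriminant(one_grp), "both groups")
})

test_that("evaluation counts the confusion matrix with resistance positive", {
  perf <- evaluate_predictions(c("resistant", "sensitive"), c("R", "S"))
  expect_equal(c(perf$tp, perf$fn, perf$tn, perf$fp), c(1, 0, 1, 0))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_error(evaluate_predictions(character(0), character(0)), "no predictions")
  expect_warning(evaluate_predictions(c("resistant"), c("S")), "sensitivity undefined")
})

test_that("sensitivity ignores added sensitive records and vice versa", {
  pred <- c("resistant", "resistant", "sensitive")
  truth <- c("R", "S", "S")
  base <- evaluate_predictions(pred, truth)
  more_s <- evaluate_predictions(c(pred, "sensitive", "resistant"),
                                 c(truth, "S", "S"))
  expect_equal(more_s$sensitivity, base$sensitivity)
  more_r <- evaluate_predictions(c(pred, "sensitive", "resistant"),
                                 c(truth, "R", "R"))
  expect_equal(more_r$specificity, base$specificity)
})

test_that("the learning-set G7S cutoff matches the published operating point", {
  res <- optimal_cutoff(learning$g7s_percent / 100, learning$group)
  expect_equal(res$cutoff, 0.526)
  expect_equal(round(100 * res$sensitivity, 1), 88.9)
  expect_equal(round(100 * res$specificity, 1), 88.9)
})

test_that("cutoff search matches exhaustive enumeration on random data", {
  expect_equal(optimal_cutoff(c(1, 2, 3, 4), c("R", "R", "S", "S"))$cutoff, 2.5)
  set.seed(13)
  for (i in 1:100) {
    n <- sample(6:16, 1)
    labels <- sample(c("R", "S"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("R", "S")
    values <- round(rnorm(n), sample(0:2, 1)) # ties likely
    got <- optimal_cutoff(values, labels)
    ref <- cutoff_oracle(values, labels)
    expect_equal(got$cutoff, ref$cut)
    expect_equal(got$sensitivity + got$specificity, ref$youden)
  }
  expect_warning(optimal_cutoff(rep(1, 4), c("R", "R", "S", "S")), "constant")
})

test_that("G7PS models serialize to JSON and back", {
  m <- recover_published_model(cohort)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_g7ps_model(m, tmp)
  back <- read_g7ps_model(tmp)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coef_g7s, m$coef_g7s)
  expect_equal(back$coef_g7nl, m$coef_g7nl)
  expect_equal(back$source, "recovered_ols")
})
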