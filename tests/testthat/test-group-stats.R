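test_that("descriptive statistics match textbook values", {
  d <- descriptive_stats(c(1, 2, 3, 4, 5))
  expect_equal(d$mean, 3)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)
  expect_equal(d$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(d$q1, 2)
  expect_equal(d$q3, 4)

  const <- descriptive_stats(rep(7, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$q1, const$mean)
  expect_equal(const$q3, const$mean)

  expect_error(descriptive_stats(3), "n >= 2")
})

test_that("descriptive rows always satisfy the order-statistic chain", {
  set.seed(7)
  for (i in 1:25) {
    d <- descriptive_stats(rnorm(sample(2:40, 1), sd = runif(1, 0.1, 10)))
    expect_true(d$min <= d$q1 && d$q1 <= d$q3 && d$q3 <= d$max)
    expect_true(d$min <= d$mean && d$mean <= d$max)
  }
})

test_that("rm_anova gives F ~ 0 when condition means are identical", {
  set.seed(1)
  subj <- rnorm(12, 10, 3)
  m <- cbind(Fz = subj, F3 = subj, F4 = subj)  # per-subject offsets only
  res <- rm_anova(m)
  expect_lt(res$f, 1e-10)
  expect_lt(res$eta_sq_partial, 1e-10)
})

test_that("rm_anova reproduces a hand-computed sums-of-squares example", {
  # 4 subjects x 3 leads, integer data
  m <- matrix(c(3, 5, 9, 7,
                4, 6, 8, 10,
                8, 10, 12, 14), nrow = 4,
              dimnames = list(NULL, c("Fz", "F3", "F4")))
  # manual decomposition
  grand <- mean(m)
  ss_cond <- 4 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_cond - ss_subj
  f_manual <- (ss_cond / 2) / (ss_err / 6)
  res <- rm_anova(m)
  expect_equal(res$f, f_manual, tolerance = 1e-9)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$eta_sq_partial, ss_cond / (ss_cond + ss_err),
               tolerance = 1e-12)
})

test_that("rm_anova agrees with aov's within-subjects stratum", {
  set.seed(33)
  m <- matrix(rnorm(18 * 3, 8, 2), 18, dimnames = list(NULL, c("Cz", "C3", "C4")))
  m[, 2] <- m[, 2] + 1.5
  long <- data.frame(
    y = as.vector(m),
    lead = factor(rep(colnames(m), each = 18)),
    subj = factor(rep(seq_len(18), times = 3))
  )
  fit <- summary(stats::aov(y ~ lead + Error(subj/lead), data = long))
  ref <- fit[["Error: subj:lead"]][[1]]
  res <- rm_anova(m)
  expect_equal(res$f, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(res$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
})

test_that("rm_anova validates its input shape and completeness", {
  expect_error(rm_anova(matrix(1:8, 2, 4)), "3")
  expect_error(rm_anova(matrix(1:6, 2, 3)), ">= 3 subjects")
  m <- matrix(rnorm(9), 3); m[2, 2] <- NA
  expect_error(rm_anova(m), "complete cases")
})

test_that("eta-squared stays within [0, 1] across random inputs", {
  set.seed(9)
  for (i in 1:40) {
    m <- matrix(rnorm(3 * sample(3:25, 1), sd = runif(1, 0.5, 5)), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    eta <- rm_anova(m)$eta_sq_partial
    expect_gte(eta, 0)
    expect_lte(eta, 1)
  }
})

test_that("the region battery runs one test per band x region", {
  spec <- cohort_spec(n_subjects = 6, duration_s = 8.2, seed = 2)
  gt <- generate_cohort(spec)$ground_truth
  tbl <- tibble::tibble(subject = gt$subject, lead = gt$lead, band = gt$band,
                        amplitude_uv = gt$amplitude_uv)
  res <- region_battery(tbl)
  expect_equal(nrow(res), 18)
  expect_setequal(unique(res$region), c("frontal", "central", "parietal"))

  single <- region_battery(tbl[tbl$band == "Alpha", ])
  expect_equal(nrow(single), 3)

  expect_error(region_battery(tbl[tbl$lead != "Pz", ]), "Pz")
})

test_that("assumption checks are attached without switching the test", {
  set.seed(5)
  m <- matrix(rnorm(30, 8, 2), 10, dimnames = list(NULL, c("Pz", "P3", "P4")))
  res <- rm_anova(m)
  expect_length(res$shapiro_p[[1]], 3)
  expect_true(all(res$shapiro_p[[1]] > 0 & res$shapiro_p[[1]] <= 1))
  expect_true(res$levene_p > 0 && res$levene_p <= 1)
})

test_that("levene check agrees with car's Brown-Forsythe version", {
  skip_if_not_installed("car")
  set.seed(8)
  m <- matrix(rnorm(36, 10, c(1, 3, 6)), 12, byrow = TRUE,
              dimnames = list(NULL, c("Fz", "F3", "F4")))
  res <- rm_anova(m)
  long <- data.frame(y = as.vector(m),
                     g = factor(rep(colnames(m), each = 12)))
  ref <- car::leveneTest(y ~ g, data = long, center = median)
  expect_equal(res$levene_p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
})

test_that("group summaries produce per-band descriptive rows in canonical order", {
  spec <- cohort_spec(n_subjects = 5, duration_s = 8.2, seed = 4)
  gt <- generate_cohort(spec)$ground_truth
  tbl <- tibble::tibble(subject = gt$subject, lead = gt$lead, band = gt$band,
                        amplitude_uv = gt$amplitude_uv)
  gs <- group_summary(tbl)
  expect_equal(nrow(gs$descriptives), 54)
  expect_equal(gs$descriptives$band[1:9], rep("Delta", 9))
  expect_equal(gs$descriptives$lead[1:9], nine_leads())
  expect_true(all(gs$descriptives$n == 5))
})
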