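# Descriptive statistics, symmetry, dimorphism gate, ICC.

test_that("group summaries compute mean, sample SD and CV", {
  s <- summarize_group(c(1, 2, 3, 4), "g")
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))
  expect_equal(s$cv, 100 * s$sd / s$mean)

  const <- summarize_group(rep(7, 5), "g")
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)

  expect_error(summarize_group(3), "at least 2")
  expect_error(summarize_group(c(-5, -3)), "CV undefined")

  # a sample constructed with exactly the published moments reproduces the
  # printed CV cell: 8.9 / 128.5 -> 6.9%
  x <- 128.5 + 8.9 * scale(c(115, 125, 130, 131, 135, 145))[, 1]
  s2 <- summarize_group(x, "w")
  expect_equal(s2$mean, 128.5, tolerance = 1e-9)
  expect_equal(s2$sd, 8.9, tolerance = 1e-9)
  expect_equal(mandimorph:::round_half_out(s2$cv), 6.9)
})

test_that("CV is scale invariant", {
  set.seed(1)
  x <- rnorm(40, 50, 4)
  for (c_ in c(0.2, 3, 117)) {
    expect_equal(summarize_group(c_ * x, "g")$cv, summarize_group(x, "g")$cv,
                 tolerance = 1e-9)
  }
})

test_that("bilateral averaging matches the published worked example and is linear", {
  # female gonial side means 128.5 / 129.3 average to the printed 128.9
  expect_equal((128.5 + 129.3) / 2, 128.9)
  mm <- default_subject()
  tab <- rbind(mm$record,
               {
                 r <- mm$record; r$subject_id <- "S2"
                 r$gonial_angle_L <- r$gonial_angle_L + 4
                 r
               })
  avg <- bilateral_average(tab)
  expect_equal(avg$gonial_angle,
               (tab$gonial_angle_L + tab$gonial_angle_R) / 2)
  expect_equal(avg$bigonial_length, tab$bigonial_length)
  # group mean of bilateral averages = average of the side group means
  expect_equal(mean(avg$gonial_angle),
               (mean(tab$gonial_angle_L) + mean(tab$gonial_angle_R)) / 2)
  broken <- tab
  broken$gonial_angle_L[1] <- NA
  expect_error(bilateral_average(broken), "missing side")
})

test_that("asymmetry summary flags the largest left/right group-mean difference", {
  ref <- mandible_reference_table()
  asym <- asymmetry_summary(ref, angles_only = TRUE)
  f <- asym[asym$group == "female", ]
  expect_equal(f$abs_diff[f$measurement == "basilar_angle"], 4.3, tolerance = 1e-9)
  expect_true(f$is_max[f$measurement == "basilar_angle"])
  expect_false(any(f$is_max[f$measurement != "basilar_angle"]))

  # a perfectly symmetric cohort has zero differences everywhere
  mm <- symmetric_subject()
  tab <- dplyr::bind_rows(lapply(1:3, function(i) {
    r <- mm$record; r$subject_id <- paste0("S", i); r$sex <- "female"; r
  }))
  a0 <- asymmetry_summary(tab)
  expect_lt(max(a0$abs_diff), 1e-9)
})

test_that("an injected unilateral bias is identified as the asymmetry maximum", {
  # baseline with symmetric angle draws (the published left/right basilar
  # means already differ by 4.3 degrees, which would mask a 3-degree probe)
  hits <- 0
  for (s in 1:20) {
    params <- sample_cohort_params("female", 30, seed = 600 + s)
    params <- lapply(params, function(p) {
      for (f in c("gonial_angle", "basilar_symphysis_angle", "canine_angle"))
        p[[f]][] <- mean(p[[f]])
      p
    })
    tab <- cohort_truth_table(params, "female")
    tab$gonial_angle_L <- tab$gonial_angle_L + 3     # 3-degree left bias
    a <- asymmetry_summary(tab, angles_only = TRUE)
    hits <- hits + (a$measurement[which.max(a$abs_diff)] == "gonial_angle")
  }
  expect_gte(hits / 20, 0.95)
})

test_that("sex comparison gates on normality and behaves at the extremes", {
  mm <- default_subject()
  base <- dplyr::bind_rows(lapply(1:8, function(i) {
    r <- mm$record; r$subject_id <- paste0("S", i); r
  }))
  set.seed(2)
  for (nm in measurement_cols()) base[[nm]] <- base[[nm]] + rnorm(8, 0, 0.01)
  f <- base; f$sex <- "female"
  m <- base; m$sex <- "male"; m$subject_id <- paste0("M", 1:8)
  same <- compare_sexes(rbind(f, m))
  expect_true(all(!same$significant))
  expect_equal(attr(same, "n_tests"), 10)

  # shifting one group by 10 SD forces significance
  m10 <- m
  m10$bigonial_length <- m10$bigonial_length + 10 * sd(m$bigonial_length)
  shifted <- compare_sexes(rbind(f, m10))
  expect_true(shifted$significant[shifted$measurement == "bigonial_length"])
  expect_lt(shifted$p_value[shifted$measurement == "bigonial_length"], 1e-4)

  expect_error(compare_sexes(rbind(f[1:2, ], m)), "at least 3")
})

test_that("sex comparison on permuted labels rejects at about the alpha rate", {
  set.seed(42)
  tab <- rbind(cohort_truth_table(sample_cohort_params("female", 12, seed = 71), "female"),
               cohort_truth_table(sample_cohort_params("female", 12, seed = 72), "female"))
  n_rep <- 25
  rej <- 0; tot <- 0
  for (r in seq_len(n_rep)) {
    t2 <- tab
    t2$sex <- sample(rep(c("female", "male"), each = 12))
    cs <- compare_sexes(t2)
    rej <- rej + sum(cs$significant)
    tot <- tot + nrow(cs)
  }
  rate <- rej / tot        # 250 tests in total
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})

test_that("the within-subject side contrast (Friedman) runs on bilateral columns", {
  tab <- cohort_truth_table(sample_cohort_params("female", 15, seed = 81), "female")
  res <- side_symmetry_test(tab, "gonial_angle")
  expect_s3_class(res, "htest")
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  expect_error(side_symmetry_test(tab, "bigonial_length"), "bilateral")
})

test_that("ICC(2,1): perfect repeats, Rosner classes, and the mean-squares oracle", {
  m <- matrix(rep(c(10, 12, 14, 16), 3), ncol = 3)
  r <- icc_absolute_agreement(m)
  expect_equal(r$icc, 1, tolerance = 1e-12)
  expect_equal(r$reliability, "excellent")

  expect_equal(classify_reliability(0.74), "fair to good")
  expect_equal(classify_reliability(0.75), "excellent")
  expect_equal(classify_reliability(0.39), "poor")

  # independent oracle: mean squares from a two-way anova fit
  set.seed(3)
  x <- matrix(rnorm(24, 50, 5) + rep(rnorm(6, 0, 4), 4), nrow = 6)
  d <- data.frame(v = as.vector(x),
                  subj = factor(rep(1:6, 4)),
                  rep = factor(rep(1:4, each = 6)))
  ms <- anova(lm(v ~ subj + rep, d))$`Mean Sq`
  n <- 6; k <- 4
  icc_ref <- (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
  expect_equal(icc_absolute_agreement(x)$icc, icc_ref, tolerance = 1e-9)

  expect_error(icc_absolute_agreement(matrix(c(1, NA, 2, 3), 2)), "complete")
  expect_error(icc_absolute_agreement(matrix(1:3, 1)), "at least 2")
})

test_that("pure-noise repeat matrices have mean ICC near zero and rate poor", {
  set.seed(11)
  iccs <- replicate(100, icc_absolute_agreement(matrix(rnorm(50), 10, 5))$icc)
  expect_lt(abs(mean(iccs)), 0.1)
  expect_equal(unname(table(classify_reliability(iccs))["poor"] > 80), TRUE)
})
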