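# Parametric mandible generator: ground truth, sampling, placement noise.

test_that("ground truth is self-consistent: record equals distances between true points", {
  mm <- default_subject()
  tr <- mm$truth
  ls <- as_landmark_set(tr$landmarks)
  pt <- function(nm, sd = "M") mandimorph:::lmk(ls, nm, sd)
  d <- function(a, b) mandimorph:::vnorm(a - b) / 10
  g <- tr$derived$gonion
  bi <- tr$derived$basilar_inflexion
  ai <- tr$derived$alveolar_inflexion
  expect_equal(tr$record$bigonial_length, d(g$R, g$L), tolerance = 1e-9)
  expect_equal(tr$record$basilar_symphysis_length, d(bi$R, bi$L), tolerance = 1e-9)
  expect_equal(tr$record$alveolar_symphysis_length, d(ai$R, ai$L), tolerance = 1e-9)
  expect_equal(tr$record$symphyseal_height,
               d(pt("inter_incisor"), pt("mental_protuberance")), tolerance = 1e-9)
  for (sd in c("L", "R")) {
    expect_equal(tr$record[[paste0("vertical_posterior_dimension_", sd)]],
                 d(pt("upper_condyle", sd), g[[sd]]), tolerance = 1e-9)
    expect_equal(tr$record[[paste0("dentate_length_", sd)]],
                 d(pt("canine", sd), pt("molar_distal", sd)), tolerance = 1e-9)
    expect_equal(tr$record[[paste0("basilar_body_length_", sd)]],
                 d(g[[sd]], bi[[sd]]), tolerance = 1e-9)
  }
})

test_that("symmetric parameters give exactly symmetric left/right values", {
  mm <- symmetric_subject()
  rec <- mm$record
  for (m in mandimorph:::bilateral_measurements()) {
    expect_equal(rec[[paste0(m, "_L")]], rec[[paste0(m, "_R")]], tolerance = 1e-9)
  }
})

test_that("an exact sharp corner is recovered to numerical precision", {
  mm <- symmetric_subject()   # fillet_radius = 0, gonial 120 both sides
  expect_equal(mm$record$gonial_angle_L, 120, tolerance = 1e-6)
  expect_equal(mm$record$gonial_angle_R, 120, tolerance = 1e-6)
})

test_that("invalid parameter combinations name the conflicting pair", {
  expect_error(mandible_params(gonial_angle = 85), "90, 170")
  expect_error(mandible_params(basilar_symphysis_angle = 175), "90, 170")
  expect_error(mandible_params(ramus_height = -1), "positive")
  expect_error(mandible_params(fillet_radius = -0.5), "fillet_radius")
  expect_error(mandible_params(basilar_symphysis_angle = 168),
               "basilar_symphysis_angle vs body_flare")
  expect_error(mandible_params(basilar_symphysis_angle = c(95, 160)),
               "left vs right")
  expect_error(mandible_truth(mandible_params(symphyseal_height = 0.95)),
               "symphyseal_height")
  expect_error(make_mandible(mandible_params(fillet_radius = 25,
                                             basilar_body_length = 3)),
               "fillet_radius vs basilar_body_length")
})

test_that("cohort sampling is reproducible and matches the reference moments", {
  a <- sample_cohort_params("female", 12, seed = 5)
  b <- sample_cohort_params("female", 12, seed = 5)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  expect_error(sample_cohort_params("other", 5), "'arg'")

  # n = 30, fixed seed: sample mean of the right gonial angle within 2 SE
  # of 128.5 (a frozen draw of an ~95% event)
  gr <- sapply(sample_cohort_params("female", 30, seed = 1),
               function(p) p$gonial_angle[["R"]])
  expect_lt(abs(mean(gr) - 128.5), 2 * 8.9 / sqrt(30))

  # large n: sample SD of the male right gonial angle within 5% of 5.7
  gm <- sapply(sample_cohort_params("male", 4000, seed = 8),
               function(p) p$gonial_angle[["R"]])
  expect_lt(abs(sd(gm) / 5.7 - 1), 0.05)
})

test_that("the derived bi-gonial breadth is plausible against the printed means", {
  for (sx in c("female", "male")) {
    tab <- cohort_truth_table(sample_cohort_params(sx, 120, seed = 31), sx)
    ref <- mandible_reference_table()
    printed <- ref$mean[ref$measurement == "bigonial_length" & ref$group == sx]
    expect_lt(abs(mean(tab$bigonial_length) - printed), 1)   # cm
  }
})

test_that("landmark jitter is seed-reproducible, surface-bound, and identity at zero", {
  mm <- default_subject()
  lf <- mm$truth$landmarks
  expect_identical(jitter_landmarks(lf, 0, mesh = mm$mesh, seed = 1), lf)
  j1 <- jitter_landmarks(lf, 0.5, mesh = mm$mesh, seed = 9)
  j2 <- jitter_landmarks(lf, 0.5, mesh = mm$mesh, seed = 9)
  expect_equal(as.data.frame(j1$landmarks), as.data.frame(j2$landmarks))
  expect_error(jitter_landmarks(lf, -1), "sigma")

  # displaced points are re-projected onto the mesh surface
  P <- as.matrix(j1$landmarks[, c("x", "y", "z")])
  Q <- mandimorph:::project_points_to_mesh(P, mm$mesh)
  expect_lt(max(abs(P - Q)), 1e-8)

  # jittered sets keep the midpoint invariant (midpoints re-derived)
  ls <- as_landmark_set(j1)
  for (sd in c("L", "R")) {
    mid <- mandimorph:::lmk(ls, "molar_distal", sd)
    v <- mandimorph:::lmk(ls, "molar_distal_vestibular", sd)
    l <- mandimorph:::lmk(ls, "molar_distal_lingual", sd)
    expect_equal(mid, (v + l) / 2, tolerance = 1e-12)
  }
})

test_that("simulated cohorts reproduce the direction of the published dimorphisms", {
  # male lengths larger, female gonial angle larger, in most replicates
  hits <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    f <- cohort_truth_table(sample_cohort_params("female", 30, seed = 400 + s), "female")
    m <- cohort_truth_table(sample_cohort_params("male", 30, seed = 500 + s), "male")
    fa <- bilateral_average(rbind(f, m))
    fm <- fa[fa$sex == "female", ]; mm_ <- fa[fa$sex == "male", ]
    ok <- mean(fm$gonial_angle) > mean(mm_$gonial_angle) &&
      all(sapply(c("vertical_posterior_dimension", "basilar_body_length",
                   "basilar_symphysis_length", "symphyseal_height",
                   "bigonial_length", "dentate_length"),
                 function(v) mean(mm_[[v]]) > mean(fm[[v]])))
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.9)
})
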