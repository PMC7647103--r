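# STL and landmark/cohort file input-output.

test_that("a tetrahedron survives an STL round trip", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  mesh <- surface_mesh(v, f)
  for (fmt in c("binary", "ascii")) {
    path <- tempfile(fileext = ".stl")
    write_mesh(mesh, path, fmt)
    back <- read_mesh(path)
    expect_equal(nrow(back$vertices), 4)
    # same vertex set up to ordering
    key <- function(m) sort(apply(round(m, 6), 1, paste, collapse = ","))
    expect_equal(key(back$vertices), key(v))
    expect_equal(nrow(back$faces), 4)
  }
})

test_that("binary STL of a synthetic mandible preserves the generator vertex count", {
  mm <- default_subject()
  path <- tempfile(fileext = ".stl")
  write_mesh(mm$mesh, path, "binary")
  back <- read_mesh(path)
  expect_equal(nrow(back$vertices), mm$truth$vertex_count)
})

test_that("binary and ASCII dialects give identical measurements", {
  mm <- default_subject()
  pb <- tempfile(fileext = ".stl"); write_mesh(mm$mesh, pb, "binary")
  pa <- tempfile(fileext = ".stl"); write_mesh(mm$mesh, pa, "ascii")
  mb <- read_mesh(pb); ma <- read_mesh(pa)
  expect_equal(ma$vertices, mb$vertices, tolerance = 1e-12)
  rb <- measure_subject(mb, mm$truth$landmarks)
  ra <- measure_subject(ma, mm$truth$landmarks)
  expect_equal(unlist(ra[measurement_cols()]), unlist(rb[measurement_cols()]),
               tolerance = 1e-9)
})

test_that("malformed STL input is reported with a byte offset", {
  path <- tempfile(fileext = ".stl")
  mm <- default_subject()
  write_mesh(mm$mesh, path, "binary")
  full <- readBin(path, "raw", n = file.info(path)$size)
  truncated <- tempfile(fileext = ".stl")
  writeBin(full[1:200], truncated)
  expect_error(read_mesh(truncated), "byte")
  expect_error(read_mesh(tempfile()), "not found")
})

test_that("landmark files round-trip and validate the protocol vocabulary", {
  mm <- default_subject()
  lf <- mm$truth$landmarks
  path <- tempfile(fileext = ".csv")
  write_landmarks(lf, path)
  back <- read_landmarks(path)
  expect_equal(back$subject_id, lf$subject_id)
  expect_equal(back$sex, lf$sex)
  expect_equal(as.data.frame(back$landmarks), as.data.frame(lf$landmarks),
               tolerance = 1e-12)

  bad <- lf$landmarks
  bad$name[1] <- "coronoid_tip"
  expect_error(landmark_file("x", "female", 30, bad), "vocabulary")

  dup <- rbind(lf$landmarks, lf$landmarks[1, ])
  expect_error(landmark_file("x", "female", 30, dup), "duplicate")

  missing <- lf$landmarks[lf$landmarks$name != "inter_incisor", ]
  expect_error(landmark_file("x", "female", 30, missing), "inter_incisor")
})

test_that("primed pairs are accepted and midpoints derived downstream", {
  mm <- default_subject()
  lf <- mm$truth$landmarks   # carries primed pairs, no explicit midpoints
  expect_true(all(c("canine_vestibular", "canine_lingual") %in% lf$landmarks$name))
  expect_false("canine" %in% lf$landmarks$name)
  ls <- as_landmark_set(lf)
  expect_true(all(c("canine", "molar_distal") %in% ls$name))
  for (sd in c("L", "R")) {
    mid <- mandimorph:::lmk(ls, "canine", sd)
    v <- mandimorph:::lmk(ls, "canine_vestibular", sd)
    l <- mandimorph:::lmk(ls, "canine_lingual", sd)
    expect_equal(mid, (v + l) / 2, tolerance = 1e-12)
  }
  # a midpoint that disagrees with its primed pair violates the invariant
  tb <- lf$landmarks
  tb <- rbind(tb, data.frame(name = "canine", side = "R",
                             x = 0, y = 0, z = 0))
  expect_error(as_landmark_set(landmark_file("x", "female", 30, tb)),
               "primed pair")
})

test_that("cohort tables round-trip at full precision", {
  mm <- default_subject()
  recs <- list(mm$record,
               {
                 r <- mm$record
                 r$subject_id <- "S2"
                 r$gonial_angle_L <- r$gonial_angle_L + pi * 1e-5
                 r
               })
  path <- tempfile(fileext = ".csv")
  write_cohort_table(recs, path)
  tab <- read_cohort_table(path)
  expect_equal(dim(tab), c(2, 19))      # subject/sex/age + 16 values
  expect_equal(unlist(tab[1, measurement_cols()]),
               unlist(recs[[1]][measurement_cols()]), tolerance = 1e-12)

  broken <- recs
  broken[[2]] <- broken[[2]][, 1:10]
  expect_error(write_cohort_table(broken, tempfile()), "mismatched")
  expect_error(write_cohort_table(list(), tempfile()), "empty")
})

test_that("simulated cohort files can be measured back from disk", {
  dir <- file.path(tempdir(), "cohort_rt")
  manifest <- simulate_cohort_files(dir, n = 2, sex = "female", seed = 42)
  measured <- measure_cohort_dir(dir)
  expect_equal(nrow(measured), 2)
  for (nm in measurement_cols()) {
    lim <- if (grepl("angle", nm)) 1 else 0.1
    expect_lt(max(abs(measured[[nm]] - manifest[[nm]])), lim)
  }
})
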