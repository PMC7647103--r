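# The measurement protocol: derived points and the ten measurements.

test_that("canine angle examples", {
  mm <- symmetric_subject()
  ls <- as_landmark_set(mm$truth$landmarks)
  expect_equal(canine_angle(ls, "R"), mm$truth$record$canine_angle_R,
               tolerance = 1e-6)

  # equilateral in-plane configuration -> 60 degrees; collinear -> error
  base <- mm$truth$landmarks$landmarks
  tri <- base
  set_pt <- function(tb, nm, sd, p) {
    tb[tb$name == nm & tb$side == sd, c("x", "y", "z")] <- as.list(p)
    tb
  }
  z <- tri$z[tri$name == "inter_incisor"]
  tri <- set_pt(tri, "inter_incisor", "M", c(0, 0, z))
  tri <- set_pt(tri, "canine_vestibular", "R", c(10, -10 * sqrt(3), z))
  tri <- set_pt(tri, "canine_lingual", "R", c(10, -10 * sqrt(3), z))
  tri <- set_pt(tri, "molar_distal_vestibular", "R", c(20, 0, z))
  tri <- set_pt(tri, "molar_distal_lingual", "R", c(20, 0, z))
  ls2 <- as_landmark_set(landmark_file("x", "unknown", NA, tri))
  fr <- mm$truth$frame
  expect_equal(canine_angle(ls2, "R", fr), 60, tolerance = 1e-9)

  col <- set_pt(tri, "canine_vestibular", "R", c(10, 0, z))
  col <- set_pt(col, "canine_lingual", "R", c(10, 0, z))
  ls3 <- as_landmark_set(landmark_file("x", "unknown", NA, col))
  expect_error(canine_angle(ls3, "R", fr), "collinear")
})

test_that("gonion at a sharp right-angle corner is the corner itself", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  contour <- structure(list(vertices = sq, centroid = c(5, 5)),
                       class = "planar_contour")
  t1 <- line2d(c(0, 0), c(1, 0))
  t2 <- line2d(c(10, 0), c(0, 1))
  g <- locate_gonion(t1, t2, contour, witness = c(5, 5))
  expect_equal(g$angle, 90)
  expect_equal(as.numeric(g$point), c(10, 0), tolerance = 1e-9)
})

test_that("a filleted gonial corner places the gonion on the arc at the closed-form offset", {
  p <- mandible_params(gonial_angle = 120, basilar_symphysis_angle = 120,
                       canine_angle = 114, ramus_height = 6,
                       basilar_body_length = 7.3, dentate_length = 3.8,
                       fillet_radius = 2)
  mm <- make_mandible(p)
  ls <- as_landmark_set(mm$truth$landmarks)
  fr <- build_anatomical_frame(ls)
  P <- function(nm, sd) as.numeric(mandimorph:::to_frame(mandimorph:::lmk(ls, nm, sd), fr))
  cond <- P("posterior_condyle", "R")
  fora <- P("mental_foramen_basilar", "R")
  contour <- project_silhouette(mm$mesh, fr, "lateral_R")
  t_ram <- supporting_tangent(contour, rbind(cond[2:3], c(cond[2], fora[3])), c(-1, 0))
  t_bod <- supporting_tangent(contour, rbind(fora[2:3], c(cond[2], fora[3])), c(0, -1))
  g <- locate_gonion(t_ram, t_bod, contour, (cond[2:3] + fora[2:3]) / 2)
  offset <- mandimorph:::vnorm(g$point - line_intersection(t_ram, t_bod))
  closed_form <- 2 * (1 / sin(60 * pi / 180) - 1)   # r (1/sin(gamma/2) - 1)
  expect_equal(offset, closed_form, tolerance = 0.15)
  # and the full pipeline recovers the generator's gonial corner within 1 mm
  rec <- measure_subject(mm$mesh, ls)
  expect_lt(abs(rec$gonial_angle_R - 120), 0.5)
})

test_that("basilar and alveolar inflexions are tangent intersections with the stated angle", {
  t1 <- line2d(c(0, 0), c(cos(-5 * pi / 180), sin(-5 * pi / 180)))
  t2 <- line2d(c(10, 0), c(cos(-65 * pi / 180), sin(-65 * pi / 180)))
  wit <- c(5, -10)
  bi <- basilar_inflexion(t1, t2, wit)
  expect_equal(bi$angle, 120, tolerance = 1e-9)
  ai <- alveolar_inflexion(t1, t2, wit)
  expect_equal(ai$point, bi$point, tolerance = 1e-12)
  # translation equivariance
  sh <- c(-3, 8)
  bi2 <- basilar_inflexion(line2d(t1$anchor + sh, t1$direction),
                           line2d(t2$anchor + sh, t2$direction), wit + sh)
  expect_equal(bi2$point, bi$point + sh, tolerance = 1e-9)
  expect_error(basilar_inflexion(t1, line2d(c(0, 5), t1$direction), wit), "parallel")
})

test_that("noise-free measurement recovers generator truth within 1 degree / 1 mm", {
  for (mm in list(symmetric_subject(), default_subject())) {
    rec <- if (is.null(mm$record)) measure_subject(mm$mesh, mm$truth$landmarks) else mm$record
    tr <- mm$truth$record
    for (nm in measurement_cols()) {
      if (grepl("angle", nm)) {
        expect_lt(abs(rec[[nm]] - tr[[nm]]), 1)
      } else {
        expect_lt(abs(rec[[nm]] - tr[[nm]]), 0.1)   # cm
      }
    }
  }
})

test_that("lateral silhouette area matches the generator closed form within 2 percent", {
  mm <- symmetric_subject()
  fr <- build_anatomical_frame(mm$truth$landmarks)
  for (sd in c("L", "R")) {
    ct <- project_silhouette(mm$mesh, fr, paste0("lateral_", sd))
    expect_lt(abs(ct$area / mm$truth$lateral_area[[sd]] - 1), 0.02)
  }
})

test_that("an axially projected box is its footprint rectangle", {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 2), z = c(0, 3)))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  mesh <- surface_mesh(v, f)
  fr <- structure(list(origin = c(0, 0, 0), axes = diag(3)),
                  class = "anatomical_frame")
  ct <- project_silhouette(mesh, fr, "axial")
  expect_equal(abs(ct$area), 2, tolerance = 1e-9)
  expect_equal(range(ct$vertices[, 1]), c(0, 1))
  expect_equal(range(ct$vertices[, 2]), c(0, 2))
})

test_that("mirroring swaps left and right columns exactly", {
  mm <- default_subject()
  rec <- mm$record
  m_rec <- measure_subject(mirror_surface_mesh(mm$mesh),
                           mirror_landmark_file(mm$truth$landmarks))
  for (nm in measurement_cols()) {
    expect_equal(m_rec[[swap_side(nm)]], rec[[nm]], tolerance = 1e-12)
  }
})

test_that("measurements are invariant under rigid motion and covariant under scaling", {
  mm <- default_subject()
  rec <- mm$record
  R <- rotation_matrix(-0.8, 0.3, 1.2)
  t <- c(-40, 11, 70)
  rec_rot <- measure_subject(mandimorph:::transform_mesh(mm$mesh, R, t),
                             transform_landmark_file(mm$truth$landmarks, R, t))
  for (nm in measurement_cols()) {
    expect_lt(abs(rec_rot[[nm]] - rec[[nm]]), 1e-6)
  }
  rec_scaled <- measure_subject(surface_mesh(2 * mm$mesh$vertices, mm$mesh$faces),
                                transform_landmark_file(mm$truth$landmarks, scale = 2))
  for (nm in measurement_cols()) {
    expected <- if (grepl("angle", nm)) rec[[nm]] else 2 * rec[[nm]]
    expect_lt(abs(rec_scaled[[nm]] - expected), 1e-6 * max(1, expected))
  }
})

test_that("measurement records enforce their invariants", {
  mm <- default_subject()
  vals <- as.list(mm$record[measurement_cols()])
  vals$gonial_angle_L <- 190
  expect_error(measurement_record("x", "female", 30, vals), "0, 180")
  vals <- as.list(mm$record[measurement_cols()])
  vals$bigonial_length <- -1
  expect_error(measurement_record("x", "female", 30, vals), "positive")
  vals$bigonial_length <- NULL
  expect_error(measurement_record("x", "female", 30, vals), "missing")
})
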