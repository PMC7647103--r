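# Parametric synthetic mandible with closed-form ground truth.
#
# The phantom is a stylized dentate adult mandible assembled from a small
# number of watertight planar-faced components in the canonical frame
# (x right, y anterior, z up, origin at the chin):
#
#   * per side, a body+ramus solid: an L-shaped lateral profile (basilar edge
#     at z = 0, posterior ramus border leaning back by gonial angle - 90deg,
#     optional fillet arc at the gonial corner) extruded across the bone
#     thickness and sheared laterally so the basilar body edge flares at the
#     angle implied by the basilar symphysis angle;
#   * an anterior symphyseal wall whose outer face carries the chin and meets
#     each body edge at the basilar symphysis angle;
#   * an alveolar ridge band following the dental arch at the height implied
#     by the symphyseal height, whose vestibular outline carries the
#     alveolar inflexion corners.
#
# Every protocol measurement follows from the parameters in closed form, so
# the full pipeline can be validated against exact ground truth.

deg2rad <- function(d) d * pi / 180

lr <- function(v, what) {
  v <- as.numeric(v)
  if (length(v) == 1) v <- c(v, v)
  if (length(v) != 2) stop(what, " must have length 1 (symmetric) or 2 (L, R)")
  names(v) <- c("L", "R")
  v
}

#' Parameters of a synthetic mandible
#'
#' Defaults are the female cohort means of the reference table (angles in
#' degrees, anatomical lengths in cm, construction thicknesses in mm).
#' Bilateral parameters accept a single value (symmetric) or a `(L, R)`
#' pair. The bi-gonial length is not a parameter: it is derived from the
#' body lengths, the basilar angles and the symphysis chord by planar
#' trigonometry, since sampling it independently would over-constrain the
#' geometry.
#'
#' @param gonial_angle,basilar_symphysis_angle,canine_angle Degrees.
#' @param ramus_height,basilar_body_length,basilar_symphysis_length,alveolar_symphysis_length,symphyseal_height,dentate_length cm.
#' @param section_thickness Body cross-section width, mm.
#' @param fillet_radius Gonial corner rounding radius, mm (0 = sharp corner).
#' @param body_flare Lateral flare of the basilar body lines relative to the
#'   antero-posterior axis, degrees. The symphyseal chevron cant is derived
#'   per subject as `mean(basilar angles) - 90 - body_flare`, so the
#'   subject-level basilar-angle variation lives in the chin region and the
#'   derived bi-gonial breadth keeps a realistic dispersion; per-side angle
#'   asymmetry still flares the two body lines differently.
#' @param alveolar_cant Chevron half-angle of the alveolar arch at the
#'   midline, degrees.
#' @param ridge_width,ridge_thickness Alveolar ridge band width/height, mm.
#' @param ramus_width Antero-posterior ramus width, mm.
#' @param seed Optional seed recorded with the parameters.
#' @return Object of class `mandible_params`.
#' @export
mandible_params <- function(gonial_angle = c(129.3, 128.5),
                            basilar_symphysis_angle = c(118.2, 122.5),
                            canine_angle = c(114.5, 114.6),
                            ramus_height = c(6.0, 6.0),
                            basilar_body_length = c(7.5, 7.2),
                            basilar_symphysis_length = 2.5,
                            alveolar_symphysis_length = 2.8,
                            symphyseal_height = 2.7,
                            dentate_length = c(3.8, 3.8),
                            section_thickness = 10,
                            fillet_radius = 1,
                            body_flare = 25.3,
                            alveolar_cant = 5,
                            ridge_width = 6,
                            ridge_thickness = 3,
                            ramus_width = 33,
                            seed = NULL) {
  p <- list(gonial_angle = lr(gonial_angle, "gonial_angle"),
            basilar_symphysis_angle = lr(basilar_symphysis_angle, "basilar_symphysis_angle"),
            canine_angle = lr(canine_angle, "canine_angle"),
            ramus_height = lr(ramus_height, "ramus_height"),
            basilar_body_length = lr(basilar_body_length, "basilar_body_length"),
            basilar_symphysis_length = basilar_symphysis_length,
            alveolar_symphysis_length = alveolar_symphysis_length,
            symphyseal_height = symphyseal_height,
            dentate_length = lr(dentate_length, "dentate_length"),
            section_thickness = section_thickness,
            fillet_radius = fillet_radius,
            body_flare = body_flare,
            alveolar_cant = alveolar_cant,
            ridge_width = ridge_width,
            ridge_thickness = ridge_thickness,
            ramus_width = ramus_width,
            seed = seed)
  ang <- c(p$gonial_angle, p$basilar_symphysis_angle, p$canine_angle)
  if (any(ang <= 90 | ang >= 170))
    stop("angles must lie in (90, 170) degrees")
  len <- c(p$ramus_height, p$basilar_body_length, p$basilar_symphysis_length,
           p$alveolar_symphysis_length, p$symphyseal_height, p$dentate_length)
  if (any(len <= 0)) stop("lengths must be positive")
  if (p$fillet_radius < 0) stop("fillet_radius must be >= 0")
  if (p$body_flare <= 1 || p$body_flare >= 60)
    stop("body_flare must lie in (1, 60) degrees")
  cant <- mean(p$basilar_symphysis_angle) - 90 - p$body_flare
  if (cant <= -20 || cant >= 50)
    stop("conflicting parameters: basilar_symphysis_angle vs body_flare ",
         "(symphyseal cant ", round(cant, 1), " degrees is outside (-20, 50))")
  if (any(p$basilar_symphysis_angle - 90 - cant < 1))
    stop("conflicting parameters: left vs right basilar_symphysis_angle ",
         "(one body line would not flare outwards)")
  if (any(p$canine_angle - 90 - p$alveolar_cant < 1))
    stop("conflicting parameters: canine_angle vs alveolar_cant ",
         "(molar segment flare would be <= 0)")
  if (p$section_thickness >= 10 * p$basilar_symphysis_length)
    stop("conflicting parameters: section_thickness vs basilar_symphysis_length ",
         "(body would cross to the contralateral side)")
  structure(p, class = "mandible_params")
}

#' @export
print.mandible_params <- function(x, ...) {
  cat("<mandible_params>\n")
  cat(sprintf("  gonial %.1f/%.1f deg, basilar %.1f/%.1f deg, canine %.1f/%.1f deg\n",
              x$gonial_angle[1], x$gonial_angle[2],
              x$basilar_symphysis_angle[1], x$basilar_symphysis_angle[2],
              x$canine_angle[1], x$canine_angle[2]))
  cat(sprintf("  ramus %.1f/%.1f cm, body %.1f/%.1f cm, symphysis %.1f cm, height %.1f cm\n",
              x$ramus_height[1], x$ramus_height[2],
              x$basilar_body_length[1], x$basilar_body_length[2],
              x$basilar_symphysis_length, x$symphyseal_height))
  invisible(x)
}

# --- closed-form geometry shared by the truth and the mesh -----------------

mandible_geometry <- function(p) {
  phi <- deg2rad(mean(p$basilar_symphysis_angle) - 90 - p$body_flare)
  phia <- deg2rad(p$alveolar_cant)
  s <- 10 * p$basilar_symphysis_length
  as_ <- 10 * p$alveolar_symphysis_length
  h <- 10 * p$symphyseal_height
  wa <- p$ridge_width
  delta <- 1 + (wa / 2) / cos(phia)        # chin-to-incisor anterior setback, mm
  if (h <= delta + 5)
    stop("conflicting parameters: symphyseal_height vs ridge_width ",
         "(alveolar plane would not clear the chin)")
  za <- sqrt(h^2 - delta^2)
  zb <- za - 6                              # body top, below the ridge band
  if (zb < 8)
    stop("conflicting parameters: symphyseal_height vs ridge_thickness ",
         "(body wall too short)")
  y_apx <- (s / 2) * tan(phi)

  side_geom <- function(sd) {
    sgn <- if (sd == "L") -1 else 1
    gam <- deg2rad(p$gonial_angle[[sd]])
    bet <- deg2rad(p$basilar_symphysis_angle[[sd]])
    kap <- deg2rad(p$canine_angle[[sd]])
    lam <- gam - pi / 2
    mu <- bet - pi / 2 - phi
    mua <- kap - pi / 2 - phia
    k <- tan(mu)
    b <- 10 * p$basilar_body_length[[sd]]
    r <- 10 * p$ramus_height[[sd]]
    d <- 10 * p$dentate_length[[sd]]
    rf <- p$fillet_radius
    eps <- rf * (1 / sin(gam / 2) - 1)
    bis2 <- unit(c(1, 0) + c(-sin(lam), cos(lam)))   # lateral-plane interior bisector
    under <- b^2 - (eps * bis2[2])^2
    if (under <= 0) stop("conflicting parameters: fillet_radius vs basilar_body_length")
    y_gon <- -sqrt(under / (1 + k^2))
    y_c <- y_gon - eps * bis2[1]                      # sharp corner y
    tf <- if (rf > 0) rf / tan(gam / 2) else 0
    if (tf > 0.4 * abs(y_c))
      stop("conflicting parameters: fillet_radius vs basilar_body_length (fillet too large)")
    gon_lat <- c(y_c, 0) + eps * bis2
    x_out <- function(y) s / 2 - k * y
    gon3 <- c(sgn * x_out(gon_lat[1]), gon_lat[1], gon_lat[2])
    u3 <- unit(c(sgn * k * sin(lam), -sin(lam), cos(lam)))
    cond_up3 <- gon3 + r * u3
    cond_post3 <- gon3 + 0.78 * r * u3
    infl3 <- c(sgn * s / 2, 0, 0)
    y_f <- 0.35 * y_c
    foramen3 <- c(sgn * x_out(y_f), y_f, 0)

    # alveolar arch (axial plane at z = za)
    n1 <- c(sgn * sin(phia), cos(phia))               # incisor segment outward normal
    n2 <- c(sgn * cos(mua), sin(mua))                 # molar segment outward normal
    off <- (wa / 2) * (n1 + n2) / (1 + sum(n1 * n2))  # mitered vestibular offset
    y_I <- y_apx - delta
    # canine midline point: x fixed by the vestibular corner, y by the incisor line
    cx <- sgn * as_ / 2 - off[1]
    cy <- y_I - abs(cx) * tan(phia)
    C2 <- c(cx, cy)
    Cv2 <- C2 + off
    M2 <- C2 + d * c(sgn * sin(mua), -cos(mua))
    list(sgn = sgn, gam = gam, bet = bet, kap = kap, lam = lam, mu = mu, mua = mua,
         k = k, b = b, r = r, d = d, rf = rf, eps = eps, tf = tf,
         y_c = y_c, y_gon = y_gon, gon3 = gon3, u3 = u3,
         cond_up3 = cond_up3, cond_post3 = cond_post3,
         infl3 = infl3, foramen3 = foramen3,
         C2 = C2, Cv2 = Cv2, M2 = M2, n1 = n1, n2 = n2)
  }

  # the body strip must stay on its own side of the mid-sagittal plane; the
  # effective extrusion depth is capped by the symphysis chord (section
  # thickness shapes the mesh only, no measurement depends on it)
  wb_eff <- min(p$section_thickness, 0.45 * s)
  list(phi = phi, phia = phia, s = s, as_ = as_, h = h, wa = wa,
       ta = p$ridge_thickness, wb = wb_eff, wr = p$ramus_width,
       delta = delta, za = za, zb = zb, y_apx = y_apx, y_I = (s / 2) * tan(phi) - delta,
       L = side_geom("L"), R = side_geom("R"))
}

#' Closed-form ground truth of a synthetic mandible
#'
#' Computes the true landmark set, derived points and measurement record for
#' a parameter vector without building the mesh.
#'
#' @param p A `mandible_params`.
#' @param subject_id,sex,age Metadata for the emitted landmark file/record.
#' @return Object of class `mandible_truth`: list with `record`
#'   (a `measurement_record`), `landmarks` (a `landmark_file` with primed
#'   pairs), `frame` (the declared `anatomical_frame`), `derived` points and
#'   `lateral_area` (the analytic lateral-silhouette area per side, mm^2).
#' @export
mandible_truth <- function(p, subject_id = "synthetic", sex = "unknown", age = NA) {
  g <- mandible_geometry(p)
  rows <- list()
  add <- function(name, side, pt) {
    rows[[length(rows) + 1]] <<- tibble::tibble(name = name, side = side,
                                                x = pt[1], y = pt[2], z = pt[3])
  }
  add("mental_protuberance", "M", c(0, g$y_apx, 0))
  add("inter_incisor", "M", c(0, g$y_I, g$za))
  for (sd in c("L", "R")) {
    gs <- g[[sd]]
    add("upper_condyle", sd, gs$cond_up3)
    add("posterior_condyle", sd, gs$cond_post3)
    add("mental_foramen_basilar", sd, gs$foramen3)
    u_ext <- unit(gs$n1 + gs$n2)
    add("canine_vestibular", sd, c(gs$C2 + (g$wa / 2) * u_ext, g$za))
    add("canine_lingual", sd, c(gs$C2 - (g$wa / 2) * u_ext, g$za))
    add("molar_distal_vestibular", sd, c(gs$M2 + (g$wa / 2) * gs$n2, g$za))
    add("molar_distal_lingual", sd, c(gs$M2 - (g$wa / 2) * gs$n2, g$za))
  }
  lf <- landmark_file(subject_id, sex, age, dplyr::bind_rows(rows))

  alvL <- c(g$L$Cv2, g$za); alvR <- c(g$R$Cv2, g$za)
  vals <- list(
    gonial_angle_L = p$gonial_angle[["L"]], gonial_angle_R = p$gonial_angle[["R"]],
    basilar_angle_L = p$basilar_symphysis_angle[["L"]],
    basilar_angle_R = p$basilar_symphysis_angle[["R"]],
    canine_angle_L = p$canine_angle[["L"]], canine_angle_R = p$canine_angle[["R"]],
    vertical_posterior_dimension_L = p$ramus_height[["L"]],
    vertical_posterior_dimension_R = p$ramus_height[["R"]],
    dentate_length_L = p$dentate_length[["L"]], dentate_length_R = p$dentate_length[["R"]],
    basilar_body_length_L = p$basilar_body_length[["L"]],
    basilar_body_length_R = p$basilar_body_length[["R"]],
    basilar_symphysis_length = p$basilar_symphysis_length,
    alveolar_symphysis_length = vnorm(alvR - alvL) / 10,
    symphyseal_height = p$symphyseal_height,
    bigonial_length = vnorm(g$R$gon3 - g$L$gon3) / 10)
  record <- measurement_record(subject_id, sex, age, vals)

  frame <- structure(list(origin = c(0, g$y_apx, 0), axes = diag(3)),
                     class = "anatomical_frame")
  colnames(frame$axes) <- c("right", "anterior", "up")
  structure(list(record = record, landmarks = lf, frame = frame,
                 derived = list(gonion = list(L = g$L$gon3, R = g$R$gon3),
                                basilar_inflexion = list(L = g$L$infl3, R = g$R$infl3),
                                alveolar_inflexion = list(L = alvL, R = alvR)),
                 geometry = g),
            class = "mandible_truth")
}

# --- mesh assembly ---------------------------------------------------------

# posterior-border length of the ramus profile: beyond the condyle, and at
# a strongly oblique ramus still clearing the body top so the profile stays
# a simple polygon
ramus_border_length <- function(g, gs) {
  max(1.12 * gs$r / sqrt(1 + gs$k^2 * sin(gs$lam)^2),
      (g$zb + 8) / cos(gs$lam))
}

# closed prism from a 2D footprint polygon (CCW) spanning z in [z0, z1]
prism_mesh <- function(foot, z0, z1) {
  if (polygon_area(foot) < 0) foot <- foot[nrow(foot):1, , drop = FALSE]
  n <- nrow(foot)
  V <- rbind(cbind(foot, z0), cbind(foot, z1))
  tri <- ear_clip(foot)
  Fb <- tri[, c(1, 3, 2), drop = FALSE]          # bottom, facing -z
  Ft <- tri + n                                   # top, facing +z
  i <- seq_len(n); j <- c(2:n, 1)
  Fs <- rbind(cbind(i, j, j + n), cbind(i, j + n, i + n))
  list(V = V, F = rbind(Fb, Ft, Fs))
}

# body+ramus solid for one side: L-profile in (y, z), extruded across x and
# sheared so the outer face lies in the plane x = s/2 - k*y
body_ramus_mesh <- function(g, sd, arc_n = 12) {
  gs <- g[[sd]]
  corner <- c(gs$y_c, 0)
  upb <- c(-sin(gs$lam), cos(gs$lam))
  L_pb <- ramus_border_length(g, gs)
  Tp <- corner + L_pb * upb
  Ta <- Tp + c(g$wr, 0)
  Ab <- Ta + ((Ta[2] - g$zb) / cos(gs$lam)) * c(sin(gs$lam), -cos(gs$lam))
  if (Ab[1] > -1)
    stop("conflicting parameters: ramus_width vs basilar_body_length ",
         "(anterior ramus border crosses the symphysis)")
  at <- 3   # anterior trim: the symphyseal wall carries the outer boundary
            # through the basilar inflexion corner (see symphysis_mesh)
  if (gs$rf > 0) {
    O <- corner + (gs$rf / sin(gs$gam / 2)) * unit(c(1, 0) + upb)
    F1 <- corner + c(gs$tf, 0)
    F2 <- corner + gs$tf * upb
    a1 <- atan2(F1[2] - O[2], F1[1] - O[1])
    a2 <- atan2(F2[2] - O[2], F2[1] - O[1])
    delta <- a2 - a1
    if (delta > pi) delta <- delta - 2 * pi
    if (delta < -pi) delta <- delta + 2 * pi     # short way: the convex fillet
    th <- seq(a1, a1 + delta, length.out = arc_n + 1)
    arc <- cbind(O[1] + gs$rf * cos(th), O[2] + gs$rf * sin(th))
    low <- rbind(c(-at, 0), arc)                 # bottom edge -> F1 -> arc -> F2
  } else {
    low <- rbind(c(-at, 0), corner)
  }
  prof <- rbind(low, Tp, Ta, Ab, c(-at, g$zb))
  if (polygon_area(prof) < 0) prof <- prof[nrow(prof):1, , drop = FALSE]
  n <- nrow(prof)
  x_in <- g$s / 2 - g$wb
  x_out <- g$s / 2
  V <- rbind(cbind(x_in, prof), cbind(x_out, prof))
  V[, 1] <- V[, 1] - gs$k * V[, 2]                # lateral shear
  tri <- ear_clip(prof)
  Fc1 <- tri[, c(1, 3, 2), drop = FALSE]
  Fc2 <- tri + n
  i <- seq_len(n); j <- c(2:n, 1)
  Fs <- rbind(cbind(i, j, j + n), cbind(i, j + n, i + n))
  V3 <- V[, c(1, 2, 3)]
  if (gs$sgn < 0) {
    V3[, 1] <- -V3[, 1]
    Fall <- rbind(Fc1, Fc2, Fs)[, c(1, 3, 2), drop = FALSE]
  } else {
    Fall <- rbind(Fc1, Fc2, Fs)
  }
  list(V = V3, F = Fall)
}

# The symphyseal wall carries the anterior outer boundary: chin apex,
# basilar inflexion corners, and a short continuation along each body line
# (collinear with the body tangent, overlapping the trimmed body pieces).
# Its 9 mm lingual depth keeps the basilar union contiguous.
symphysis_mesh <- function(g) {
  phi <- g$phi
  ws <- 9; ext <- 6
  nR <- c(sin(phi), cos(phi)); nL <- c(-sin(phi), cos(phi))
  apex <- c(0, g$y_apx)
  inflR <- c(g$s / 2, 0)
  inflL <- c(-g$s / 2, 0)
  dbR <- c(sin(g$R$mu), -cos(g$R$mu))
  dbL <- c(-sin(g$L$mu), -cos(g$L$mu))
  nbR <- c(cos(g$R$mu), sin(g$R$mu))
  nbL <- c(-cos(g$L$mu), sin(g$L$mu))
  contR <- inflR + ext * dbR
  contL <- inflL + ext * dbL
  miter <- function(p, n1, n2) p - ws * (n1 + n2) / (1 + sum(n1 * n2))
  inner <- rbind(contR - ws * nbR,
                 miter(inflR, nR, nbR),
                 apex - c(0, ws / cos(phi)),
                 miter(inflL, nL, nbL),
                 contL - ws * nbL)
  foot <- rbind(contL, inflL, apex, inflR, contR, inner[c(1:3, 4:5), , drop = FALSE])
  prism_mesh(foot, 0, g$zb)
}

alveolar_mesh <- function(g) {
  wa2 <- g$wa / 2
  apex_v <- c(0, g$y_I + wa2 / cos(g$phia))
  apex_l <- c(0, g$y_I - wa2 / cos(g$phia))
  MvR <- g$R$M2 + wa2 * g$R$n2; MlR <- g$R$M2 - wa2 * g$R$n2
  MvL <- g$L$M2 + wa2 * g$L$n2; MlL <- g$L$M2 - wa2 * g$L$n2
  foot <- rbind(MvR, g$R$Cv2, apex_v, g$L$Cv2, MvL,
                MlL, g$L$C2 - (g$L$Cv2 - g$L$C2), apex_l,
                g$R$C2 - (g$R$Cv2 - g$R$C2), MlR)
  prism_mesh(foot, g$za - g$ta, g$za)
}

#' Generate a synthetic mandible mesh with ground truth
#'
#' @param p A `mandible_params`.
#' @param subject_id,sex,age Metadata passed to the ground truth.
#' @return List with `mesh` (a `surface_mesh`) and `truth`
#'   (a `mandible_truth`; see [mandible_truth()]). `truth$lateral_area`
#'   holds the closed-form lateral silhouette area per side and
#'   `truth$vertex_count` the emitted vertex count.
#' @export
make_mandible <- function(p, subject_id = "synthetic", sex = "unknown", age = NA) {
  truth <- mandible_truth(p, subject_id, sex, age)
  g <- truth$geometry
  parts <- list(body_ramus_mesh(g, "L"), body_ramus_mesh(g, "R"),
                symphysis_mesh(g), alveolar_mesh(g))
  V <- NULL; F <- NULL; off <- 0
  for (pt in parts) {
    V <- rbind(V, pt$V)
    F <- rbind(F, pt$F + off)
    off <- off + nrow(pt$V)
  }
  # merge coordinates shared between components so the emitted vertex count
  # is reproducible through STL round-trips
  key <- paste(V[, 1], V[, 2], V[, 3])
  idx <- match(key, key[!duplicated(key)])
  mesh <- surface_mesh(V[!duplicated(key), , drop = FALSE],
                       matrix(idx[F], ncol = 3))
  # analytic lateral-profile area per side: L-profile plus the anterior
  # symphysis sliver (y > 0) of the symphyseal wall
  lat <- vapply(c("L", "R"), function(sd) {
    gs <- g[[sd]]
    corner <- c(gs$y_c, 0)
    upb <- c(-sin(gs$lam), cos(gs$lam))
    L_pb <- ramus_border_length(g, gs)
    Tp <- corner + L_pb * upb
    Ta <- Tp + c(g$wr, 0)
    Ab <- Ta + ((Ta[2] - g$zb) / cos(gs$lam)) * c(sin(gs$lam), -cos(gs$lam))
    at <- 3
    prof <- rbind(c(-at, 0), corner, Tp, Ta, Ab, c(-at, g$zb))
    a <- abs(polygon_area(prof))
    if (gs$rf > 0) {
      # fillet shaves the circular-segment area between arc and corner
      gam <- gs$gam
      a <- a - (gs$rf^2 * (cos(gam / 2) / sin(gam / 2) - (pi - gam) / 2))
    }
    # the symphyseal wall extends the silhouette anteriorly from the body
    # trim plane to the chin apex
    a + max(g$y_apx + at, 0) * g$zb
  }, numeric(1))
  truth$lateral_area <- lat
  truth$vertex_count <- nrow(mesh$vertices)
  list(mesh = mesh, truth = truth)
}

# --- cohort simulation -----------------------------------------------------

table2_param_rows <- function(sex) {
  ref <- mandible_reference_table()
  ref[ref$group == sex, ]
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  lo <- max(lo, mean - 4 * sd); hi <- min(hi, mean + 4 * sd)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Sample cohort parameters from the reference distributions
#'
#' Each measurement is drawn from a normal distribution with its
#' sex-specific published mean and SD (truncated at +/- 4 SD and at the
#' geometric validity bounds). Distinct measurements are independent; the
#' left/right pair of a bilateral measurement shares a subject-level
#' component (correlation 0.9) so that each side keeps its printed marginal
#' distribution while within-subject asymmetry stays in the few-degree /
#' few-millimetre range the source cohort reports. The bi-gonial length is
#' not sampled (it is derived; see [mandible_params()]).
#'
#' @param sex `"female"` or `"male"`.
#' @param n Number of subjects.
#' @param seed Optional RNG seed for reproducibility.
#' @return List of `mandible_params`, with subject ids in `names()`.
#' @export
sample_cohort_params <- function(sex, n, seed = NULL) {
  sex <- match.arg(sex, c("female", "male"))
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ref <- table2_param_rows(sex)
  rho <- 0.9
  val <- function(meas, side) {
    r <- ref[ref$measurement == meas & (is.na(ref$side) | ref$side == side), ]
    c(mean = r$mean[1], sd = r$sd[1])
  }
  draw <- function(meas, side, lo, hi) {
    v <- val(meas, side)
    rtrunc_norm(n, v["mean"], v["sd"], lo, hi)
  }
  draw_pair <- function(meas, lo, hi) {
    vL <- val(meas, "L"); vR <- val(meas, "R")
    out <- matrix(NA_real_, n, 2)
    need <- seq_len(n)
    loL <- max(lo, vL["mean"] - 4 * vL["sd"]); hiL <- min(hi, vL["mean"] + 4 * vL["sd"])
    loR <- max(lo, vR["mean"] - 4 * vR["sd"]); hiR <- min(hi, vR["mean"] + 4 * vR["sd"])
    while (length(need)) {
      z0 <- stats::rnorm(length(need))
      zL <- stats::rnorm(length(need)); zR <- stats::rnorm(length(need))
      L <- vL["mean"] + vL["sd"] * (sqrt(rho) * z0 + sqrt(1 - rho) * zL)
      R <- vR["mean"] + vR["sd"] * (sqrt(rho) * z0 + sqrt(1 - rho) * zR)
      ok <- L >= loL & L <= hiL & R >= loR & R <= hiR
      out[need[ok], ] <- cbind(L[ok], R[ok])
      need <- need[!ok]
    }
    out
  }
  gon <- draw_pair("gonial_angle", 95, 168)
  bas <- draw_pair("basilar_angle", 97, 168)
  can <- draw_pair("canine_angle", 97, 168)
  ram <- draw_pair("vertical_posterior_dimension", 3, 10)
  bod <- draw_pair("basilar_body_length", 4, 12)
  den <- draw_pair("dentate_length", 2, 6)
  bsy <- draw("basilar_symphysis_length", NA, 1.4, 5)
  asy <- draw("alveolar_symphysis_length", NA, 1.4, 5)
  shh <- draw("symphyseal_height", NA, 1.6, 5)
  pre <- if (sex == "female") "F" else "M"
  out <- lapply(seq_len(n), function(i)
    mandible_params(gonial_angle = gon[i, ],
                    basilar_symphysis_angle = bas[i, ],
                    canine_angle = can[i, ],
                    ramus_height = ram[i, ],
                    basilar_body_length = bod[i, ],
                    basilar_symphysis_length = bsy[i],
                    alveolar_symphysis_length = asy[i],
                    symphyseal_height = shh[i],
                    dentate_length = den[i, ]))
  names(out) <- sprintf("%s%02d", pre, seq_len(n))
  out
}

#' Ground-truth cohort table from sampled parameters
#'
#' Convenience wrapper: closed-form measurement records (no meshing) for a
#' simulated cohort, ready for the statistics layer.
#'
#' @param params Named list of `mandible_params` (see
#'   [sample_cohort_params()]).
#' @param sex Sex label stored in the records.
#' @return A cohort tibble (one `measurement_record` row per subject).
#' @export
cohort_truth_table <- function(params, sex = "unknown") {
  recs <- lapply(names(params), function(id)
    mandible_truth(params[[id]], subject_id = id, sex = sex)$record)
  dplyr::bind_rows(recs)
}

# --- landmark placement noise ---------------------------------------------

# nearest point on a triangle soup to each row of P (all in the same coords)
project_points_to_mesh <- function(P, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  E1 <- V[F[, 2], , drop = FALSE] - A
  E2 <- V[F[, 3], , drop = FALSE] - A
  a11 <- rowSums(E1 * E1); a22 <- rowSums(E2 * E2); a12 <- rowSums(E1 * E2)
  det <- a11 * a22 - a12 * a12
  out <- P
  for (i in seq_len(nrow(P))) {
    D <- sweep(A, 2, P[i, ], "-")
    b1 <- -rowSums(D * E1); b2 <- -rowSums(D * E2)
    u <- (a22 * b1 - a12 * b2) / det
    v <- (a11 * b2 - a12 * b1) / det
    # clamp to the triangle: project onto edges where outside
    w <- 1 - u - v
    u2 <- u; v2 <- v
    bad <- !(u >= 0 & v >= 0 & w >= 0) | !is.finite(u) | !is.finite(v)
    if (any(bad)) {
      cl <- function(x) pmin(1, pmax(0, x))
      # candidate points on the three edges
      t1 <- cl(b1 / a11)                       # edge A + t*E1
      t2 <- cl(b2 / a22)                       # edge A + t*E2
      d3 <- E2 - E1                            # edge (A+E1) + t*(E2-E1)
      t3 <- cl(rowSums((-D - E1) * d3) / rowSums(d3 * d3))
      cand <- list(cbind(t1, 0), cbind(0, t2), cbind(1 - t3, t3))
      best_d <- rep(Inf, nrow(A)); bu <- u2; bv <- v2
      for (cc in cand) {
        px <- A + cc[, 1] * E1 + cc[, 2] * E2
        dd <- rowSums(sweep(px, 2, P[i, ], "-")^2)
        sel <- bad & dd < best_d
        best_d[sel] <- dd[sel]; bu[sel] <- cc[sel, 1]; bv[sel] <- cc[sel, 2]
      }
      u2 <- bu; v2 <- bv
    }
    Q <- A + u2 * E1 + v2 * E2
    dist2 <- rowSums(sweep(Q, 2, P[i, ], "-")^2)
    out[i, ] <- Q[which.min(dist2), ]
  }
  out
}

#' Add landmark placement noise
#'
#' Emulates repeated manual landmark placement: every placed landmark is
#' displaced by isotropic zero-mean Gaussian noise of SD `sigma` (mm) and,
#' when the mesh is supplied, re-projected onto the nearest surface point.
#' Derived midpoints are recomputed downstream from the jittered primed
#' pairs, so the landmark-set midpoint invariant is preserved.
#'
#' @param lm A `landmark_file`.
#' @param sigma Noise SD in mm (>= 0).
#' @param mesh Optional `surface_mesh` for surface re-projection.
#' @param seed Optional RNG seed.
#' @return A jittered `landmark_file`.
#' @export
jitter_landmarks <- function(lm, sigma, mesh = NULL, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  stopifnot(inherits(lm, "landmark_file"))
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(lm)
  tb <- lm$landmarks
  n <- nrow(tb)
  P <- as.matrix(tb[, c("x", "y", "z")]) + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
  if (!is.null(mesh)) P <- project_points_to_mesh(P, mesh)
  tb$x <- P[, 1]; tb$y <- P[, 2]; tb$z <- P[, 3]
  landmark_file(lm$subject_id, lm$sex, lm$age, tb)
}
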