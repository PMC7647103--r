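# The standardized measurement protocol: six bilateral and four single
# measurements per mandible.
#
# Angles come from tangent pairs on planar silhouettes (gonial angle in each
# lateral plane; basilar symphysis angle in the axial plane), the canine
# angle from axial landmark projections. Derived points: the gonion as the
# first silhouette point along the interior bisector of the gonial tangents;
# basilar and alveolar inflexion points as tangent intersections. Lengths are
# Euclidean distances between landmarks and lifted derived points, reported
# in centimetres (internal unit is mm).

#' Locate the gonion from the gonial tangent pair
#'
#' The gonion is the bony projection along the bisector of the gonial angle:
#' the interior bisector ray is cast from the tangent intersection towards
#' the bone and the first silhouette boundary point hit is the (2D) gonion.
#' When the ray grazes several boundary points the smallest ray parameter
#' (first hit) wins.
#'
#' @param t_ramus,t_body `line2d` tangents to the posterior ramus border and
#'   the basilar body edge, in the lateral plane.
#' @param contour The lateral `planar_contour`.
#' @param witness Optional bone-side 2D point (defaults to the contour
#'   centroid).
#' @return List with `point` (2D, mm) and `angle` (the gonial angle, deg).
#' @export
locate_gonion <- function(t_ramus, t_body, contour, witness = NULL) {
  if (is.null(witness)) witness <- contour$centroid
  ang <- angle_between_lines(t_ramus, t_body, witness)
  bis <- interior_bisector(t_ramus, t_body, witness)
  hit <- ray_polygon_first_hit(bis$origin, bis$direction, contour$vertices)
  if (is.null(hit)) {
    # heavily displaced landmarks can push the tangent intersection past the
    # silhouette; fall back to the boundary point nearest to the bisector ray
    v <- contour$vertices
    t <- (v[, 1] - bis$origin[1]) * bis$direction[1] +
      (v[, 2] - bis$origin[2]) * bis$direction[2]
    t <- pmax(t, 0)
    px <- bis$origin[1] + t * bis$direction[1]
    py <- bis$origin[2] + t * bis$direction[2]
    hit <- v[which.min((v[, 1] - px)^2 + (v[, 2] - py)^2), ]
  }
  list(point = hit, angle = ang)
}

#' Basilar inflexion point
#'
#' Intersection of the tangents to the basilar edge of the symphysis and the
#' basilar edge of the horizontal branch, in the axial plane; the basilar
#' symphysis angle is the angle of the same tangent pair on the bone side.
#'
#' @param t_symphysis,t_body Axial `line2d` tangents.
#' @param witness Bone-side 2D point for the angle convention.
#' @return List with `point` (2D) and `angle` (deg).
#' @export
basilar_inflexion <- function(t_symphysis, t_body, witness) {
  list(point = line_intersection(t_symphysis, t_body),
       angle = angle_between_lines(t_symphysis, t_body, witness))
}

#' Alveolar inflexion point
#'
#' Intersection of the tangents to the alveolar vestibular borders of the
#' incisor/canine and the molar regions (axial plane). Same contract as
#' [basilar_inflexion()].
#'
#' @inheritParams basilar_inflexion
#' @param t_incisor_canine,t_molar Axial `line2d` tangents.
#' @return List with `point` (2D) and `angle` (deg).
#' @export
alveolar_inflexion <- function(t_incisor_canine, t_molar, witness) {
  list(point = line_intersection(t_incisor_canine, t_molar),
       angle = angle_between_lines(t_incisor_canine, t_molar, witness))
}

#' Canine angle
#'
#' The angle at the canine between the incisor-canine and canine-molar
#' directions, computed on the axial-plane projections of the inter-incisor,
#' canine and distal-molar landmarks.
#'
#' @param ls A `landmark_set`.
#' @param side `"L"` or `"R"`.
#' @param frame Optional `anatomical_frame` (built from `ls` if omitted).
#' @return Angle in degrees, open interval (0, 180).
#' @export
canine_angle <- function(ls, side, frame = NULL) {
  ls <- as_landmark_set(ls)
  if (is.null(frame)) frame <- build_anatomical_frame(ls)
  pts <- to_frame(rbind(lmk(ls, "inter_incisor"),
                        lmk(ls, "canine", side),
                        lmk(ls, "molar_distal", side)), frame)[, 1:2]
  v1 <- pts[1, ] - pts[2, ]
  v2 <- pts[3, ] - pts[2, ]
  if (vnorm(v1) < 1e-9 || vnorm(v2) < 1e-9) stop("coincident landmarks for the canine angle")
  ang <- acos(max(-1, min(1, sum(unit(v1) * unit(v2))))) * 180 / pi
  if (ang <= 1e-9 || ang >= 180 - 1e-9)
    stop("degenerate canine angle: incisor, canine and molar are collinear")
  ang
}

# perpendicular of `axis` pointing away from `witness` at the band midpoint
perp_away <- function(axis, mid, witness) {
  p <- c(axis[2], -axis[1])
  if (sum(p * (witness - mid)) > 0) p <- -p
  unit(p)
}

#' Measure one mandible
#'
#' Runs the full protocol: anatomical frame, lateral and axial silhouettes,
#' tangent/bisector constructions, and the sixteen values (six bilateral
#' measurements on both sides plus four single measurements). Lengths are
#' reported in cm, angles in degrees.
#'
#' @param mesh A `surface_mesh` (mm).
#' @param lm A `landmark_file` or `landmark_set` for the same subject.
#' @return Object of class `measurement_record`: a one-row tibble.
#' @export
measure_subject <- function(mesh, lm) {
  ls <- as_landmark_set(lm)
  frame <- build_anatomical_frame(ls)
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(what, ": ", conditionMessage(e), call. = FALSE))
  }

  P <- function(name, side = "M") as.numeric(to_frame(lmk(ls, name, side), frame))
  chin <- P("mental_protuberance"); inc <- P("inter_incisor")
  h <- inc[3]
  if (h <= 0) stop("inter-incisor point is not above the chin; frame construction failed")
  z_alv <- mean(c(inc[3], P("canine", "L")[3], P("canine", "R")[3],
                  P("molar_distal", "L")[3], P("molar_distal", "R")[3]))

  out <- list()
  gon3 <- list()
  # --- lateral constructions: gonial angle and gonion, per side ------------
  for (sd in c("L", "R")) {
    cond <- P("posterior_condyle", sd)
    fora <- P("mental_foramen_basilar", sd)
    contour <- step(paste0("gonial_angle_", sd),
                    project_silhouette(mesh, frame, paste0("lateral_", sd)))
    # bone-side witness: a point just above the basilar border at the mental
    # foramen is inside the gonial sector for any ramus inclination (the
    # condyle/foramen midpoint can drift behind the corner at extreme angles)
    wit <- c(fora[2], fora[3] + 0.25 * (cond[3] - fora[3]))
    # band from the condyle straight down to the basilar level, so only the
    # posterior border (and the gonial corner region) is in play
    t_ram <- step(paste0("gonial_angle_", sd, " ramus tangent"),
                  supporting_tangent(contour, rbind(cond[2:3], c(cond[2], fora[3])),
                                     c(-1, 0)))
    t_bod <- step(paste0("gonial_angle_", sd, " body tangent"),
                  supporting_tangent(contour,
                                     rbind(fora[2:3], c(cond[2], fora[3])), c(0, -1)))
    g <- step(paste0("gonion_", sd), locate_gonion(t_ram, t_bod, contour, wit))
    out[[paste0("gonial_angle_", sd)]] <- g$angle
    gon3[[sd]] <- step(paste0("gonion_", sd, " lift"),
                       lift_lateral_point(g$point, mesh, frame, sd))
  }

  # --- axial basilar constructions ----------------------------------------
  bas <- step("basilar silhouette",
              project_silhouette(mesh, frame, "axial",
                                 region = list(zmax = 0.12 * h, near = chin[1:2])))
  fmid <- (P("mental_foramen_basilar", "L")[1:2] + P("mental_foramen_basilar", "R")[1:2]) / 2
  infl3 <- list()
  z_bas <- mean(c(chin[3], P("mental_foramen_basilar", "L")[3],
                  P("mental_foramen_basilar", "R")[3]))
  for (sd in c("L", "R")) {
    sgn <- if (sd == "L") -1 else 1
    fora <- P("mental_foramen_basilar", sd)
    cond <- P("posterior_condyle", sd)
    t_sym <- step(paste0("basilar_angle_", sd, " symphysis tangent"),
                  supporting_tangent(bas, rbind(chin[1:2], fora[1:2]), c(0, 1)))
    t_bod <- step(paste0("basilar_angle_", sd, " body tangent"),
                  supporting_tangent(bas, rbind(fora[1:2], cond[1:2]), c(sgn, 0)))
    bi <- step(paste0("basilar_inflexion_", sd), basilar_inflexion(t_sym, t_bod, fmid))
    out[[paste0("basilar_angle_", sd)]] <- bi$angle
    infl3[[sd]] <- c(bi$point, z_bas)
  }

  # --- axial alveolar constructions ---------------------------------------
  mmid <- (P("molar_distal", "L")[1:2] + P("molar_distal", "R")[1:2]) / 2
  alv <- step("alveolar silhouette",
              project_silhouette(mesh, frame, "axial",
                                 region = list(zmin = z_alv - 0.15 * h,
                                               near = (inc[1:2] + mmid) / 2)))
  alv3 <- list()
  for (sd in c("L", "R")) {
    sgn <- if (sd == "L") -1 else 1
    mol <- P("molar_distal", sd)
    t_ic <- step(paste0("alveolar_inflexion_", sd, " incisor tangent"),
                 supporting_tangent(alv, rbind(inc[1:2], mol[1:2]), unit(c(0.3 * sgn, 1))))
    t_mo <- step(paste0("alveolar_inflexion_", sd, " molar tangent"),
                 supporting_tangent(alv, rbind(inc[1:2], mol[1:2]), c(sgn, 0)))
    ai <- step(paste0("alveolar_inflexion_", sd), alveolar_inflexion(t_ic, t_mo, mmid))
    alv3[[sd]] <- c(ai$point, z_alv)
  }

  # --- canine angles and distances ----------------------------------------
  for (sd in c("L", "R")) {
    out[[paste0("canine_angle_", sd)]] <-
      step(paste0("canine_angle_", sd), canine_angle(ls, sd, frame))
    out[[paste0("vertical_posterior_dimension_", sd)]] <-
      vnorm(P("upper_condyle", sd) - gon3[[sd]]) / 10
    out[[paste0("dentate_length_", sd)]] <-
      vnorm(P("molar_distal", sd) - P("canine", sd)) / 10
    out[[paste0("basilar_body_length_", sd)]] <-
      vnorm(gon3[[sd]] - infl3[[sd]]) / 10
  }
  out$basilar_symphysis_length <- vnorm(infl3$R - infl3$L) / 10
  out$alveolar_symphysis_length <- vnorm(alv3$R - alv3$L) / 10
  out$symphyseal_height <- vnorm(inc - chin) / 10
  out$bigonial_length <- vnorm(gon3$R - gon3$L) / 10

  measurement_record(subject_id = attr(ls, "subject_id") %||% "subject",
                     sex = attr(ls, "sex") %||% "unknown",
                     age = attr(ls, "age"), values = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

measurement_names <- function() {
  c(paste0(rep(c("gonial_angle", "basilar_angle", "canine_angle",
                 "vertical_posterior_dimension", "dentate_length",
                 "basilar_body_length"), each = 2), c("_L", "_R")),
    "basilar_symphysis_length", "alveolar_symphysis_length",
    "symphyseal_height", "bigonial_length")
}

angle_measurements <- function() c("gonial_angle", "basilar_angle", "canine_angle")
bilateral_measurements <- function() c("gonial_angle", "basilar_angle", "canine_angle",
                                       "vertical_posterior_dimension", "dentate_length",
                                       "basilar_body_length")
single_measurements <- function() c("basilar_symphysis_length", "alveolar_symphysis_length",
                                    "symphyseal_height", "bigonial_length")

#' Assemble a validated measurement record
#'
#' @param subject_id,sex,age Subject metadata.
#' @param values Named list/vector with the sixteen measurement values
#'   (angles in degrees, lengths in cm).
#' @return One-row tibble of class `measurement_record`.
#' @export
measurement_record <- function(subject_id, sex = "unknown", age = NA, values) {
  need <- measurement_names()
  values <- as.list(values)
  miss <- setdiff(need, names(values))
  if (length(miss)) stop("measurement record incomplete; missing: ",
                         paste(miss, collapse = ", "))
  v <- unlist(values[need])
  angles <- grepl("angle", need)
  if (any(!is.finite(v))) stop("non-finite measurement values")
  if (any(v[angles] <= 0 | v[angles] >= 180))
    stop("angles must lie in (0, 180) degrees")
  if (any(v[!angles] <= 0)) stop("lengths must be positive")
  rec <- tibble::tibble(subject_id = as.character(subject_id), sex = sex,
                        age = if (is.null(age)) NA_real_ else as.numeric(age))
  for (nm in need) rec[[nm]] <- as.numeric(values[[nm]])
  class(rec) <- c("measurement_record", class(rec))
  rec
}
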