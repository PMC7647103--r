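# Shared synthetic fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default (reference female means, left/right asymmetric) subject
default_subject <- function() fixture("default", function() {
  mm <- make_mandible(mandible_params(), subject_id = "S1", sex = "female", age = 30)
  mm$record <- measure_subject(mm$mesh, mm$truth$landmarks)
  mm
})

# fully symmetric subject with a sharp gonial corner
symmetric_subject <- function() fixture("symmetric", function() {
  p <- mandible_params(gonial_angle = 120, basilar_symphysis_angle = 120,
                       canine_angle = 114, ramus_height = 6,
                       basilar_body_length = 7.3, dentate_length = 3.8,
                       fillet_radius = 0)
  mm <- make_mandible(p, subject_id = "SYM", sex = "unknown")
  mm$record <- measure_subject(mm$mesh, mm$truth$landmarks)
  mm
})

measurement_cols <- function() mandimorph:::measurement_names()

rotation_matrix <- function(yaw, pitch, roll) {
  Rz <- rbind(c(cos(yaw), -sin(yaw), 0), c(sin(yaw), cos(yaw), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(pitch), 0, sin(pitch)), c(0, 1, 0), c(-sin(pitch), 0, cos(pitch)))
  Rx <- rbind(c(1, 0, 0), c(0, cos(roll), -sin(roll)), c(0, sin(roll), cos(roll)))
  Rz %*% Ry %*% Rx
}

transform_landmark_file <- function(lf, R = diag(3), t = c(0, 0, 0), scale = 1) {
  xyz <- scale * as.matrix(lf$landmarks[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, -as.numeric(t))
  lf$landmarks$x <- xyz[, 1]; lf$landmarks$y <- xyz[, 2]; lf$landmarks$z <- xyz[, 3]
  lf
}

mirror_landmark_file <- function(lf) {
  lf$landmarks$x <- -lf$landmarks$x
  lf$landmarks$side <- chartr("LR", "RL", lf$landmarks$side)
  lf
}

mirror_surface_mesh <- function(mesh) {
  V <- mesh$vertices
  V[, 1] <- -V[, 1]
  surface_mesh(V, mesh$faces[, c(1, 3, 2), drop = FALSE])
}

swap_side <- function(nm) {
  ifelse(grepl("_L$", nm), sub("_L$", "_R", nm),
         ifelse(grepl("_R$", nm), sub("_R$", "_L", nm), nm))
}

# small deterministic convex polygons (CCW) for geometry property tests
random_convex_polygon <- function(n, seed) {
  set.seed(seed)
  pts <- cbind(runif(3 * n, -1, 1), runif(3 * n, -1, 1))
  h <- rev(grDevices::chull(pts))
  pts[h, , drop = FALSE]
}

# boundary points of a closed polygon clipped to the slab between two
# anchors (plain re-statement of the band definition, for the oracle)
band_points <- function(poly, anchors) {
  axis <- anchors[2, ] - anchors[1, ]
  L2 <- sum(axis^2)
  s_of <- function(p) sum((p - anchors[1, ]) * axis) / L2
  n <- nrow(poly)
  out <- NULL
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    sa <- s_of(a); sb <- s_of(b)
    if (max(sa, sb) < 0 || min(sa, sb) > 1) next
    ts <- c(0, 1)
    if (sb != sa) ts <- pmin(1, pmax(0, sort(c((0 - sa) / (sb - sa), (1 - sa) / (sb - sa)))))
    out <- rbind(out, a + ts[1] * (b - a), a + ts[2] * (b - a))
  }
  unique(out)
}

# brute-force supporting line: over all directed point pairs, keep lines with
# every point on one side, return the one whose outward normal best matches
# `outward` (independent of the hull-edge implementation)
brute_force_tangent <- function(pts, outward) {
  outward <- outward / sqrt(sum(outward^2))
  n <- nrow(pts)
  best <- NULL; best_score <- -Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(d^2))
    if (len < 1e-12) next
    cr <- (pts[, 1] - pts[i, 1]) * d[2] - (pts[, 2] - pts[i, 2]) * d[1]
    if (any(cr > 1e-9)) next              # all points on the left of i -> j
    nrm <- c(d[2], -d[1]) / len           # outward normal (away from the points)
    score <- sum(nrm * outward)
    if (score > best_score + 1e-12 ||
        (score > best_score - 1e-12 && !is.null(best) && len > best$len)) {
      best_score <- score
      best <- list(anchor = pts[i, ], direction = d / len, len = len)
    }
  }
  best
}
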