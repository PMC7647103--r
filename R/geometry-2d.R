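# 2D geometric primitives used by the tangent/bisector measurement protocol.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

#' A 2D line through an anchor point
#'
#' Lines are stored as an anchor point plus a unit direction. They represent
#' the tangents of the measurement protocol (posterior ramus border, basilar
#' edges, alveolar borders), so only the undirected line matters; the stored
#' direction is a representative.
#'
#' @param anchor Numeric length-2 point on the line (mm).
#' @param direction Numeric length-2 direction; normalised internally.
#' @return An object of class `line2d`.
#' @export
line2d <- function(anchor, direction) {
  stopifnot(length(anchor) == 2, length(direction) == 2,
            all(is.finite(anchor)), all(is.finite(direction)))
  structure(list(anchor = as.numeric(anchor), direction = unit(as.numeric(direction))),
            class = "line2d")
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d> through (%.3f, %.3f) along (%.4f, %.4f)\n",
              x$anchor[1], x$anchor[2], x$direction[1], x$direction[2]))
  invisible(x)
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' Intersection point of two 2D lines
#'
#' @param a,b `line2d` objects.
#' @param tol Parallelism tolerance on the sine of the angle between them.
#' @return Numeric length-2 intersection point.
#' @export
line_intersection <- function(a, b, tol = 1e-12) {
  d <- cross2(a$direction, b$direction)
  if (abs(d) < tol) stop("lines are parallel (or nearly so): no intersection point")
  t <- cross2(b$anchor - a$anchor, b$direction) / d
  a$anchor + t * a$direction
}

#' Angle between two lines, disambiguated by a bone-side witness point
#'
#' A pair of intersecting lines defines two supplementary angles; the
#' measurement protocol always reports the angle of the sector that contains
#' the bone (all printed mandibular angles are obtuse). Both line directions
#' are flipped to point from the intersection towards the witness, and the
#' angle between the flipped directions is returned.
#'
#' @param a,b `line2d` tangent lines.
#' @param witness Length-2 point on the bone side (e.g. the silhouette
#'   centroid).
#' @return Angle in degrees, in the open interval (0, 180).
#' @export
angle_between_lines <- function(a, b, witness) {
  s <- sector_rays(a, b, witness)
  ang <- acos(max(-1, min(1, sum(s$da * s$db)))) * 180 / pi
  if (ang <= 0 || ang >= 180) stop("degenerate angle: lines are collinear at this tolerance")
  ang
}

# The two rays bounding the sector (of the four cut out by the line pair)
# that contains the witness: each direction is oriented to lie inside the
# other line's witness half-plane.
sector_rays <- function(a, b, witness) {
  p <- line_intersection(a, b)
  w <- as.numeric(witness) - p
  if (vnorm(w) == 0) stop("witness point coincides with the line intersection")
  na <- c(-a$direction[2], a$direction[1])
  nb <- c(-b$direction[2], b$direction[1])
  sa <- sign(sum(na * w)); if (sa == 0) sa <- 1
  sb <- sign(sum(nb * w)); if (sb == 0) sb <- 1
  da <- if (sign(sum(nb * a$direction)) == sb) a$direction else -a$direction
  db <- if (sign(sum(na * b$direction)) == sa) b$direction else -b$direction
  list(origin = p, da = da, db = db)
}

# Interior bisector ray of the sector containing `witness`.
interior_bisector <- function(a, b, witness) {
  s <- sector_rays(a, b, witness)
  list(origin = s$origin, direction = unit(s$da + s$db))
}

# First intersection of the ray origin + t*direction (t >= -tol) with a closed
# polygon boundary; returns the hit point or NULL.
ray_polygon_first_hit <- function(origin, direction, poly, tol = 1e-9) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]
  ey <- b[, 2] - a[, 2]
  denom <- direction[1] * ey - direction[2] * ex
  qx <- a[, 1] - origin[1]
  qy <- a[, 2] - origin[2]
  t <- (qx * ey - qy * ex) / denom
  u <- (qx * direction[2] - qy * direction[1]) / denom
  scale <- max(abs(range(poly))) + 1
  ok <- is.finite(t) & is.finite(u) & t >= -tol * scale & u >= -tol & u <= 1 + tol
  if (!any(ok)) return(NULL)
  tmin <- min(t[ok])
  origin + max(tmin, 0) * direction
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Drop consecutive duplicate and collinear vertices of a closed polygon.
clean_polygon <- function(poly, tol = 1e-9) {
  scale <- max(1, max(abs(poly)))
  n <- nrow(poly)
  if (n < 3) return(poly)
  keep <- rep(TRUE, n)
  prev <- poly[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  dup <- rowSums(abs(poly - prev)) < tol * scale
  v1 <- poly - prev
  v2 <- nxt - poly
  col <- abs(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]) < tol * scale^2
  keep <- !(dup | (col & !dup & rowSums(abs(v2)) > 0))
  out <- poly[keep, , drop = FALSE]
  if (nrow(out) < 3) poly else out
}

#' Supporting tangent line of a silhouette band
#'
#' Deterministic stand-in for the manually drawn tangents of the measurement
#' protocol: among the convex-hull edges of the boundary vertices lying in the
#' band between two anchor points, the edge whose outward normal best aligns
#' with the requested outside direction is returned as the tangent line. The
#' whole band then lies on one side of the line and the line touches at least
#' one boundary vertex.
#'
#' @param contour A `planar_contour` (or plain 2-column matrix of boundary
#'   vertices).
#' @param anchors 2x2 matrix (rows = the two anchor points) delimiting the
#'   band: vertices are kept if their projection on the anchor axis falls
#'   between the anchors.
#' @param outward Length-2 direction pointing from the bone outwards across
#'   the sought tangent (e.g. `c(0, -1)` for a tangent supporting the contour
#'   from below).
#' @return A `line2d` with the contour on its bone side.
#' @export
supporting_tangent <- function(contour, anchors, outward) {
  pts <- if (inherits(contour, "planar_contour")) contour$vertices else as.matrix(contour)
  anchors <- as.matrix(anchors)
  stopifnot(nrow(anchors) == 2, ncol(anchors) == 2)
  axis <- anchors[2, ] - anchors[1, ]
  L2 <- sum(axis^2)
  if (L2 == 0) stop("band anchors coincide")
  # clip every boundary edge to the band slab so that straight silhouette
  # edges contribute in-band points even where their corner vertices fall
  # outside the band
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  sa <- ((a[, 1] - anchors[1, 1]) * axis[1] + (a[, 2] - anchors[1, 2]) * axis[2]) / L2
  sb <- ((b[, 1] - anchors[1, 1]) * axis[1] + (b[, 2] - anchors[1, 2]) * axis[2]) / L2
  clip_band <- function(lo, hi) {
    keep <- pmax(sa, sb) >= lo & pmin(sa, sb) <= hi
    if (!any(keep)) return(NULL)
    band <- NULL
    for (i in which(keep)) {
      t0 <- 0; t1 <- 1
      ds <- sb[i] - sa[i]
      if (abs(ds) > 0) {
        tt <- sort(c((lo - sa[i]) / ds, (hi - sa[i]) / ds))
        t0 <- max(0, tt[1]); t1 <- min(1, tt[2])
      }
      if (t1 < t0) next
      band <- rbind(band,
                    a[i, ] + t0 * (b[i, ] - a[i, ]),
                    a[i, ] + t1 * (b[i, ] - a[i, ]))
    }
    if (!is.null(band)) band <- unique(band)
    band
  }
  band <- clip_band(0, 1)
  # misplaced anchors (e.g. heavy landmark noise) may leave the slab off the
  # contour; widen it once before giving up
  if (is.null(band) || nrow(band) < 2) band <- clip_band(-0.5, 1.5)
  if (is.null(band) || nrow(band) < 2)
    stop("no silhouette boundary between the anchors; move the anchors apart")
  hull_tangent(band, outward)
}

# Tangent = hull edge of a point set maximising outward-normal alignment.
hull_tangent <- function(pts, outward) {
  outward <- unit(as.numeric(outward))
  h <- grDevices::chull(pts)      # clockwise order
  h <- rev(h)                     # counter-clockwise
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m == 2) {
    d <- hp[2, ] - hp[1, ]
    return(line2d(hp[1, ], d))
  }
  nxt <- c(2:m, 1)
  ex <- hp[nxt, 1] - hp[, 1]
  ey <- hp[nxt, 2] - hp[, 2]
  len <- sqrt(ex^2 + ey^2)
  # micro-edges (clip artefacts, coincident points) carry no direction
  # information and must not be selected as tangents
  diagl <- sqrt(diff(range(hp[, 1]))^2 + diff(range(hp[, 2]))^2)
  ok <- len > 2e-3 * diagl
  if (!any(ok)) ok <- len >= max(len)
  # outward normal of a CCW polygon edge (dx,dy) is (dy,-dx)
  score <- (ey * outward[1] - ex * outward[2]) / len
  score[!ok] <- -Inf
  i <- which.max(score)
  dir <- c(ex[i], ey[i]) / len[i]
  # refit through the band points lying on the supporting line (within a
  # small tolerance): points that are collinear but for micrometre
  # projection wobble otherwise rotate the tangent by sub-degree amounts.
  # The line through the two most separated on-line points bounds the
  # rotation by tolerance / chord length even if a few slightly curved
  # neighbours are collected.
  off <- (pts[, 1] - hp[i, 1]) * dir[2] - (pts[, 2] - hp[i, 2]) * dir[1]
  on_line <- which(abs(off) <= 1e-4 * diagl)
  if (length(on_line) > 2) {
    q <- pts[on_line, , drop = FALSE]
    s <- q %*% dir
    a <- which.min(s); b <- which.max(s)
    if (s[b] - s[a] > len[i] / 2) return(line2d(q[a, ], q[b, ] - q[a, ]))
  }
  line2d(hp[i, ], c(ex[i], ey[i]))
}

# Clip a convex polygon by a half-plane {x : dot(n, x) <= c}. Used by the
# synthetic generator for closed-form silhouette areas.
clip_convex <- function(poly, n, c) {
  m <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  d <- poly %*% n - c
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, poly[i, ])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}
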