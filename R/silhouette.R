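# Planar silhouettes of a mandible mesh.
#
# The tangent constructions of the measurement protocol are drawn on 2D
# silhouettes: each hemimandible projected onto its lateral (sagittal-
# parallel) plane for the gonial construction, and basilar/alveolar z-bands
# projected onto the axial plane for the inflexion constructions. The
# silhouette is the exact outer boundary of the union of the projected
# triangles (continuous coordinates, no voxel grid).

#' Project a mesh silhouette onto an anatomical plane
#'
#' @param mesh A `surface_mesh`.
#' @param frame An `anatomical_frame`.
#' @param plane `"lateral_L"`, `"lateral_R"` (2D coordinates = anterior, up)
#'   or `"axial"` (2D coordinates = right, anterior).
#' @param region Optional list restricting which faces are projected, by face
#'   centroid in frame coordinates: `zmin`, `zmax` (mm) and, for axial
#'   projections, `side` (`"L"`/`"R"`). A `near` 2D point selects, among
#'   disconnected silhouette components, the loop containing (or closest to)
#'   it; otherwise the largest loop is returned.
#' @return Object of class `planar_contour`: list with `plane`, `vertices`
#'   (counter-clockwise closed polygon, 2 columns, mm), `area` (mm^2),
#'   `centroid`, and all `loops`.
#' @export
project_silhouette <- function(mesh, frame, plane = c("lateral_L", "lateral_R", "axial"),
                               region = list()) {
  plane <- match.arg(plane)
  Vf <- to_frame(mesh$vertices, frame)
  F <- mesh$faces
  cen <- (Vf[F[, 1], , drop = FALSE] + Vf[F[, 2], , drop = FALSE] + Vf[F[, 3], , drop = FALSE]) / 3

  keep <- rep(TRUE, nrow(F))
  side <- switch(plane, lateral_L = "L", lateral_R = "R", region$side)
  if (!is.null(side)) {
    sgn <- if (side == "L") -1 else 1
    keep <- keep & (sgn * cen[, 1] > 0)
  }
  if (!is.null(region$zmin)) keep <- keep & cen[, 3] >= region$zmin
  if (!is.null(region$zmax)) keep <- keep & cen[, 3] <= region$zmax
  if (!any(keep)) stop("empty projection: no faces in the requested region (", plane, ")")

  # faces nearly parallel to the projection direction (within ~3 degrees)
  # contribute no silhouette area but project to micro-slivers that poison
  # the boundary extraction; drop them
  e1 <- Vf[F[, 2], , drop = FALSE] - Vf[F[, 1], , drop = FALSE]
  e2 <- Vf[F[, 3], , drop = FALSE] - Vf[F[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- sqrt(rowSums(nrm^2))
  proj_axis <- if (plane == "axial") 3 else 1
  keep <- keep & nl > 0 & abs(nrm[, proj_axis]) >= 0.05 * nl
  if (!any(keep)) stop("empty projection: no silhouette-bearing faces in the region (", plane, ")")

  Fk <- F[keep, , drop = FALSE]
  cols <- if (plane == "axial") c(1, 2) else c(2, 3)
  tris <- array(0, c(nrow(Fk), 3, 2))
  for (j in 1:3) tris[, j, ] <- Vf[Fk[, j], cols, drop = FALSE]

  loops <- triangle_union_loops(tris)
  pick <- 1L
  if (!is.null(region$near) && length(loops) > 1) {
    p <- as.numeric(region$near)
    score <- vapply(loops, function(lp) {
      if (point_in_polygon(p, lp)) 0 else min(sqrt((lp[, 1] - p[1])^2 + (lp[, 2] - p[2])^2))
    }, numeric(1))
    pick <- which.min(score)
  }
  outer <- loops[[pick]]
  structure(list(plane = plane, vertices = outer,
                 area = polygon_area(outer),
                 centroid = polygon_centroid(outer),
                 loops = loops),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour> %s: %d vertices, area %.1f mm^2 (%d loop%s)\n",
              x$plane, nrow(x$vertices), x$area, length(x$loops),
              if (length(x$loops) == 1) "" else "s"))
  invisible(x)
}

point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  j <- c(n, 1:(n - 1))
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- poly[j, 1]; yj <- poly[j, 2]
  cross <- ((yi > p[2]) != (yj > p[2])) &
    (p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi)
  sum(cross) %% 2 == 1
}

# Lift a 2D lateral-silhouette point back to the 3D surface: among that
# side's mesh vertices near the inverse-projection line, take the most
# lateral one (the outer cortex). The tie-band is adaptive: a slightly
# tilted frame smears the projection of an edge running across the bone by
# up to thickness * tilt, so a plain nearest-vertex rule can snap to the
# medial cortex (a full bone-width away); preferring the lateral vertex
# within a small 2D neighbourhood recovers the bony point.
lift_lateral_point <- function(p2, mesh, frame, side) {
  sgn <- if (side == "L") -1 else 1
  Vf <- to_frame(mesh$vertices, frame)
  sel <- sgn * Vf[, 1] > 0
  Vs <- Vf[sel, , drop = FALSE]
  if (!nrow(Vs)) stop("no mesh vertices on side ", side)
  d2 <- sqrt((Vs[, 2] - p2[1])^2 + (Vs[, 3] - p2[2])^2)
  rng <- apply(Vf, 2, range)
  diagl <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  near <- which(d2 <= min(d2) + 0.02 * diagl)
  # among the near vertices, keep the lateral cortex (within a band wide
  # enough to track surface relief but far narrower than the bone width),
  # then take the nearest of those
  lat <- sgn * Vs[near, 1]
  outer <- near[lat >= max(lat) - 0.025 * diagl]
  i <- outer[which.min(d2[outer])]
  Vs[i, ]
}
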