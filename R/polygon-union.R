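# Outer boundary of a union of projected triangles.
#
# Silhouettes are computed exactly in continuous coordinates: every projected
# triangle edge is split at its intersections with all other edges, each
# sub-segment is classified by probing just inside/outside of its midpoint,
# and the surviving boundary segments are chained into closed loops. No
# rasterisation is involved.

# tris: n x 3 x 2 array (triangle, vertex, xy). Returns a list of CCW loops
# (2-column matrices), largest area first.
triangle_union_loops <- function(tris, tol = 1e-9) {
  stopifnot(length(dim(tris)) == 3, dim(tris)[2] == 3, dim(tris)[3] == 2)
  n <- dim(tris)[1]
  if (n == 0) stop("empty projection: no triangles to outline")

  ax <- tris[, 1, 1]; ay <- tris[, 1, 2]
  bx <- tris[, 2, 1]; by <- tris[, 2, 2]
  cx <- tris[, 3, 1]; cy <- tris[, 3, 2]

  diag2 <- (max(ax, bx, cx) - min(ax, bx, cx))^2 + (max(ay, by, cy) - min(ay, by, cy))^2
  diagl <- sqrt(diag2)

  # weld near-coincident coordinates (single-precision file round-trips
  # perturb shared edges by ~1e-5 mm; sub-tolerance arc slivers collapse to
  # exactly degenerate triangles and are dropped cleanly below)
  P <- weld_points(cbind(c(ax, bx, cx), c(ay, by, cy)), 2e-5 * diagl)
  n3 <- length(ax)
  ax <- P[1:n3, 1]; ay <- P[1:n3, 2]
  bx <- P[n3 + 1:n3, 1]; by <- P[n3 + 1:n3, 2]
  cx <- P[2 * n3 + 1:n3, 1]; cy <- P[2 * n3 + 1:n3, 2]
  area2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  keep <- abs(area2) > 1e-9 * diag2
  if (!any(keep)) stop("empty projection: all triangles are degenerate in this plane")
  ax <- ax[keep]; ay <- ay[keep]; bx <- bx[keep]; by <- by[keep]
  cx <- cx[keep]; cy <- cy[keep]; area2 <- area2[keep]
  # orient all triangles counter-clockwise
  flip <- area2 < 0
  tmp <- bx[flip]; bx[flip] <- cx[flip]; cx[flip] <- tmp
  tmp <- by[flip]; by[flip] <- cy[flip]; cy[flip] <- tmp
  nt <- length(ax)

  # directed edges, interior on the left
  ex1 <- c(ax, bx, cx); ey1 <- c(ay, by, cy)
  ex2 <- c(bx, cx, ax); ey2 <- c(by, cy, ay)
  ne <- length(ex1)

  # pairwise split parameters --------------------------------------------
  lo_x <- pmin(ex1, ex2); hi_x <- pmax(ex1, ex2)
  lo_y <- pmin(ey1, ey2); hi_y <- pmax(ey1, ey2)
  pad <- tol * diagl
  cuts <- vector("list", ne)
  Pu <- unique(cbind(c(ax, bx, cx), c(ay, by, cy)))
  h_weld <- 2e-5 * diagl

  rx <- ex2 - ex1; ry <- ey2 - ey1
  for (i in seq_len(ne)) {
    # T-junctions: split at any mesh vertex lying on this edge's interior
    li2 <- rx[i]^2 + ry[i]^2
    tv <- ((Pu[, 1] - ex1[i]) * rx[i] + (Pu[, 2] - ey1[i]) * ry[i]) / li2
    dperp <- abs((Pu[, 1] - ex1[i]) * ry[i] - (Pu[, 2] - ey1[i]) * rx[i]) / sqrt(li2)
    on_edge <- dperp <= h_weld & tv > tol & tv < 1 - tol
    if (any(on_edge)) cuts[[i]] <- tv[on_edge]
    cand <- which(lo_x <= hi_x[i] + pad & hi_x >= lo_x[i] - pad &
                  lo_y <= hi_y[i] + pad & hi_y >= lo_y[i] - pad)
    cand <- cand[cand != i]
    if (!length(cand)) next
    qx <- ex1[cand]; qy <- ey1[cand]
    sx <- rx[cand];  sy <- ry[cand]
    denom <- rx[i] * sy - ry[i] * sx
    dqx <- qx - ex1[i]; dqy <- qy - ey1[i]
    tpar <- (dqx * sy - dqy * sx) / denom
    upar <- (dqx * ry[i] - dqy * rx[i]) / denom
    crossing <- is.finite(tpar) & is.finite(upar) &
      tpar > tol & tpar < 1 - tol & upar >= -tol & upar <= 1 + tol
    ts <- c(cuts[[i]], tpar[crossing])
    # collinear overlaps: project the other edge's endpoints onto this edge
    coll <- abs(denom) <= tol * diag2 &
      abs(dqx * ry[i] - dqy * rx[i]) <= tol * diag2
    if (any(coll)) {
      t0 <- (dqx[coll] * rx[i] + dqy[coll] * ry[i]) / li2
      t1 <- ((dqx[coll] + sx[coll]) * rx[i] + (dqy[coll] + sy[coll]) * ry[i]) / li2
      ts <- c(ts, t0[t0 > tol & t0 < 1 - tol], t1[t1 > tol & t1 < 1 - tol])
    }
    if (length(ts)) cuts[[i]] <- ts
  }

  # assemble sub-segments
  seg_from <- list(); seg_to <- list()
  for (i in seq_len(ne)) {
    ts <- sort(unique(c(0, cuts[[i]], 1)))
    ts <- ts[c(TRUE, diff(ts) > tol)]
    if (ts[length(ts)] < 1 - tol) ts <- c(ts, 1)
    p1 <- cbind(ex1[i] + ts[-length(ts)] * rx[i], ey1[i] + ts[-length(ts)] * ry[i])
    p2 <- cbind(ex1[i] + ts[-1] * rx[i], ey1[i] + ts[-1] * ry[i])
    seg_from[[i]] <- p1; seg_to[[i]] <- p2
  }
  P1 <- do.call(rbind, seg_from)
  P2 <- do.call(rbind, seg_to)

  # classify midpoints probed to each side; a second, much closer probe
  # keeps sliver triangles (thinner than the main probe distance, e.g.
  # near-vertical walls under a slightly tilted frame) from opening cracks
  mid <- (P1 + P2) / 2
  dx <- P2[, 1] - P1[, 1]; dy <- P2[, 2] - P1[, 2]
  len <- sqrt(dx^2 + dy^2)
  eps <- 1e-6 * diagl
  eps2 <- eps / 64
  nxl <- -dy / len; nyl <- dx / len     # left normal
  probe <- function(s, e) points_in_any_triangle(
    cbind(mid[, 1] + s * e * nxl, mid[, 2] + s * e * nyl),
    ax, ay, bx, by, cx, cy)
  left_in <- probe(1, eps) | probe(1, eps2)
  right_in <- probe(-1, eps) | probe(-1, eps2)
  keep_fwd <- left_in & !right_in
  keep_rev <- right_in & !left_in
  A <- rbind(P1[keep_fwd, , drop = FALSE], P2[keep_rev, , drop = FALSE])
  B <- rbind(P2[keep_fwd, , drop = FALSE], P1[keep_rev, , drop = FALSE])
  if (!nrow(A)) stop("silhouette extraction failed: no boundary segments survive")

  # deduplicate coincident directed segments (e.g. top and bottom faces of a
  # prism project to the same footprint)
  h <- 1e-7 * diagl
  key <- paste(round(A[, 1] / h), round(A[, 2] / h), round(B[, 1] / h), round(B[, 2] / h))
  dup <- duplicated(key)
  A <- A[!dup, , drop = FALSE]; B <- B[!dup, , drop = FALSE]

  chain_loops(A, B, h, diagl)
}

# snap points within `h` of an earlier point onto that point (grid hash
# with neighbour-cell lookup, so cell-boundary straddling cannot split a
# cluster)
weld_points <- function(P, h) {
  gx <- round(P[, 1] / h); gy <- round(P[, 2] / h)
  reps <- new.env(hash = TRUE, parent = emptyenv())
  out <- P
  for (i in seq_len(nrow(P))) {
    found <- FALSE
    for (dx in -1:1) {
      for (dy in -1:1) {
        j <- reps[[paste(gx[i] + dx, gy[i] + dy)]]
        if (!is.null(j) &&
            (P[i, 1] - out[j, 1])^2 + (P[i, 2] - out[j, 2])^2 <= h * h) {
          out[i, ] <- out[j, ]
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) {
      k <- paste(gx[i], gy[i])
      if (is.null(reps[[k]])) reps[[k]] <- i
    }
  }
  out
}

# point-in-union test, vectorised over points with a per-triangle loop
points_in_any_triangle <- function(pts, ax, ay, bx, by, cx, cy, tol = 0) {
  np <- nrow(pts)
  inside <- rep(FALSE, np)
  px <- pts[, 1]; py <- pts[, 2]
  for (k in seq_along(ax)) {
    idx <- which(!inside)
    if (!length(idx)) break
    x <- px[idx]; y <- py[idx]
    d1 <- (bx[k] - ax[k]) * (y - ay[k]) - (by[k] - ay[k]) * (x - ax[k])
    d2 <- (cx[k] - bx[k]) * (y - by[k]) - (cy[k] - by[k]) * (x - bx[k])
    d3 <- (ax[k] - cx[k]) * (y - cy[k]) - (ay[k] - cy[k]) * (x - cx[k])
    inside[idx[d1 >= -tol & d2 >= -tol & d3 >= -tol]] <- TRUE
  }
  inside
}

# chain directed boundary segments into closed loops; leftmost turn at
# junctions keeps the walk on the outer boundary. A walk that dead-ends
# releases its segments (a wrong branch elsewhere must not consume them)
# and sub-tolerance cracks are bridged to the nearest free segment start.
chain_loops <- function(A, B, h, diagl) {
  keyA <- paste(round(A[, 1] / h), round(A[, 2] / h))
  keyB <- paste(round(B[, 1] / h), round(B[, 2] / h))
  out_map <- split(seq_along(keyA), keyA)
  n <- nrow(A)
  used <- rep(FALSE, n)
  dead <- rep(FALSE, n)     # starts whose walk failed
  loops <- list()
  for (s in seq_len(n)) {
    if (used[s] || dead[s]) next
    idx <- s
    walk <- s
    loop <- list(A[s, ])
    used[s] <- TRUE
    closed <- FALSE
    repeat {
      nk <- keyB[idx]
      loop[[length(loop) + 1]] <- B[idx, ]
      if (nk == keyA[s] && length(loop) > 2) { closed <- TRUE; break }
      cand <- out_map[[nk]]
      cand <- cand[!used[cand]]
      if (!length(cand)) {
        # bridge tiny cracks (well below any anatomical feature scale)
        free <- which(!used)
        if (!length(free)) break
        d2 <- (A[free, 1] - B[idx, 1])^2 + (A[free, 2] - B[idx, 2])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) > 1e-4 * diagl) break
        cand <- free[j]
      }
      if (length(cand) == 1) {
        nxt <- cand
      } else {
        din <- B[idx, ] - A[idx, ]
        ang <- vapply(cand, function(j) {
          d <- B[j, ] - A[j, ]
          atan2(din[1] * d[2] - din[2] * d[1], din[1] * d[1] + din[2] * d[2])
        }, numeric(1))
        nxt <- cand[which.max(ang)]   # leftmost turn
      }
      used[nxt] <- TRUE
      walk <- c(walk, nxt)
      idx <- nxt
    }
    if (closed) {
      m <- do.call(rbind, loop)
      m <- m[-nrow(m), , drop = FALSE]
      m <- clean_polygon(m)
      if (nrow(m) >= 3 && abs(polygon_area(m)) > (1e-8 * diagl)^2)
        loops[[length(loops) + 1]] <- m
    } else {
      used[walk] <- FALSE
      dead[s] <- TRUE
    }
  }
  if (!length(loops)) stop("silhouette extraction failed: boundary did not close")
  areas <- vapply(loops, function(p) abs(polygon_area(p)), numeric(1))
  loops <- loops[order(areas, decreasing = TRUE)]
  lapply(loops, function(p) if (polygon_area(p) < 0) p[nrow(p):1, , drop = FALSE] else p)
}

# Ear-clipping triangulation of a simple polygon (CCW). Returns an index
# matrix (m x 3) into the polygon's rows.
ear_clip <- function(poly) {
  n <- nrow(poly)
  stopifnot(n >= 3)
  if (polygon_area(poly) < 0) {
    poly <- poly[n:1, , drop = FALSE]
    remap <- n:1
  } else remap <- 1:n
  idx <- seq_len(n)
  tris <- matrix(integer(0), ncol = 3)
  guard <- 0
  while (length(idx) > 3 && guard < n * n) {
    guard <- guard + 1
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[if (k == 1) m else k - 1]
      i1 <- idx[k]
      i2 <- idx[if (k == m) 1 else k + 1]
      a <- poly[i0, ]; b <- poly[i1, ]; c <- poly[i2, ]
      if (cross2(b - a, c - b) <= 0) next       # reflex
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others)) {
        px <- poly[others, 1]; py <- poly[others, 2]
        d1 <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
        d2 <- (c[1] - b[1]) * (py - b[2]) - (c[2] - b[2]) * (px - b[1])
        d3 <- (a[1] - c[1]) * (py - c[2]) - (a[2] - c[2]) * (px - c[1])
        # vertices on the candidate ear's boundary block it too (a reflex
        # vertex exactly on the diagonal would otherwise cause overlap)
        eps <- 1e-12 * max(abs(poly))^2
        if (any(d1 >= -eps & d2 >= -eps & d3 >= -eps)) next
      }
      tris <- rbind(tris, c(i0, i1, i2))
      idx <- idx[-k]
      clipped <- TRUE
      break
    }
    if (!clipped) stop("ear clipping failed: polygon may be self-intersecting")
  }
  tris <- rbind(tris, idx)
  matrix(remap[tris], ncol = 3)
}
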