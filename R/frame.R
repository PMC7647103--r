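# Anatomical reference frame of one mandible.
#
# Axes: x = right (mid-sagittal normal), y = anterior, z = up; origin at the
# mental protuberance. The mid-sagittal plane is the best-fit plane through
# the midpoints of the bilateral landmark pairs, constrained to contain the
# chin-to-inter-incisor direction. The up axis comes from the basilar plane
# fitted to the two basilar mental-foramen points and the chin (the
# mandibular-plane convention), orthogonalised against the sagittal normal
# and signed so the condyles lie above the body.

#' Build the anatomical frame from a landmark set
#'
#' @param ls A `landmark_set` (see [as_landmark_set()]).
#' @return Object of class `anatomical_frame`: list with `origin` (mm) and
#'   `axes`, a 3x3 matrix whose columns are the right, anterior and up unit
#'   vectors (orthonormal, right-handed).
#' @export
build_anatomical_frame <- function(ls) {
  ls <- as_landmark_set(ls)
  prot <- lmk(ls, "mental_protuberance")
  incisor <- lmk(ls, "inter_incisor")
  a <- incisor - prot
  if (vnorm(a) < 1e-9) stop("degenerate landmarks: chin and inter-incisor coincide")
  a <- unit(a)

  mids <- t(vapply(lm_bilateral,
                   function(nm) (lmk(ls, nm, "L") + lmk(ls, nm, "R")) / 2,
                   numeric(3)))
  pts <- rbind(mids, incisor, prot)

  # deterministic in-plane basis orthogonal to the constraint axis
  r <- colSums(t(vapply(lm_bilateral,
                        function(nm) lmk(ls, nm, "R") - lmk(ls, nm, "L"),
                        numeric(3)))) / length(lm_bilateral)
  e1 <- r - sum(r * a) * a
  if (vnorm(e1) < 1e-9) stop("degenerate landmarks: left-right axis parallel to the symphysis axis")
  e1 <- unit(e1)
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])

  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  u <- pc %*% e1
  w <- pc %*% e2
  sxx <- sum(u * u); syy <- sum(w * w); sxy <- sum(u * w)
  if (sxx + syy < 1e-12)
    stop("degenerate landmarks: collinear midpoints, mid-sagittal plane undetermined")
  # major principal direction of the 2x2 scatter, closed form
  d <- sxx - syy
  rt <- sqrt(d * d + 4 * sxy * sxy)
  if (d >= 0) v <- c(d + rt, 2 * sxy) else v <- c(2 * sxy, rt - d)
  if (vnorm(v) < 1e-12 * (sxx + syy)) v <- c(1, 0)
  v <- unit(v)
  n2 <- c(-v[2], v[1])                       # minor axis = plane normal in (e1, e2)
  ex <- n2[1] * e1 + n2[2] * e2
  if (sum(ex * r) < 0) ex <- -ex             # point towards the right side

  # basilar (mandibular) plane for the up axis
  fL <- lmk(ls, "mental_foramen_basilar", "L")
  fR <- lmk(ls, "mental_foramen_basilar", "R")
  b1 <- fL - prot; b2 <- fR - prot
  nb <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  if (vnorm(nb) < 1e-9) stop("degenerate landmarks: basilar points are collinear")
  ez <- nb - sum(nb * ex) * ex
  if (vnorm(ez) < 1e-9) stop("degenerate landmarks: basilar normal parallel to sagittal normal")
  ez <- unit(ez)
  cond_mid <- (lmk(ls, "upper_condyle", "L") + lmk(ls, "upper_condyle", "R")) / 2
  if (sum((cond_mid - prot) * ez) < 0) ez <- -ez
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])

  fr <- structure(list(origin = prot, axes = cbind(right = ex, anterior = ey, up = ez)),
                  class = "anatomical_frame")
  validate_frame(fr, ls)
  fr
}

validate_frame <- function(fr, ls) {
  G <- crossprod(fr$axes)
  if (max(abs(G - diag(3))) > 1e-8) stop("frame axes are not orthonormal")
  if (det(fr$axes) < 0) stop("frame is not right-handed")
  # left and right landmark pairs should fall on opposite sides of the
  # plane; heavy placement noise can violate this near the midline, so it
  # is reported rather than fatal
  for (nm in lm_bilateral) {
    sL <- sum((lmk(ls, nm, "L") - fr$origin) * fr$axes[, 1])
    sR <- sum((lmk(ls, nm, "R") - fr$origin) * fr$axes[, 1])
    if (!(sL < 0 && sR > 0))
      warning("mid-sagittal plane does not separate the ", nm, " pair",
              call. = FALSE)
  }
  cond_mid <- (lmk(ls, "posterior_condyle", "L") + lmk(ls, "posterior_condyle", "R")) / 2
  if (sum((fr$origin - cond_mid) * fr$axes[, 2]) < 0)
    stop("anterior axis points backwards; landmark configuration inconsistent")
  invisible(fr)
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n  origin:", sprintf("%.2f", x$origin), "mm\n")
  for (i in 1:3)
    cat(" ", colnames(x$axes)[i], ":", sprintf("% .4f", x$axes[, i]), "\n")
  invisible(x)
}

# express 3D points (rows) in frame coordinates (right, anterior, up)
to_frame <- function(P, frame) {
  P <- matrix(as.numeric(P), ncol = 3)
  sweep(P, 2, frame$origin) %*% frame$axes
}

# map frame coordinates back to world
from_frame <- function(P, frame) {
  P <- matrix(as.numeric(P), ncol = 3)
  sweep(P %*% t(frame$axes), 2, -frame$origin)
}
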