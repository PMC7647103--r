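# Fibular osteotomy planning for standardized anterior mandibular
# reconstruction.
#
# The anterior mandible is reconstructed from straight fibular segments
# joined by closing-wedge osteotomies: a symphyseal segment flanked by two
# body segments, with the bone wedge removed at each junction equal to
# 180 deg minus the planned interior angle. Perfusion constrains every
# segment to a minimum length (15 mm by default): small fragments compromise
# the periosteal blood supply. The default targets are the standardized
# ("universal") recommendation: symphysis angle 120 deg, symphysis length
# 25 mm. Planning is 2D (axial): gonial/ramus reconstruction is excluded
# from standardization because of its large inter-individual variability.

#' Specification of an anterior reconstruction guide
#'
#' @param symphysis_angle Target interior angle at each symphyseal junction,
#'   degrees (default 120; valid range (90, 179)).
#' @param symphysis_length Symphyseal segment length, mm (default 25).
#' @param body_extension Length of each flanking body segment, mm
#'   (default 40; a configuration choice, not a published value).
#' @param min_segment Minimum admissible segment length, mm (default 15,
#'   the perfusion limit).
#' @return Object of class `guide_spec`.
#' @export
guide_spec <- function(symphysis_angle = 120, symphysis_length = 25,
                       body_extension = 40, min_segment = 15) {
  if (symphysis_angle <= 90 || symphysis_angle >= 179)
    stop("symphysis_angle must lie in (90, 179) degrees ",
         "(>= 179 means no osteotomy is needed)")
  if (symphysis_length <= 0 || body_extension <= 0 || min_segment <= 0)
    stop("lengths must be positive")
  structure(list(symphysis_angle = symphysis_angle,
                 symphysis_length = symphysis_length,
                 body_extension = body_extension,
                 min_segment = min_segment),
            class = "guide_spec")
}

#' Plan the anterior osteotomy sequence
#'
#' Symmetric three-segment plan: one symphyseal segment of the target length
#' flanked by two body segments, with a closing wedge of
#' 180 deg - symphysis_angle removed at each junction.
#'
#' @param spec A `guide_spec`.
#' @return Object of class `guide_plan`: list with `segments` (mm, in
#'   mandibular order left body / symphysis / right body), `interior_angles`
#'   (deg, at the two junctions), `wedge_angles` (deg), `total_length` (mm)
#'   and the `spec`.
#' @export
plan_anterior_guide <- function(spec = guide_spec()) {
  stopifnot(inherits(spec, "guide_spec"))
  segments <- c(body_L = spec$body_extension,
                symphysis = spec$symphysis_length,
                body_R = spec$body_extension)
  short <- segments < spec$min_segment
  if (any(short))
    stop("segment(s) below the ", spec$min_segment, " mm perfusion minimum: ",
         paste(sprintf("%s (%.1f mm)", names(segments)[short], segments[short]),
               collapse = ", "))
  interior <- c(junction_L = spec$symphysis_angle, junction_R = spec$symphysis_angle)
  structure(list(segments = segments,
                 interior_angles = interior,
                 wedge_angles = 180 - interior,
                 total_length = sum(segments),
                 spec = spec),
            class = "guide_plan")
}

#' @export
print.guide_plan <- function(x, ...) {
  cat("<guide_plan>\n  segments (mm):",
      paste(sprintf("%s=%.1f", names(x$segments), x$segments), collapse = ", "), "\n")
  cat(sprintf("  wedges: %.1f / %.1f deg (interior %.1f deg); total %.1f mm\n",
              x$wedge_angles[1], x$wedge_angles[2], x$interior_angles[1],
              x$total_length))
  invisible(x)
}

#' Validate an osteotomy plan against its specification
#'
#' Checks every segment against the perfusion minimum and each wedge against
#' the interior-angle duality (wedge = 180 deg - interior angle). Violations
#' are reported, not raised.
#'
#' @param plan A `guide_plan`.
#' @param spec A `guide_spec` (defaults to the plan's own).
#' @param tol Angle consistency tolerance, degrees.
#' @return List with `pass` (logical) and `reasons` (character).
#' @export
validate_plan <- function(plan, spec = plan$spec, tol = 1e-6) {
  stopifnot(inherits(plan, "guide_plan"))
  reasons <- character(0)
  short <- plan$segments < spec$min_segment
  if (any(short))
    reasons <- c(reasons, sprintf(
      "segment %s (%.1f mm) is below the %.0f mm perfusion minimum (vascular compromise)",
      names(plan$segments)[short], plan$segments[short], spec$min_segment))
  bad <- abs(plan$wedge_angles - (180 - plan$interior_angles)) > tol
  if (any(bad))
    reasons <- c(reasons, sprintf(
      "wedge at %s (%.2f deg) inconsistent with interior angle %.2f deg (expected %.2f deg)",
      names(plan$interior_angles)[bad], plan$wedge_angles[bad],
      plan$interior_angles[bad], 180 - plan$interior_angles[bad]))
  if (sum(plan$segments) != plan$total_length)
    reasons <- c(reasons, "total length does not equal the sum of segments")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Guide specification from cohort-mean geometry
#'
#' Builds a `guide_spec` from a cohort summary (or the published reference
#' table): target angle = group mean basilar symphysis angle (bilateral
#' average), symphysis length = group mean basilar symphysis length.
#'
#' @param summary Tibble with `measurement`, `side`, `group`, `mean` rows.
#' @param group Group label to use (e.g. `"female"`).
#' @param ... Passed to [guide_spec()] (e.g. `min_segment`).
#' @return A `guide_spec`.
#' @export
guide_spec_from_summary <- function(summary, group, ...) {
  s <- summary[summary$group == group, ]
  ang <- mean(s$mean[s$measurement == "basilar_angle"])
  len <- s$mean[s$measurement == "basilar_symphysis_length" & is.na(s$side)]
  guide_spec(symphysis_angle = ang, symphysis_length = 10 * len, ...)
}
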