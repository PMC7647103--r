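# The landmark protocol: named, sided surface points on one mandible.
#
# Nine named points capture the geometry: upper and posterior condyle, distal
# molar and canine (each the midpoint of a vestibular/lingual primed pair),
# the basilar projection of the mental foramen (all bilateral), plus the
# median inter-incisor point (CEJ of the central incisors) and the mental
# protuberance ("chin", the lowest median symphysis point).

lm_bilateral <- c("upper_condyle", "posterior_condyle", "molar_distal",
                  "canine", "mental_foramen_basilar")
lm_median <- c("inter_incisor", "mental_protuberance")
lm_primed <- c("molar_distal_vestibular", "molar_distal_lingual",
               "canine_vestibular", "canine_lingual")

#' Landmark name vocabulary
#'
#' @return Character vector of all accepted landmark names (bilateral, median
#'   and primed sub-landmarks).
#' @export
landmark_vocabulary <- function() c(lm_bilateral, lm_median, lm_primed)

#' Read a landmark file
#'
#' Delimited text, one landmark per row, with a header and columns
#' `subject`, `sex`, `age`, `name`, `side`, `x`, `y`, `z` (mm). `side` is one
#' of `L`, `R`, `M` (median). Primed sub-landmarks (the vestibular/lingual
#' pairs defining the molar and canine midpoints) are accepted and retained;
#' the midpoints themselves may be supplied or derived downstream.
#'
#' @param path Path to the CSV file.
#' @return Object of class `landmark_file` with fields `subject_id`, `sex`,
#'   `age` and a tibble `landmarks`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "sex", "age", "name", "side", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("landmark file lacks column(s): ", paste(miss, collapse = ", "))
  landmark_file(subject_id = as.character(df$subject[1]),
                sex = as.character(df$sex[1]),
                age = df$age[1],
                landmarks = tibble::tibble(name = as.character(df$name),
                                           side = as.character(df$side),
                                           x = as.numeric(df$x),
                                           y = as.numeric(df$y),
                                           z = as.numeric(df$z)))
}

#' Construct a validated landmark file object
#'
#' @param subject_id Subject identifier.
#' @param sex One of `"female"`, `"male"`, `"unknown"`.
#' @param age Age in years (>= 18) or `NA` for unknown.
#' @param landmarks Tibble with columns `name`, `side`, `x`, `y`, `z`.
#' @return Object of class `landmark_file`.
#' @export
landmark_file <- function(subject_id, sex = "unknown", age = NA, landmarks) {
  sex <- match.arg(sex, c("female", "male", "unknown"))
  if (!is.na(age) && (!is.numeric(age) || age < 18))
    stop("age must be >= 18 years (adult, fully developed mandible) or NA")
  lm <- tibble::as_tibble(landmarks)
  unknown <- setdiff(unique(lm$name), landmark_vocabulary())
  if (length(unknown))
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "),
         "\n  vocabulary: ", paste(landmark_vocabulary(), collapse = ", "))
  bad_side <- setdiff(unique(lm$side), c("L", "R", "M"))
  if (length(bad_side)) stop("side labels must be L, R or M; got: ",
                             paste(bad_side, collapse = ", "))
  key <- paste(lm$name, lm$side)
  if (anyDuplicated(key))
    stop("duplicate (name, side) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!all(is.finite(c(lm$x, lm$y, lm$z)))) stop("landmark coordinates must be finite")
  out <- structure(list(subject_id = subject_id, sex = sex, age = age, landmarks = lm),
                   class = "landmark_file")
  # completeness: every protocol point must be present or derivable
  check_landmark_completeness(out)
  out
}

lf_get <- function(lf, name, side) {
  i <- which(lf$landmarks$name == name & lf$landmarks$side == side)
  if (!length(i)) return(NULL)
  as.numeric(lf$landmarks[i[1], c("x", "y", "z")])
}

check_landmark_completeness <- function(lf) {
  missing <- character(0)
  for (nm in lm_median)
    if (is.null(lf_get(lf, nm, "M"))) missing <- c(missing, paste0(nm, " (M)"))
  for (nm in lm_bilateral) for (sd in c("L", "R")) {
    ok <- !is.null(lf_get(lf, nm, sd))
    if (!ok && nm %in% c("molar_distal", "canine")) {
      ok <- !is.null(lf_get(lf, paste0(nm, "_vestibular"), sd)) &&
        !is.null(lf_get(lf, paste0(nm, "_lingual"), sd))
    }
    if (!ok) missing <- c(missing, paste0(nm, " (", sd, ")"))
  }
  if (length(missing))
    stop("incomplete landmark protocol; missing: ", paste(missing, collapse = ", "))
  invisible(lf)
}

#' Resolve a landmark file into the full measurement landmark set
#'
#' Midpoint landmarks (distal molar, canine) that were not placed directly
#' are computed as the average of their vestibular/lingual primed pair; if
#' both a midpoint and its pair are present they must agree to 1e-9 mm.
#'
#' @param lf A `landmark_file`.
#' @return Object of class `landmark_set`: a tibble (`name`, `side`, `x`,
#'   `y`, `z`) holding one point per protocol landmark, with primed points
#'   retained, plus subject metadata attributes.
#' @export
as_landmark_set <- function(lf) {
  if (inherits(lf, "landmark_set")) return(lf)
  stopifnot(inherits(lf, "landmark_file"))
  lm <- lf$landmarks
  for (nm in c("molar_distal", "canine")) for (sd in c("L", "R")) {
    v <- lf_get(lf, paste0(nm, "_vestibular"), sd)
    l <- lf_get(lf, paste0(nm, "_lingual"), sd)
    mid <- lf_get(lf, nm, sd)
    if (!is.null(v) && !is.null(l)) {
      derived <- (v + l) / 2
      if (is.null(mid)) {
        lm <- dplyr::bind_rows(lm, tibble::tibble(name = nm, side = sd,
                                                  x = derived[1], y = derived[2], z = derived[3]))
      } else if (max(abs(mid - derived)) > 1e-9) {
        stop(nm, " (", sd, ") midpoint does not equal the mean of its primed pair")
      }
    }
  }
  structure(tibble::as_tibble(lm),
            class = c("landmark_set", class(tibble::tibble())),
            subject_id = lf$subject_id, sex = lf$sex, age = lf$age)
}

# fetch one named point from a landmark set as a length-3 numeric
lmk <- function(ls, name, side = "M") {
  i <- which(ls$name == name & ls$side == side)
  if (!length(i)) stop("landmark not present: ", name, " (", side, ")")
  as.numeric(ls[i[1], c("x", "y", "z")])
}

#' Write a landmark set or file to CSV
#'
#' @param lf A `landmark_file` or `landmark_set`.
#' @param path Output path.
#' @export
write_landmarks <- function(lf, path) {
  if (inherits(lf, "landmark_set")) {
    df <- data.frame(subject = attr(lf, "subject_id"), sex = attr(lf, "sex"),
                     age = attr(lf, "age"), as.data.frame(lf))
  } else {
    df <- data.frame(subject = lf$subject_id, sex = lf$sex, age = lf$age,
                     as.data.frame(lf$landmarks))
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# transform helpers mirroring the mesh ones
transform_landmarks <- function(ls, R = diag(3), t = c(0, 0, 0), scale = 1) {
  xyz <- scale * as.matrix(ls[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, -as.numeric(t))
  out <- ls
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}

mirror_landmarks <- function(ls) {
  out <- ls
  out$x <- -out$x
  out$side <- chartr("LR", "RL", out$side)
  out
}
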