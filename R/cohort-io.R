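# Cohort table serialization: one row per subject, one column per
# measurement (16 value columns + subject/sex/age), full double precision.

#' Write a cohort measurement table to CSV
#'
#' @param records List of `measurement_record`s (or an already-bound cohort
#'   tibble).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  if (inherits(records, "data.frame")) {
    tab <- records
  } else {
    if (!length(records)) stop("empty record list")
    bad <- !vapply(records, function(r) all(measurement_names() %in% names(r)), logical(1))
    if (any(bad)) stop("record(s) with mismatched measurement sets at position(s): ",
                       paste(which(bad), collapse = ", "))
    tab <- dplyr::bind_rows(records)
  }
  validate_cohort_table(tab)
  tab <- tab[, c("subject_id", "sex", "age", measurement_names())]
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort measurement table
#'
#' @param path CSV written by [write_cohort_table()].
#' @return Cohort tibble.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tibble::as_tibble(df)
  validate_cohort_table(tab)
  tab$subject_id <- as.character(tab$subject_id)
  tab
}

#' Simulate a cohort to disk (STL + landmark CSV per subject)
#'
#' Writes, per subject, `<id>.stl` (binary) and `<id>_landmarks.csv`, plus a
#' `manifest.csv` of ground-truth measurement values for test harnesses.
#'
#' @param dir Output directory (created if needed).
#' @param n Subjects per sex.
#' @param sex `"female"`, `"male"` or `"both"`.
#' @param seed RNG seed.
#' @return Tibble manifest of ground-truth records, invisibly.
#' @export
simulate_cohort_files <- function(dir, n = 30, sex = "both", seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sexes <- if (sex == "both") c("female", "male") else match.arg(sex, c("female", "male"))
  rows <- list()
  for (i in seq_along(sexes)) {
    params <- sample_cohort_params(sexes[i], n, seed = seed + i - 1)
    for (id in names(params)) {
      mm <- make_mandible(params[[id]], subject_id = id, sex = sexes[i])
      write_mesh(mm$mesh, file.path(dir, paste0(id, ".stl")))
      write_landmarks(mm$truth$landmarks, file.path(dir, paste0(id, "_landmarks.csv")))
      rows[[length(rows) + 1]] <- mm$truth$record
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write_cohort_table(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Measure every subject in a cohort directory
#'
#' Pairs `<id>.stl` with `<id>_landmarks.csv` and runs [measure_subject()].
#'
#' @param dir Directory produced by [simulate_cohort_files()] (or with the
#'   same layout for real data).
#' @return Cohort tibble of measured records.
#' @export
measure_cohort_dir <- function(dir) {
  stls <- sort(list.files(dir, pattern = "\\.stl$", full.names = TRUE))
  if (!length(stls)) stop("no STL files in ", dir)
  recs <- lapply(stls, function(f) {
    id <- sub("\\.stl$", "", basename(f))
    lmf <- file.path(dir, paste0(id, "_landmarks.csv"))
    if (!file.exists(lmf)) stop("no landmark file for subject ", id)
    measure_subject(read_mesh(f), read_landmarks(lmf))
  })
  dplyr::bind_rows(recs)
}
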