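# Cohort statistics: descriptive summaries with CV, bilateral averaging,
# side asymmetry, sexual dimorphism with a normality gate, and ICC
# reliability with the Rosner classification.

#' Descriptive summary of one group of values
#'
#' Mean, sample SD (n-1 denominator) and coefficient of variation
#' (CV = 100 * SD / mean, defined for positive means).
#'
#' @param values Numeric vector (n >= 2, finite).
#' @param label Group label carried through.
#' @param measurement Optional measurement name.
#' @return One-row tibble: `measurement`, `group`, `n`, `mean`, `sd`, `cv`.
#' @export
summarize_group <- function(values, label = "group", measurement = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values to summarise a group")
  if (!all(is.finite(values))) stop("values must be finite")
  m <- mean(values)
  s <- stats::sd(values)
  if (m <= 0) stop("CV undefined: group mean is not positive")
  tibble::tibble(measurement = measurement, group = label,
                 n = length(values), mean = m, sd = s, cv = 100 * s / m)
}

#' Check that rows form a valid cohort table
#'
#' @param table Tibble with `subject_id`, `sex`, `age` and the sixteen
#'   measurement columns.
#' @return The table, invisibly, or an error.
#' @export
validate_cohort_table <- function(table) {
  miss <- setdiff(c("subject_id", "sex", measurement_names()), names(table))
  if (length(miss)) stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Bilateral (side-averaged) values per subject
#'
#' Bilateral measurements are replaced by the arithmetic mean of their left
#' and right values; single measurements pass through. All sex comparisons
#' operate on these per-subject side averages, since side asymmetry would
#' otherwise interfere with the dimorphism analysis.
#'
#' @param table A cohort table (or a single `measurement_record`).
#' @return Tibble with `subject_id`, `sex`, `age` and one column per
#'   measurement (ten columns).
#' @export
bilateral_average <- function(table) {
  validate_cohort_table(table)
  out <- table[, c("subject_id", "sex", "age")]
  for (m in bilateral_measurements()) {
    l <- table[[paste0(m, "_L")]]; r <- table[[paste0(m, "_R")]]
    if (any(!is.finite(l)) || any(!is.finite(r)))
      stop("missing side values for ", m)
    out[[m]] <- (l + r) / 2
  }
  for (m in single_measurements()) out[[m]] <- table[[m]]
  out
}

#' Summary table in the layout of the published cohort table
#'
#' Per group and measurement/side: n, mean, SD and CV.
#'
#' @param table A cohort table.
#' @param by Grouping column, default `"sex"`.
#' @return Tibble of group summaries.
#' @export
cohort_summary <- function(table, by = "sex") {
  validate_cohort_table(table)
  rows <- list()
  for (g in unique(table[[by]])) {
    sub <- table[table[[by]] == g, ]
    for (m in bilateral_measurements()) for (sd_ in c("L", "R")) {
      s <- summarize_group(sub[[paste0(m, "_", sd_)]], g, m)
      s$side <- sd_
      rows[[length(rows) + 1]] <- s
    }
    for (m in single_measurements()) {
      s <- summarize_group(sub[[m]], g, m)
      s$side <- NA_character_
      rows[[length(rows) + 1]] <- s
    }
  }
  dplyr::bind_rows(rows)[, c("measurement", "side", "group", "n", "mean", "sd", "cv")]
}

#' Left/right asymmetry of group means
#'
#' Per group and bilateral measurement, the absolute difference between the
#' left and right group means, with the largest difference flagged (the
#' symmetry tolerance statement of the analysis). Accepts either a cohort
#' table or a precomputed summary (a tibble with `measurement`, `side`,
#' `group`, `mean`), so the published group means can be analysed directly.
#'
#' @param x Cohort table or summary tibble.
#' @param angles_only Restrict the argmax flag to angle measurements.
#' @return Tibble `group`, `measurement`, `mean_L`, `mean_R`, `abs_diff`,
#'   `is_max` (largest within group among the flagged set).
#' @export
asymmetry_summary <- function(x, angles_only = FALSE) {
  if (!all(c("measurement", "side", "mean") %in% names(x))) {
    validate_cohort_table(x)
    x <- cohort_summary(x)
  }
  x <- x[!is.na(x$side), ]
  keys <- unique(x[, c("group", "measurement")])
  wide <- dplyr::bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    sub <- x[x$group == keys$group[i] & x$measurement == keys$measurement[i], ]
    tibble::tibble(group = keys$group[i], measurement = keys$measurement[i],
                   mean_L = sub$mean[sub$side == "L"][1],
                   mean_R = sub$mean[sub$side == "R"][1])
  }))
  wide$abs_diff <- abs(wide$mean_L - wide$mean_R)
  eligible <- if (angles_only) wide$measurement %in% angle_measurements() else TRUE
  wide$is_max <- FALSE
  for (g in unique(wide$group)) {
    i <- which(wide$group == g & eligible)
    if (length(i)) wide$is_max[i[which.max(wide$abs_diff[i])]] <- TRUE
  }
  wide
}

#' Sexual dimorphism tests with a normality gate
#'
#' Per measurement (on the per-subject bilateral averages): both sexes are
#' tested for normality (Shapiro-Wilk at `alpha`); if both pass, a two-group
#' one-way ANOVA compares the sexes, otherwise the unpaired rank analogue
#' (Wilcoxon-Mann-Whitney). Significance at `alpha`. No multiplicity
#' correction is applied (matching the source analysis); the number of tests
#' is returned for transparency.
#'
#' @param table A cohort table containing both sexes (n >= 3 each).
#' @param alpha Significance level (default 0.05).
#' @return Tibble `measurement`, `mean_female`, `mean_male`, `test`
#'   (`"anova"`/`"rank"`), `p_value`, `significant`; attribute `n_tests`.
#' @export
compare_sexes <- function(table, alpha = 0.05) {
  avg <- bilateral_average(table)
  f <- avg[avg$sex == "female", ]; m <- avg[avg$sex == "male", ]
  if (nrow(f) < 3 || nrow(m) < 3)
    stop("need at least 3 subjects of each sex (have ", nrow(f), " female, ",
         nrow(m), " male)")
  meas <- c(bilateral_measurements(), single_measurements())
  rows <- lapply(meas, function(mm) {
    xf <- f[[mm]]; xm <- m[[mm]]
    normal <- stats::shapiro.test(xf)$p.value > alpha &&
      stats::shapiro.test(xm)$p.value > alpha
    if (normal) {
      p <- stats::anova(stats::lm(v ~ g, data = data.frame(
        v = c(xf, xm), g = rep(c("f", "m"), c(length(xf), length(xm))))))$`Pr(>F)`[1]
      test <- "anova"
    } else {
      p <- stats::wilcox.test(xf, xm, exact = FALSE)$p.value
      test <- "rank"
    }
    tibble::tibble(measurement = mm, mean_female = mean(xf), mean_male = mean(xm),
                   test = test, p_value = p, significant = p < alpha)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_tests") <- nrow(out)
  out
}

#' Within-subject side comparison (repeated-measures rank test)
#'
#' The Friedman test on the subjects x {left, right} block design, exposed
#' for the bilateral symmetry question (the paired repeated-measures
#' contrast; independent sexes cannot be compared this way).
#'
#' @param table A cohort table.
#' @param measurement One of the bilateral measurement names.
#' @return `htest` result of `stats::friedman.test`.
#' @export
side_symmetry_test <- function(table, measurement) {
  validate_cohort_table(table)
  stopifnot(measurement %in% bilateral_measurements())
  v <- c(table[[paste0(measurement, "_L")]], table[[paste0(measurement, "_R")]])
  stats::friedman.test(y = v,
                       groups = rep(c("L", "R"), each = nrow(table)),
                       blocks = rep(table$subject_id, 2))
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-measurement ICC(2,1) from the standard mean-squares decomposition
#' of a complete subjects x repeats matrix, with the Rosner reliability
#' classes: poor (< 0.4), fair to good (0.4 to < 0.75), excellent (>= 0.75).
#'
#' @param repeats Numeric matrix, rows = subjects (n >= 2), columns =
#'   repeated measurements (k >= 2), complete.
#' @param measurement Optional measurement name.
#' @return Tibble `measurement`, `icc`, `reliability`.
#' @export
icc_absolute_agreement <- function(repeats, measurement = NA_character_) {
  m <- as.matrix(repeats)
  if (any(!is.finite(m))) stop("the repeats matrix must be complete and finite")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 repeats")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  tibble::tibble(measurement = measurement, icc = icc,
                 reliability = classify_reliability(icc))
}

#' Rosner reliability class of an ICC value
#'
#' @param icc Numeric ICC estimate(s).
#' @return `"poor"` (< 0.4), `"fair to good"` (0.4 to < 0.75) or
#'   `"excellent"` (>= 0.75).
#' @export
classify_reliability <- function(icc) {
  ifelse(icc >= 0.75, "excellent", ifelse(icc >= 0.4, "fair to good", "poor"))
}

#' Reliability study on repeated landmark placements
#'
#' Emulates the repeatability protocol: for each subject mesh, landmarks are
#' re-placed `repeats` times with placement noise `sigma` and the subject is
#' re-measured; per measurement the subjects x repeats matrix yields an
#' ICC(2,1).
#'
#' @param subjects List of `list(mesh=, truth=)` pairs from
#'   [make_mandible()].
#' @param sigma Landmark placement noise SD, mm.
#' @param repeats Number of repeated placements per subject.
#' @param seed RNG seed.
#' @param measurements Measurement columns to analyse (default all 16).
#' @return Tibble of ICC results (one row per measurement).
#' @export
reliability_study <- function(subjects, sigma, repeats = 5, seed = 1,
                              measurements = measurement_names()) {
  set.seed(seed)
  recs <- list()
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    for (r in seq_len(repeats)) {
      # at large sigma an occasional placement is degenerate (tangent bands
      # collapse); the observer re-places, so re-draw up to a few times
      rec <- NULL
      for (attempt in 1:5) {
        lmj <- jitter_landmarks(sub$truth$landmarks, sigma, mesh = sub$mesh)
        rec <- tryCatch(measure_subject(sub$mesh, lmj), error = function(e) NULL)
        if (!is.null(rec)) break
      }
      if (is.null(rec)) stop("measurement failed repeatedly at sigma = ", sigma,
                             " for subject ", i)
      rec$subject_id <- paste0("S", i)
      rec$repeat_id <- r
      recs[[length(recs) + 1]] <- rec
    }
  }
  tab <- dplyr::bind_rows(recs)
  dplyr::bind_rows(lapply(measurements, function(mm) {
    m <- matrix(tab[[mm]], nrow = length(subjects), byrow = TRUE)
    icc_absolute_agreement(m, measurement = mm)
  }))
}
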