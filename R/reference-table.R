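# Published descriptive statistics of the 30 + 30 dentate adult cohort.
#
# These printed group means and SDs are the inputs of the worked arithmetic
# checks (CV cells, bilateral means, side asymmetry) and the distributional
# parameters of the cohort simulator. Angles in degrees, lengths in cm; CVs
# as printed (percent).

#' Reference cohort table (printed group statistics)
#'
#' @return Tibble with columns `measurement`, `side` (`"L"`, `"R"` or `NA`
#'   for single measurements), `group` (`"female"`/`"male"`), `mean`, `sd`,
#'   `cv_printed` (percent) and `unit`.
#' @export
mandible_reference_table <- function() {
  row <- function(measurement, side, group, mean, sd, cv, unit)
    tibble::tibble(measurement = measurement, side = side, group = group,
                   mean = mean, sd = sd, cv_printed = cv, unit = unit)
  dplyr::bind_rows(
    row("gonial_angle", "R", "female", 128.5, 8.9, 6.9, "deg"),
    row("gonial_angle", "L", "female", 129.3, 8.9, 6.9, "deg"),
    row("canine_angle", "R", "female", 114.6, 3.8, 3.3, "deg"),
    row("canine_angle", "L", "female", 114.5, 3.6, 3.2, "deg"),
    row("basilar_angle", "R", "female", 122.5, 5.1, 4.2, "deg"),
    row("basilar_angle", "L", "female", 118.2, 6.5, 5.6, "deg"),
    row("vertical_posterior_dimension", "R", "female", 6.0, 0.4, 6.2, "cm"),
    row("vertical_posterior_dimension", "L", "female", 6.0, 0.4, 7.0, "cm"),
    row("dentate_length", "R", "female", 3.8, 0.2, 4.2, "cm"),
    row("dentate_length", "L", "female", 3.8, 0.2, 5.1, "cm"),
    row("basilar_body_length", "R", "female", 7.2, 0.6, 7.9, "cm"),
    row("basilar_body_length", "L", "female", 7.5, 0.5, 6.6, "cm"),
    row("basilar_symphysis_length", NA, "female", 2.5, 0.3, 12.9, "cm"),
    row("alveolar_symphysis_length", NA, "female", 2.8, 0.2, 6.5, "cm"),
    row("symphyseal_height", NA, "female", 2.7, 0.3, 12.0, "cm"),
    row("bigonial_length", NA, "female", 8.8, 0.6, 6.5, "cm"),
    row("gonial_angle", "R", "male", 125.9, 5.7, 4.5, "deg"),
    row("gonial_angle", "L", "male", 125.4, 6.1, 4.9, "deg"),
    row("canine_angle", "R", "male", 114.2, 4.8, 4.2, "deg"),
    row("canine_angle", "L", "male", 112.9, 4.3, 3.8, "deg"),
    row("basilar_angle", "R", "male", 119.2, 6.9, 5.8, "deg"),
    row("basilar_angle", "L", "male", 117.1, 5.6, 4.8, "deg"),
    row("vertical_posterior_dimension", "R", "male", 6.5, 0.6, 8.7, "cm"),
    row("vertical_posterior_dimension", "L", "male", 6.4, 0.5, 8.4, "cm"),
    row("dentate_length", "R", "male", 4.0, 0.3, 6.3, "cm"),
    row("dentate_length", "L", "male", 4.0, 0.3, 7.6, "cm"),
    row("basilar_body_length", "R", "male", 8.0, 0.6, 7.0, "cm"),
    row("basilar_body_length", "L", "male", 8.2, 0.6, 7.2, "cm"),
    row("basilar_symphysis_length", NA, "male", 3.0, 0.5, 15.6, "cm"),
    row("alveolar_symphysis_length", NA, "male", 2.9, 0.2, 7.4, "cm"),
    row("symphyseal_height", NA, "male", 3.1, 0.3, 8.3, "cm"),
    row("bigonial_length", NA, "male", 9.6, 0.6, 6.6, "cm"))
}

# round half away from zero at `digits` decimals (the printing convention of
# the reference table; base round() rounds half to even)
round_half_out <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
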