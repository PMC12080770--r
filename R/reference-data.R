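# Published reference tables shipped with the package.

#' Published participant demographics
#'
#' The demographic table of the original six-subject study cohort (age in
#' years, height in cm, weight in kg, and the body mass index as printed),
#' read from the package's plain-text copy. Useful for checking the table's
#' internal arithmetic: BMI = weight / (height in m)^2, column means, and the
#' printed "mean variation" row, which matches the sample (n-1) standard
#' deviation.
#'
#' @return data.frame with columns `number`, `age`, `height_cm`, `weight_kg`,
#'   `bmi_printed`.
#' @examples
#' demo <- participantDemographics()
#' mean(demo$age)
#' @export
participantDemographics <- function() {
  path <- system.file("extdata", "participant_demographics.csv",
                      package = "hrvFatigue", mustWork = TRUE)
  utils::read.csv(path)
}
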