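#' Reference cohort: study subjects
#'
#' The published male cohort used throughout as the reference design: 13
#' captive male African elephants with approximate age, shoulder height,
#' maturity group (group 1: shoulder height > 3 m and age > 25 y;
#' group 2: below both) and the number of analyzable calls each
#' contributed. Three males fall below the 10-call inclusion threshold.
#'
#' @return Data frame with columns `individual`, `age_y`, `height_m`,
#'   `maturity_group`, `n_calls`.
#' @export
table1_subjects <- function() {
  data.frame(
    individual = c("Mana", "Mike", "Sapi", "Sharu", "Chichuru", "Chova",
                   "Medwa", "Shamwari", "Tembo", "Ziziphus", "Duma",
                   "Mukwa", "Thaba"),
    age_y    = c(29, 29, 30, 30, 18, 21, 19, 19, 34, 18, 28, 29, 29),
    height_m = c(3.25, 3.20, 3.25, 3.20, 2.40, 2.50, 2.60, 2.70, 3.30,
                 2.50, 3.25, 3.25, 3.25),
    maturity_group = c("group1", "group1", "group1", "group1", "group2",
                       "group2", "group2", "group2", "group1", "group2",
                       "group1", "group1", "group1"),
    n_calls = c(13L, 18L, 10L, 2L, 20L, 20L, 15L, 14L, 20L, 14L, 18L,
                5L, 5L),
    stringsAsFactors = FALSE)
}

#' Reference feature distributions by maturity group
#'
#' Published group means and SDs of the five acoustic parameters that
#' discriminate the two maturity groups (all in Hz), together with the
#' published two-group ANOVA F statistics (df 1, 160).
#'
#' @return Data frame with columns `feature`, `F_published`, `mean1`,
#'   `sd1`, `mean2`, `sd2`.
#' @export
table3_reference <- function() {
  data.frame(
    feature = c("formant1", "formant2", "max_freq", "min_freq",
                "finish_freq"),
    F_published = c(343.144, 520.382, 133.041, 130.844, 108.385),
    mean1 = c(21.53, 77.14, 13.81, 9.91, 10.41),
    sd1   = c(2.0, 7.6, 1.6, 1.2, 1.5),
    mean2 = c(29.44, 104.53, 16.96, 12.50, 13.20),
    sd2   = c(3.3, 7.7, 1.9, 1.6, 1.9),
    stringsAsFactors = FALSE)
}
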