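#' Pilot cohort of paired sinus volumes
#'
#' Interval volume estimates (midpoint and half-width error) for six
#' maxillary sinus samples from four patients, measured before zygomatic
#' or pterygoid implant surgery and again 14--16 months after, shipped
#' as `inst/extdata/pilot_cohort.csv`. Used as the worked example for
#' [relative_change()] and [cohort_summary()].
#'
#' @return Path to the CSV (columns `sample_id`, `v_pre`, `v_pre_err`,
#'   `v_post`, `v_post_err`).
#' @examples
#' cohort <- read.csv(pilot_cohort_path())
#' tidy(cohort_summary(cohort))
#' @export
pilot_cohort_path <- function() {
  system.file("extdata", "pilot_cohort.csv", package = "sinusvol", mustWork = TRUE)
}
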