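#' Evaluation-cohort tables
#'
#' Subject-level tables from the ten-subject evaluation cohort (four healthy,
#' six asthmatic young adults) used to validate the segmentation method:
#' demographics and spirometry (`study_spirometry()`), and the per-subject
#' ventilated lung volumes from the semiautomatic and manual segmentations
#' together with their Dice coefficients (`study_vlv()`). PC20 is the
#' methacholine concentration provoking a 20% FEV1 drop; it is `NA` for the
#' healthy subjects, whose PC20 exceeded the 25 mg/mL test ceiling.
#'
#' These tables drive the subject-level summary statistics and the
#' VLV-spirometry correlation analyses; see [agreement_report()],
#' [correlate()] and [summarize_values()].
#'
#' @return a `data.frame`, one row per subject.
#' @export
study_spirometry <- function() {
  read.csv(system.file("extdata", "spirometry.csv", package = "heliovent"),
           stringsAsFactors = FALSE)
}

#' @rdname study_spirometry
#' @export
study_vlv <- function() {
  read.csv(system.file("extdata", "vlv_dice.csv", package = "heliovent"),
           stringsAsFactors = FALSE)
}
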