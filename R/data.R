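#' Reference occlusion-response time constants
#'
#' Per-subject exponential time constants (seconds) of the fetal RR response
#' to umbilical-cord-occlusion onset (`tau_stim_s`) and release (`tau_rec_s`)
#' for the seven analysed sheep of the UCO experiment this package models.
#' These published values are the basis of the synthetic generator's default
#' sampling ranges and of the cohort-summary checks.
#'
#' @return data frame with columns `subject`, `tau_stim_s`, `tau_rec_s`.
#' @export
uco_tau_reference <- function() {
  utils::read.csv(system.file("extdata", "uco_tau_reference.csv",
                              package = "prsafhr"),
                  stringsAsFactors = FALSE)
}
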