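#' Bundled swine ablation study table
#'
#' The packaged transcription of the in-vivo study table this package's
#' worked examples reproduce: eight recorded interstitial-ultrasound brain
#' ablations in seven swine (plus one attempt with no recorded measurements),
#' with acoustic power (W), sonication duration (s), absolute maximal
#' ROI-mean temperature increase (degC), time for the temperature to return
#' to baseline (s), and ablation volumes from stained histology sections and
#' from the MRTI CEM43 dose maps (cm^3). Two ablations are excluded from the
#' volume analysis because suboptimal tissue staining left the damage margin
#' undemarcated; `included` marks the six analysable volume pairs.
#'
#' @return tibble with one row per ablation attempt and columns `swine`,
#'   `lesion_site`, `acuity`, `probe_pattern_deg`, `probe_length_mm`,
#'   `acoustic_power_W`, `duration_s`, `max_temp_rise_C`,
#'   `time_to_baseline_s`, `histology_volume_cm3`, `mrti_volume_cm3`,
#'   `included`, `exclusion_reason`, `note`.
#' @examples
#' t1 <- load_table1_fixture()
#' sum(t1$included)  # 6 analysable volume pairs
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "thermodose",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    swine = readr::col_integer(),
                    lesion_site = readr::col_character(),
                    acuity = readr::col_character(),
                    probe_pattern_deg = readr::col_integer(),
                    probe_length_mm = readr::col_double(),
                    acoustic_power_W = readr::col_double(),
                    duration_s = readr::col_double(),
                    max_temp_rise_C = readr::col_double(),
                    time_to_baseline_s = readr::col_double(),
                    histology_volume_cm3 = readr::col_double(),
                    mrti_volume_cm3 = readr::col_double(),
                    included = readr::col_logical(),
                    exclusion_reason = readr::col_character(),
                    note = readr::col_character()))
}
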