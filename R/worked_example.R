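#' Reference worked-example panel
#'
#' Dimension measurements for the 21 hard-shelled individuals of the
#' reference panel worked example (a 25 x 35 cm uncoated panel): species,
#' projected length and width, and the published attachment area, shell dry
#' weight and carbonate carbon values computed from them at 4-decimal
#' precision. The companion destructively measured total carbonate carbon
#' for the same panel is 0.6037 g (see [worked_example_measured_g]).
#'
#' @return tibble with columns `no`, `species`, `L_mm`, `B_mm`, `area_cm2`,
#'   `dry_weight_g`, `carbon_g`.
#' @export
worked_example <- function() {
  tibble::as_tibble(read.csv(
    system.file("extdata", "worked_example_panel.csv",
                package = "shellcarbon"),
    stringsAsFactors = FALSE))
}

#' Destructively measured carbon of the worked-example panel
#'
#' Total carbonate carbon (g) obtained by scraping, drying and weighing the
#' organisms of the reference panel; the benchmark against which the
#' image-based estimate is judged via [relative_error()].
#'
#' @format a single number, grams.
#' @export
worked_example_measured_g <- 0.6037
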