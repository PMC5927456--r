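#' Published extreme monthly means for the Lake Alchichica population
#'
#' The printed maximum and minimum monthly population means of each
#' life-history trait (and of the oxygenated-layer temperature) reported
#' for the Lake Alchichica diaptomid population — the worked-example
#' inputs for [ppi()] and [plasticity_intensity()].
#'
#' @return Tibble: `variable`, `max_mean`, `min_mean`, `units`.
#' @examples
#' ext <- alchichica_extremes()
#' w <- ext[ext$variable == "wet_weight_ug", ]
#' ppi(c(w$max_mean, w$min_mean))
#' @export
alchichica_extremes <- function() {
  readr::read_csv(system.file("extdata", "alchichica_extremes.csv",
                              package = "plastinorm", mustWork = TRUE),
                  col_types = readr::cols(
                    variable = readr::col_character(),
                    units = readr::col_character(),
                    .default = readr::col_double()),
                  progress = FALSE)
}
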