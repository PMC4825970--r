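#' Packaged transcriptions of the study tables
#'
#' Three small fixtures ship with the package:
#' \describe{
#'   \item{`"table3"`}{the hypothesis table of cladogenetic events, their 95%
#'     divergence-time intervals under the B1/B2/B3 dating analyses, the
#'     candidate geological/biotic windows, and the recorded decisions
#'     (14 rows: 11 cladogenetic events, 13 geological plus 1 biotic
#'     hypothesis).}
#'   \item{`"table1"`}{the fossil calibration priors (7 unique fossils; the
#'     Emesinae prior is exponential with a hard 25 Ma minimum in the
#'     six-calibration configuration and normal in the seven-calibration
#'     one). Decimal commas in the printed source were normalized to points.}
#'   \item{`"areas"`}{the twelve-area alphabet A-L (Mexican Transition Zone
#'     through North America).}
#' }
#'
#' @param name One of `"table1"`, `"table3"`, `"areas"`.
#' @return `"table3"`: a hypothesis tibble (see [read_hypothesis_table()]);
#'   `"table1"`: a calibration list (see [load_calibrations()]); `"areas"`:
#'   a tibble `code`, `description` with the [area_alphabet()] attached as
#'   attribute `alphabet`.
#' @examples
#' load_fixture("table3")
#' @export
load_fixture <- function(name = c("table1", "table3", "areas")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("table1", "table3", "areas")) {
    stop("unknown fixture: ", paste(name, collapse = ", "),
         " (available: table1, table3, areas)", call. = FALSE)
  }
  path <- function(f) system.file("extdata", f, package = "vicartest",
                                  mustWork = TRUE)
  switch(name,
    table3 = read_hypothesis_table(path("table3_hypotheses.tsv")),
    table1 = load_calibrations(path("table1_calibrations.tsv")),
    areas = {
      df <- readr::read_tsv(path("area_alphabet.tsv"),
                            col_types = readr::cols(), progress = FALSE)
      attr(df, "alphabet") <- area_alphabet(df$code)
      df
    })
}
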