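#' Load fossil calibration priors
#'
#' Reads a tab-separated calibration table: `name` (fossil), `clade_taxa`
#' (semicolon-separated ingroup taxa), `kind` (`normal` with mean Ma and sd
#' Myr, or `exponential` with mean Myr and a hard minimum-age offset in Ma),
#' `mean`, `sd_or_offset`, `configurations` (semicolon list of the dating
#' analyses the prior belongs to, e.g. `B2;B3`), and `locality`. Decimal
#' commas (as sometimes printed in source tables) are normalized to points.
#'
#' A fossil may appear on two rows with different distributions when its
#' parameterization depends on the analysis configuration; the prior count
#' reported is over unique fossil names.
#'
#' @param path File path (or data frame in the same layout).
#' @return A list with `priors` (tibble, one row per prior parameterization)
#'   and `counts` (tibble `configuration`, `n` priors), plus `n_fossils`.
#' @export
load_calibrations <- function(path) {
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  if (nrow(df) == 0) stop("empty calibration file.", call. = FALSE)
  need <- c("name", "clade_taxa", "kind", "mean", "sd_or_offset", "configurations")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("calibration table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(df$kind), c("normal", "exponential"))
  if (length(bad_kind) > 0) {
    stop("unknown prior distribution kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::all_of(c("mean", "sd_or_offset")),
    ~ as.numeric(stringr::str_replace(as.character(.x), ",", "."))))
  bad_norm <- df$kind == "normal" & df$sd_or_offset <= 0
  bad_exp <- df$kind == "exponential" & (df$mean <= 0 | df$sd_or_offset < 0)
  if (any(bad_norm | bad_exp)) {
    stop("invalid prior parameters in rows: ",
         paste(which(bad_norm | bad_exp), collapse = ", "), call. = FALSE)
  }
  cfg <- stringr::str_split(df$configurations, ";")
  all_cfg <- sort(unique(unlist(cfg)))
  counts <- tibble::tibble(
    configuration = all_cfg,
    n = vapply(all_cfg, function(cc) sum(vapply(cfg, function(v) cc %in% v,
                                                logical(1))), integer(1),
               USE.NAMES = FALSE))
  list(priors = df, counts = counts, n_fossils = dplyr::n_distinct(df$name))
}
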