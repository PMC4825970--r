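#' Calibration-sensitivity regression of interval width on node age
#'
#' For each dating analysis, ordinary least squares of the width `w` of the
#' 95% node-age interval on the mean node age `m`. The slope measures how
#' fast dating uncertainty grows with node age; comparing slopes across
#' analyses with increasing numbers of fossil calibrations shows whether
#' added calibrations tighten the estimates. Analyses are only comparable on
#' a common node set, so nodes missing from any analysis are dropped with a
#' warning.
#'
#' @param summaries A tibble with columns `label` (analysis), `clade`,
#'   `mean_age` (Ma) and `width` (Myr), e.g. from [hpd_by_node()].
#' @return An object of class `precision_fit`: list of per-label [stats::lm]
#'   fits plus the shared-node data. Use [tidy()] / [glance()] to extract
#'   coefficients and fit statistics, and [ggplot2::autoplot()] to draw the
#'   width-versus-age panel.
#' @export
precision_regression <- function(summaries) {
  need <- c("label", "clade", "mean_age", "width")
  stopifnot(all(need %in% names(summaries)))
  labels <- unique(summaries$label)
  shared <- summaries |>
    dplyr::distinct(.data$label, .data$clade) |>
    dplyr::count(.data$clade) |>
    dplyr::filter(.data$n == length(labels)) |>
    dplyr::pull(.data$clade)
  dropped <- setdiff(unique(summaries$clade), shared)
  if (length(dropped) > 0) {
    warning(length(dropped), " node(s) missing from some analyses dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  }
  data <- dplyr::filter(summaries, .data$clade %in% shared)
  if (length(shared) < 3) {
    stop("fewer than 3 nodes shared across analyses; regression needs >= 3.",
         call. = FALSE)
  }
  fits <- lapply(split(data, data$label), function(df) {
    stats::lm(width ~ mean_age, data = df)
  })
  structure(list(fits = fits, data = data, dropped = dropped),
            class = "precision_fit")
}

#' @export
print.precision_fit <- function(x, ...) {
  cat("<precision_fit> interval width ~ mean node age, per analysis\n")
  print(tidy.precision_fit(x))
  invisible(x)
}

#' Tidy a precision regression
#'
#' @param x A `precision_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per label and coefficient (`term` is
#'   `"(Intercept)"` or `"mean_age"`) with `estimate`, `std.error`,
#'   `statistic`, `p.value`. `glance()`: one row per label with `r.squared`,
#'   `sigma` (residual standard error), `n_nodes`.
#' @exportS3Method generics::tidy
#' @export
tidy.precision_fit <- function(x, ...) {
  purrr::imap(x$fits, function(fit, lab) {
    cf <- summary(fit)$coefficients
    tibble::tibble(label = lab, term = rownames(cf),
                   estimate = cf[, 1], std.error = cf[, 2],
                   statistic = cf[, 3], p.value = cf[, 4])
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.precision_fit
#' @exportS3Method generics::glance
#' @export
glance.precision_fit <- function(x, ...) {
  purrr::imap(x$fits, function(fit, lab) {
    s <- summary(fit)
    tibble::tibble(label = lab,
                   slope = stats::coef(fit)[["mean_age"]],
                   intercept = stats::coef(fit)[["(Intercept)"]],
                   r.squared = s$r.squared, sigma = s$sigma,
                   n_nodes = length(stats::fitted(fit)))
  }) |> dplyr::bind_rows()
}
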