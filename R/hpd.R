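#' Highest posterior density interval from age samples
#'
#' The shortest window over the sorted samples containing at least `mass` of
#' them: with `n` samples and `k = ceiling(mass * n) - 1`, the interval is the
#' `[x_(i), x_(i+k)]` of minimal length, ties broken toward the smaller lower
#' bound. This is the standard empirical HPD used to summarize node-age
#' posteriors from Bayesian dating runs.
#'
#' @param samples Numeric vector of node-age samples (Ma), length at least 2.
#' @param mass Probability mass, in (0, 1); default 0.95.
#' @return A one-row tibble with `lower`, `upper`, `mass`.
#' @examples
#' set.seed(1)
#' hpd_interval(rnorm(1e4))
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty sample vector.", call. = FALSE)
  if (length(samples) < 2) stop("need at least 2 samples.", call. = FALSE)
  if (anyNA(samples)) stop("NA in samples.", call. = FALSE)
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n) - 1L
  starts <- seq_len(n - k)
  widths <- x[starts + k] - x[starts]
  i <- which.min(widths)  # which.min takes the first minimum: smallest lower bound
  tibble::tibble(lower = x[i], upper = x[i + k], mass = mass)
}

#' HPD intervals for every node of an age posterior
#'
#' @param posterior A tibble with columns `label`, `clade`, `age` (one row per
#'   sample), e.g. from [simulate_age_posteriors()].
#' @param mass Probability mass.
#' @return A tibble `label`, `clade`, `lower`, `upper`, `mean_age`, `width`.
#' @export
hpd_by_node <- function(posterior, mass = 0.95) {
  stopifnot(all(c("label", "clade", "age") %in% names(posterior)))
  posterior |>
    dplyr::group_by(.data$label, .data$clade) |>
    dplyr::summarise(
      lower = hpd_interval(.data$age, mass)$lower,
      upper = hpd_interval(.data$age, mass)$upper,
      mean_age = mean(.data$age),
      .groups = "drop") |>
    dplyr::mutate(width = .data$upper - .data$lower)
}
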