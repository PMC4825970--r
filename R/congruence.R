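#' Temporal congruence between a geological window and node-age intervals
#'
#' Tests whether a dated geological or climatic event could have driven a
#' cladogenetic event, by comparing the event's age window with the 95%
#' divergence-time interval of the node in each dating analysis (typically
#' B1/B2/B3, the one-, six- and seven-calibration runs). Under the default
#' rule, `"all-runs-overlap"`, the null hypothesis (the event influenced the
#' divergence) is rejected iff the window is disjoint from the interval in at
#' least one analysis; it is not rejected only when every analysis overlaps
#' the window. Intervals are closed: a shared endpoint counts as overlap,
#' which is conservative toward non-rejection. Alternative rules:
#' `"any-run-overlap"` (rejected only if disjoint in every analysis) and
#' `"mean-in-window"` (rejected unless the interval midpoint falls inside the
#' window in every analysis).
#'
#' @param intervals A named list (or 2-column data frame with rownames) of
#'   `c(lower, upper)` node-age intervals in Ma, one per dating analysis,
#'   or a tibble with columns `label`, `lower`, `upper`.
#' @param window Numeric `c(older, younger)` bounds in Ma (either order is
#'   accepted and normalized), or a one-row tibble with `older_ma`,
#'   `younger_ma`.
#' @param rule Decision rule identifier.
#' @return A list with `decision` (`"rejected"` or `"not_rejected"`), and
#'   `flags`: a tibble `label`, `overlaps`.
#' @examples
#' congruence_test(list(B1 = c(8.14, 19.72), B2 = c(9.29, 22.29),
#'                      B3 = c(9.22, 23.16)), c(35, 33))
#' @export
congruence_test <- function(intervals, window,
                            rule = c("all-runs-overlap", "any-run-overlap",
                                     "mean-in-window")) {
  rule <- match.arg(rule)
  if (is.data.frame(intervals)) {
    stopifnot(all(c("label", "lower", "upper") %in% names(intervals)))
    labs <- intervals$label
    ivs <- Map(c, intervals$lower, intervals$upper)
    names(ivs) <- labs
    intervals <- ivs
  }
  if (length(intervals) < 1) stop("need at least one analysis interval.", call. = FALSE)
  if (is.data.frame(window)) window <- c(window$older_ma[1], window$younger_ma[1])
  if (anyNA(window) || length(window) != 2) {
    stop("malformed window: need two finite bounds in Ma.", call. = FALSE)
  }
  w <- sort(as.numeric(window))  # (younger, older)
  flags <- vapply(intervals, function(iv) {
    iv <- sort(as.numeric(iv))
    iv[1] <= w[2] && w[1] <= iv[2]  # closed-interval overlap
  }, logical(1))
  decision <- switch(rule,
    "all-runs-overlap" = if (all(flags)) "not_rejected" else "rejected",
    "any-run-overlap" = if (any(flags)) "not_rejected" else "rejected",
    "mean-in-window" = {
      mids <- vapply(intervals, function(iv) mean(sort(as.numeric(iv))), numeric(1))
      if (all(mids >= w[1] & mids <= w[2])) "not_rejected" else "rejected"
    })
  list(decision = decision,
       flags = tibble::tibble(label = names(intervals), overlaps = unname(flags)),
       rule = rule)
}

#' Read a hypothesis table of cladogenetic vs geological events
#'
#' Tab-separated with header: `cladogenetic_event`, `geological_event`,
#' `kind` (`geological` or `biotic`), `older_ma`, `younger_ma`, then
#' `B1_lower`, `B1_upper`, `B2_lower`, `B2_upper`, `B3_lower`, `B3_upper`,
#' and `recorded_decision`. Decimal commas are normalized on input.
#'
#' @param path File path, or a data frame in the same layout.
#' @return A tibble, one row per (cladogenetic event, geological window) pair.
#' @export
read_hypothesis_table <- function(path) {
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  need <- c("cladogenetic_event", "geological_event", "kind", "older_ma",
            "younger_ma", "B1_lower", "B1_upper", "B2_lower", "B2_upper",
            "B3_lower", "B3_upper", "recorded_decision")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("hypothesis table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("older_ma", "younger_ma", grep("^B[123]_", need, value = TRUE))
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::all_of(num_cols),
    ~ as.numeric(stringr::str_replace(as.character(.x), ",", "."))))
  dup <- duplicated(df[, c("cladogenetic_event", "geological_event")])
  if (any(dup)) {
    stop("duplicate (cladogenetic, geological) pairs: ",
         paste(df$cladogenetic_event[dup], df$geological_event[dup],
               sep = " / ", collapse = "; "), call. = FALSE)
  }
  bad <- df$B1_lower >= df$B1_upper | df$B2_lower >= df$B2_upper |
    df$B3_lower >= df$B3_upper
  if (any(bad)) {
    stop("interval with lower >= upper in rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  df
}

#' Run every row of a hypothesis table
#'
#' Applies [congruence_test()] to each (cladogenetic event, geological window)
#' pair, counts unique cladogenetic events, geological-kind hypotheses and
#' rejections, and reports disagreements with the table's recorded decisions.
#' Biotic hypotheses (e.g. co-dispersal with a host lineage) are tested but
#' excluded from the geological count. No multiple-testing correction is
#' applied; each window is assessed on its own overlap.
#'
#' @param rows A hypothesis table from [read_hypothesis_table()] (or a path).
#' @param rule Decision rule, see [congruence_test()].
#' @return A list of class `congruence_report`: `decisions` (the table plus
#'   `decision` and per-analysis overlap flags), `counts` (tibble
#'   `n_cladogenetic_events`, `n_geological_hypotheses`, `n_rejected`),
#'   `mismatches` (rows whose computed decision differs from the recorded
#'   one) and `rule`.
#' @export
run_hypothesis_table <- function(rows, rule = "all-runs-overlap") {
  rows <- read_hypothesis_table(rows)
  if (nrow(rows) == 0) {
    return(structure(list(
      decisions = rows,
      counts = tibble::tibble(n_cladogenetic_events = 0L,
                              n_geological_hypotheses = 0L, n_rejected = 0L),
      mismatches = rows, rule = rule), class = "congruence_report"))
  }
  res <- purrr::pmap(rows, function(...) {
    r <- list(...)
    ct <- congruence_test(
      list(B1 = c(r$B1_lower, r$B1_upper),
           B2 = c(r$B2_lower, r$B2_upper),
           B3 = c(r$B3_lower, r$B3_upper)),
      c(r$older_ma, r$younger_ma), rule = rule)
    tibble::tibble(decision = ct$decision,
                   B1_overlaps = ct$flags$overlaps[1],
                   B2_overlaps = ct$flags$overlaps[2],
                   B3_overlaps = ct$flags$overlaps[3])
  })
  decisions <- dplyr::bind_cols(rows, dplyr::bind_rows(res))
  counts <- tibble::tibble(
    n_cladogenetic_events = dplyr::n_distinct(decisions$cladogenetic_event),
    n_geological_hypotheses = sum(decisions$kind == "geological"),
    n_rejected = sum(decisions$decision == "rejected"))
  mismatches <- dplyr::filter(decisions, .data$decision != .data$recorded_decision)
  structure(list(decisions = decisions, counts = counts,
                 mismatches = mismatches, rule = rule),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("<congruence_report> rule:", x$rule, "\n")
  print(x$counts)
  cat(nrow(x$mismatches), "mismatch(es) against recorded decisions\n")
  invisible(x)
}

#' @rdname run_hypothesis_table
#' @param x A `congruence_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.congruence_report <- function(x, ...) x$decisions

#' @rdname run_hypothesis_table
#' @exportS3Method generics::glance
#' @export
glance.congruence_report <- function(x, ...) {
  dplyr::mutate(x$counts, n_mismatches = nrow(x$mismatches), rule = x$rule)
}
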