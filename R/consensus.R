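#' Consensus vicariance calls across a reconstruction grid
#'
#' Applies the two-part "most probable" filter to a grid of ancestral range
#' reconstructions (methods crossed with topologies): a clade is called
#' vicariant when (1) it is annotated as vicariant in at least 50% of the
#' reconstructions in the grid (inclusive boundary) and (2) its clade key
#' occurs in every supplied topology. Support can alternatively be computed
#' per topology (`scope = "per-topology"`: the clade must reach 50% within
#' each topology's reconstructions).
#'
#' @param grid A list of `ancestral_recon` objects, each tagged with a
#'   `topology` resolvable against `names(topologies)`.
#' @param topologies A named list of `dated_tree`s.
#' @param threshold Support threshold (default 0.5, inclusive).
#' @param scope `"grid"` (fraction over the whole grid, the default) or
#'   `"per-topology"`.
#' @return A tibble with one row per retained clade: `clade`, `support`
#'   (fraction of reconstructions calling it vicariant), `n_vicariant`,
#'   `n_topologies_present`.
#' @export
consensus_vicariance <- function(grid, topologies, threshold = 0.5,
                                 scope = c("grid", "per-topology")) {
  scope <- match.arg(scope)
  stopifnot(length(grid) > 0)
  if (is.null(names(topologies))) names(topologies) <- paste0("T", seq_along(topologies))
  tags <- vapply(grid, function(r) r$topology, character(1))
  unknown <- setdiff(unique(tags), names(topologies))
  if (length(unknown) > 0) {
    stop("reconstruction(s) with unknown topology tag: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vic_tbl <- purrr::map2(grid, tags, function(rec, tag) {
    ev <- rec$events
    tibble::tibble(topology = tag,
                   clade = ev$clade[ev$event == "vicariance"])
  }) |> dplyr::bind_rows(.id = "recon_i")
  topo_clades <- lapply(topologies, function(tr) unname(clade_set(tr)))
  n_topo <- length(topologies)
  if (nrow(vic_tbl) == 0) {
    return(tibble::tibble(clade = character(0), support = numeric(0),
                          n_vicariant = integer(0),
                          n_topologies_present = integer(0)))
  }
  summ <- vic_tbl |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(n_vicariant = dplyr::n_distinct(.data$recon_i),
                     .groups = "drop") |>
    dplyr::mutate(
      support = .data$n_vicariant / length(grid),
      n_topologies_present = vapply(.data$clade, function(cl) {
        sum(vapply(topo_clades, function(ks) cl %in% ks, logical(1)))
      }, integer(1), USE.NAMES = FALSE))
  keep <- summ$n_topologies_present == n_topo
  if (scope == "grid") {
    keep <- keep & summ$support >= threshold
  } else {
    per_topo_n <- table(tags)
    ok <- vapply(summ$clade, function(cl) {
      counts <- vic_tbl |>
        dplyr::filter(.data$clade == cl) |>
        dplyr::count(.data$topology)
      all(names(topologies) %in% counts$topology) &&
        all(counts$n / per_topo_n[counts$topology] >= threshold)
    }, logical(1))
    keep <- keep & ok
  }
  summ |>
    dplyr::filter(keep) |>
    dplyr::select("clade", "support", "n_vicariant", "n_topologies_present") |>
    dplyr::arrange(dplyr::desc(.data$support), .data$clade)
}
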