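#' Bayesian binary MCMC (BBM) ancestral range reconstruction
#'
#' Models each area's presence/absence as an independent two-state
#' continuous-time Markov chain along the branches of a dated tree and samples
#' ancestral presence bits by Gibbs MCMC. Under the empirical model the
#' stationary presence frequency of each area is the observed fraction of
#' tips occupying it, clamped to `[0.05, 0.95]` to avoid degeneracy (a warning
#' is logged for all-absent or all-present areas), and the chain rate is
#' scaled so that one change per area is expected along a root-to-tip path.
#'
#' Three root priors mirror the usual options: `"null"` draws the root state
#' from the stationary distribution, `"wide"` fixes the root to the full
#' alphabet, and `"custom"` fixes it to a user-supplied range. Two independent
#' runs are pooled after discarding the first 25% of each as burn-in, and the
#' maximum absolute difference in per-node marginals between the runs is
#' reported as a convergence diagnostic.
#'
#' @param tree A `dated_tree` (bifurcating).
#' @param tips A tip distribution from [read_tip_distribution()].
#' @param prior_mode `"null"`, `"wide"` or `"custom"`.
#' @param custom_root Range (letter string or mask) for the root; required iff
#'   `prior_mode = "custom"`.
#' @param pi Optional per-area stationary presence frequencies overriding the
#'   empirical model (recycled to the alphabet length). Use when the range
#'   process is known, e.g. on simulated data.
#' @param rate Optional per-area chain rate per Myr overriding the default
#'   `1 / tree height` scaling. For a gain/loss process with rates `g` and
#'   `l`, the matching chain has `rate = g + l` and `pi = g / (g + l)`.
#' @param n_generations Sweeps per run (default 50,000).
#' @param n_runs Independent runs to pool (default 2).
#' @param burnin Fraction of each run discarded (default 0.25).
#' @param seed Integer seed; mandatory so runs are reproducible.
#' @return An `ancestral_recon` (see [diva_optimize()]) with additional
#'   elements: `marginals` (tibble `clade`, `area`, `prob`), `root_posterior`
#'   (tibble `range`, `prob`, the joint sampled root-state posterior),
#'   `convergence` (max between-run marginal difference) and `pi` (the
#'   empirical stationary frequencies). Per-clade range weights combine the
#'   marginals under per-area independence, renormalized over non-empty
#'   ranges.
#' @export
bbm_reconstruct <- function(tree, tips, prior_mode = c("null", "wide", "custom"),
                            custom_root = NULL, pi = NULL, rate = NULL,
                            n_generations = 50000L,
                            n_runs = 2L, burnin = 0.25, seed) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(tree, "dated_tree"))
  if (missing(seed)) stop("`seed` is mandatory for BBM runs.", call. = FALSE)
  alphabet <- attr(tips, "alphabet")
  k <- length(alphabet)
  if (prior_mode == "custom" && is.null(custom_root)) {
    stop("prior_mode = \"custom\" requires `custom_root`.", call. = FALSE)
  }
  tip_mask <- tip_masks_for_tree(tree, tips)
  n_tip <- length(tree$tip.label)
  tip_states <- t(vapply(tip_mask, function(m) {
    as.integer(bitwAnd(bitwShiftR(m, seq_len(k) - 1L), 1L))
  }, integer(k)))

  height <- tree_height(tree)
  if (is.null(pi)) {
    pres_frac <- colMeans(tip_states)
    degenerate <- pres_frac == 0 | pres_frac == 1
    if (any(degenerate)) {
      warning("area(s) with all-absent or all-present tips: ",
              paste(alphabet[degenerate], collapse = ", "),
              "; stationary frequencies clamped to [0.05, 0.95].", call. = FALSE)
    }
    pi <- pmin(pmax(pres_frac, 0.05), 0.95)
  } else {
    pi <- rep(pi, length.out = k)
    stopifnot(all(pi > 0), all(pi < 1))
  }
  # default chain rate: one expected transition opportunity per root-to-tip
  # path for every area, regardless of how skewed its frequency is
  mu <- if (is.null(rate)) rep(1 / height, k) else rep(rate, length.out = k)

  n <- n_tip + tree$Nnode
  parent <- integer(n); edge_time <- numeric(n)
  child_left <- integer(n); child_right <- integer(n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    parent[ch] <- p
    edge_time[ch] <- tree$edge.length[i]
    if (child_left[p] == 0L) child_left[p] <- ch else child_right[p] <- ch
  }
  custom_bits <- integer(k)
  if (prior_mode == "custom") {
    cm <- range_mask(custom_root, alphabet)
    custom_bits <- as.integer(bitwAnd(bitwShiftR(cm, seq_len(k) - 1L), 1L))
  }
  root_mode <- match(prior_mode, c("null", "wide", "custom")) - 1L

  set.seed(as.integer(seed))
  n_burn <- floor(burnin * n_generations)
  runs <- lapply(seq_len(n_runs), function(r) {
    bbm_gibbs_cpp(parent, child_left, child_right, edge_time, n_tip,
                  tip_states, pi, mu, as.integer(n_generations),
                  as.integer(n_burn), root_mode, custom_bits)
  })
  marg_runs <- lapply(runs, `[[`, "marginals")
  convergence <- if (n_runs >= 2) {
    max(vapply(seq_len(n_runs - 1), function(r) {
      max(abs(marg_runs[[r]] - marg_runs[[r + 1]]))
    }, numeric(1)))
  } else NA_real_
  marg <- Reduce(`+`, marg_runs) / n_runs
  root_counts <- Reduce(`+`, lapply(runs, `[[`, "root_counts"))

  keys <- clade_set(tree)
  internal <- (n_tip + 1L):n
  marg_tbl <- tidyr::expand_grid(node = internal, area_i = seq_len(k)) |>
    dplyr::mutate(clade = unname(keys[as.character(.data$node)]),
                  area = as.character(alphabet)[.data$area_i],
                  prob = marg[cbind(.data$node - n_tip, .data$area_i)]) |>
    dplyr::select("clade", "area", "prob")

  # range weights per node under per-area independence, non-empty ranges only
  all_masks <- seq_len(bitwShiftL(1L, k) - 1L)
  bits <- t(vapply(all_masks, function(m) {
    as.integer(bitwAnd(bitwShiftR(m, seq_len(k) - 1L), 1L))
  }, integer(k)))
  range_rows <- purrr::map(internal, function(v) {
    p <- marg[v - n_tip, ]
    w <- apply(bits, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
    w <- w / sum(w)
    tibble::tibble(clade = unname(keys[as.character(v)]),
                   mask = all_masks, weight = w)
  })
  tip_rows <- tibble::tibble(
    clade = unname(keys[as.character(seq_len(n_tip))]),
    mask = tip_mask, weight = 1)
  ranges <- dplyr::bind_rows(dplyr::bind_rows(range_rows), tip_rows) |>
    dplyr::mutate(range = mask_range(.data$mask, alphabet)) |>
    dplyr::select("clade", "range", "mask", "weight")

  root_total <- sum(root_counts)
  nz <- which(root_counts > 0)
  root_posterior <- tibble::tibble(
    range = mask_range(nz - 1L, alphabet),
    prob = root_counts[nz] / root_total) |>
    dplyr::arrange(dplyr::desc(.data$prob))

  rec <- new_ancestral_recon(
    ranges = ranges, cost = NA_integer_,
    method = paste0("BBM-", prior_mode), topology = "tree",
    alphabet = alphabet, tree = tree,
    extra = list(marginals = marg_tbl, root_posterior = root_posterior,
                 convergence = convergence, pi = stats::setNames(pi, alphabet),
                 n_generations = n_generations, n_runs = n_runs, seed = seed))
  annotate_events(rec, tree)
}
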