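#' Exact dispersal-vicariance (DIVA) ancestral range reconstruction
#'
#' Event-based parsimony reconstruction of ancestral geographic ranges under
#' the DIVA cost model: vicariant splits and within-area duplications are
#' free, each area gained along a branch (dispersal) costs 1, and each area
#' lost (local extinction) costs 1. The reconstruction is an exact dynamic
#' programme over all candidate ranges: a bottom-up pass computes, for every
#' node and every candidate range `R`, the minimal cost of the subtree given
#' the node occupies `R`, enumerating at each internal node all ordered
#' bipartitions of `R` into the two subsets inherited by the daughter
#' lineages (duplication `R,R` is allowed only for single-area ranges), with
#' the branch cost between an inherited subset `S` and the child's range `C`
#' equal to the symmetric difference `|C \ S| + |S \ C|`. A top-down traceback
#' then marks every range that occurs at a node in at least one globally
#' minimal reconstruction; ties receive uniform weights.
#'
#' Exact mode enumerates all non-empty subsets and is capped at 8 areas
#' (the subset-pair enumeration grows as 3^k). Above the cap the candidate
#' ranges are restricted to the union-closure of the observed tip ranges and
#' a warning is issued; `mode = "exact"` instead fails with a capability
#' error suggesting the restriction.
#'
#' @param tree A `dated_tree` (bifurcating).
#' @param tips A tip distribution from [read_tip_distribution()] covering the
#'   tree's tips.
#' @param max_areas Maximum allowed ancestral range size (default 12, i.e.
#'   ancestors may occupy the whole alphabet).
#' @param mode `"auto"` (exact when the alphabet has at most 8 areas, else
#'   restricted), `"exact"`, or `"restricted"`.
#' @return An object of class `ancestral_recon`: a list with `ranges` (tibble
#'   `clade`, `range`, `weight`), `events` (tibble `clade`, `event`, filled by
#'   [annotate_events()]), `cost` (the global minimum), `method`, `topology`,
#'   and the `alphabet`.
#' @examples
#' tr <- read_dated_tree("((t1:1,t2:1):1,t3:2);")
#' tips <- read_tip_distribution(data.frame(taxon = c("t1", "t2", "t3"),
#'                                          A = c(1, 0, 1), B = c(0, 1, 0)))
#' rec <- diva_optimize(tr, tips)
#' rec$cost
#' @export
diva_optimize <- function(tree, tips, max_areas = 12L,
                          mode = c("auto", "exact", "restricted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "dated_tree"))
  alphabet <- attr(tips, "alphabet")
  k <- length(alphabet)
  tip_mask <- tip_masks_for_tree(tree, tips)
  if (mode == "exact" && k > 8) {
    stop("exact DIVA is capped at 8 areas (", k, " supplied); ",
         "restrict candidate range sizes or use mode = \"restricted\".",
         call. = FALSE)
  }
  restricted <- mode == "restricted" || (mode == "auto" && k > 8)
  if (restricted && mode == "auto") {
    warning("more than 8 areas: candidate ancestral ranges restricted to ",
            "unions of observed tip ranges.", call. = FALSE)
  }
  cand <- diva_candidates(tip_mask, k, max_areas, restricted)
  fit <- diva_dp(tree, tip_mask, cand, max_areas)
  ranges <- diva_traceback(tree, fit, cand)
  keys <- clade_set(tree)
  out <- new_ancestral_recon(
    ranges = tibble::tibble(
      clade = unname(keys[as.character(ranges$node)]),
      range = mask_range(ranges$mask, alphabet),
      mask = ranges$mask,
      weight = ranges$weight),
    cost = fit$opt_cost,
    method = "S-DIVA", topology = "tree", alphabet = alphabet, tree = tree)
  annotate_events(out, tree)
}

# candidate range masks
diva_candidates <- function(tip_mask, k, max_areas, restricted) {
  if (!restricted) {
    cand <- seq_len(bitwShiftL(1L, k) - 1L)
  } else {
    cand <- unique(tip_mask)
    repeat {
      more <- unique(as.integer(outer(cand, cand, bitwOr)))
      if (length(setdiff(more, cand)) == 0) break
      cand <- union(cand, more)
    }
    cand <- sort(cand)
  }
  # observed tip ranges always stay candidates, even above max_areas
  sort(union(cand[mask_size(cand) <= max_areas], unique(tip_mask)))
}

# bottom-up DP: cost[node, candidate] with traceback info recomputed on demand
diva_dp <- function(tree, tip_mask, cand, max_areas = 12L) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  nc <- length(cand)
  cand_idx <- integer(max(cand)); cand_idx[cand] <- seq_len(nc)
  # symmetric-difference branch costs between all candidate pairs
  trans <- matrix(0L, nc, nc)
  for (i in seq_len(nc)) trans[i, ] <- mask_size(bitwXor(cand[i], cand))
  # ordered bipartitions per candidate: list of 2-col index matrices
  bip <- vector("list", nc)
  for (i in seq_len(nc)) {
    R <- cand[i]
    areas <- which(bitwAnd(bitwShiftR(R, 0:11), 1L) == 1L) - 1L
    sz <- length(areas)
    if (sz == 1L) {
      bip[[i]] <- matrix(c(i, i), ncol = 2)  # duplication only
      next
    }
    # assign each area to left (bit 1) or right (bit 0); exclude all-one-side
    assign_codes <- seq_len(bitwShiftL(1L, sz) - 2L)
    lefts <- vapply(assign_codes, function(a) {
      sum(bitwShiftL(1L, areas[bitwAnd(bitwShiftR(a, seq_len(sz) - 1L), 1L) == 1L]))
    }, numeric(1))
    rights <- R - lefts
    li <- cand_idx[as.integer(lefts)]; ri <- cand_idx[as.integer(rights)]
    keep <- li > 0L & ri > 0L
    bip[[i]] <- cbind(li[keep], ri[keep])
  }
  cost <- matrix(Inf, n, nc)
  for (t in seq_len(n_tip)) {
    ci <- cand_idx[tip_mask[t]]
    if (ci == 0L) stop("observed tip range outside candidate set.", call. = FALSE)
    cost[t, ci] <- 0
  }
  phy2 <- ape::reorder.phylo(tree, "postorder")
  children <- split(phy2$edge[, 2], phy2$edge[, 1])
  # postorder over internal nodes
  internal_order <- unique(phy2$edge[, 1])
  best_in <- matrix(Inf, n, nc)  # best_in[v, s] = min_C trans(s,C)+cost(v,C)
  for (t in seq_len(n_tip)) {
    ci <- cand_idx[tip_mask[t]]
    best_in[t, ] <- trans[, ci]
  }
  for (v in internal_order) {
    ch <- children[[as.character(v)]]
    bl <- best_in[ch[1], ]; br <- best_in[ch[2], ]
    cv <- vapply(seq_len(nc), function(i) {
      if (mask_size(cand[i]) > max_areas) return(Inf)  # ancestral-range cap
      b <- bip[[i]]
      min(bl[b[, 1]] + br[b[, 2]])
    }, numeric(1))
    cost[v, ] <- cv
    for (s in seq_len(nc)) best_in[v, s] <- min(trans[s, ] + cv)
  }
  root <- n_tip + 1L
  list(cost = cost, best_in = best_in, trans = trans, bip = bip,
       cand = cand, cand_idx = cand_idx, children = children,
       internal_order = internal_order, root = root,
       opt_cost = as.integer(min(cost[root, ])))
}

# mark every candidate range occurring in some globally optimal reconstruction
diva_traceback <- function(tree, fit, cand) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  nc <- length(cand)
  optimal <- vector("list", n)
  root <- fit$root
  tol <- 1e-9
  optimal[[root]] <- which(fit$cost[root, ] <= fit$opt_cost + tol)
  # preorder = reverse postorder over internal nodes
  preorder <- rev(fit$internal_order)
  for (v in preorder) {
    ch <- fit$children[[as.character(v)]]
    marked <- optimal[[v]]
    if (is.null(marked)) next
    child_sets <- list(integer(0), integer(0))
    for (i in marked) {
      b <- fit$bip[[i]]
      tot <- fit$best_in[ch[1], b[, 1]] + fit$best_in[ch[2], b[, 2]]
      ach <- which(tot <= fit$cost[v, i] + tol)
      for (a in ach) {
        for (side in 1:2) {
          s <- b[a, side]
          cc <- fit$trans[s, ] + fit$cost[ch[side], ]
          child_sets[[side]] <- union(child_sets[[side]],
                                      which(cc <= fit$best_in[ch[side], s] + tol))
        }
      }
    }
    for (side in 1:2) {
      if (ch[side] > n_tip) optimal[[ch[side]]] <- sort(child_sets[[side]])
    }
  }
  rows <- list()
  for (v in c(fit$root, setdiff(fit$internal_order, fit$root))) {
    idx <- optimal[[v]]
    w <- rep(1 / length(idx), length(idx))
    rows[[length(rows) + 1L]] <- tibble::tibble(node = v, mask = cand[idx], weight = w)
  }
  # tips carry their observed range with weight 1
  for (t in seq_len(n_tip)) {
    ci <- which(fit$cost[t, ] == 0)
    rows[[length(rows) + 1L]] <- tibble::tibble(node = t, mask = cand[ci], weight = 1)
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$node, .data$mask)
}

new_ancestral_recon <- function(ranges, cost, method, topology, alphabet, tree,
                                events = NULL, extra = list()) {
  structure(c(list(ranges = ranges, events = events, cost = cost,
                   method = method, topology = topology,
                   alphabet = alphabet, tree = tree), extra),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("<ancestral_recon> method:", x$method, " topology:", x$topology, "\n")
  if (!is.null(x$cost) && is.finite(x$cost)) cat("optimal cost:", x$cost, "\n")
  n_int <- sum(!grepl("^[^;]*$", unique(x$ranges$clade)))
  cat(n_int, "internal clades;", nrow(x$ranges), "range rows\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ancestral reconstruction
#'
#' @param x An `ancestral_recon`.
#' @param ... Unused.
#' @return A tibble with one row per (clade, candidate range) pair: `clade`,
#'   `range`, `weight`, plus `method` and `topology` tags.
#' @exportS3Method generics::tidy
#' @export
tidy.ancestral_recon <- function(x, ...) {
  dplyr::mutate(dplyr::select(x$ranges, -dplyr::any_of("mask")),
                method = x$method, topology = x$topology)
}

#' @rdname tidy.ancestral_recon
#' @exportS3Method generics::glance
#' @export
glance.ancestral_recon <- function(x, ...) {
  tibble::tibble(method = x$method, topology = x$topology,
                 cost = if (is.null(x$cost)) NA_integer_ else x$cost,
                 n_clades = length(unique(x$ranges$clade)),
                 n_vicariant = if (is.null(x$events)) NA_integer_ else
                   sum(x$events$event == "vicariance"))
}

#' Statistical DIVA over a sample of trees
#'
#' Runs [diva_optimize()] on every tree of a sample and averages, for each
#' clade, the uniform tie-weights of its candidate ancestral ranges over the
#' trees that contain the clade. Clades absent from some trees are flagged by
#' their occupancy (the fraction of trees containing them).
#'
#' @param trees A list of `dated_tree`s over one tip set (e.g. from
#'   [read_tree_sample()]).
#' @inheritParams diva_optimize
#' @return A tibble with columns `clade`, `range`, `frequency`, `occupancy`.
#'   Frequencies sum to 1 within each clade.
#' @export
sdiva <- function(trees, tips, max_areas = 12L,
                  mode = c("auto", "exact", "restricted")) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("empty tree list.", call. = FALSE)
  n_tree <- length(trees)
  per_tree <- purrr::map(trees, function(tr) {
    rec <- diva_optimize(tr, tips, max_areas = max_areas, mode = mode)
    dplyr::select(rec$ranges, "clade", "range", "weight")
  })
  all_ranges <- dplyr::bind_rows(per_tree, .id = "tree_i")
  occ <- all_ranges |>
    dplyr::distinct(.data$tree_i, .data$clade) |>
    dplyr::count(.data$clade, name = "n_present")
  all_ranges |>
    dplyr::group_by(.data$clade, .data$range) |>
    dplyr::summarise(total = sum(.data$weight), .groups = "drop") |>
    dplyr::left_join(occ, by = "clade") |>
    dplyr::mutate(frequency = .data$total / .data$n_present,
                  occupancy = .data$n_present / n_tree) |>
    dplyr::select("clade", "range", "frequency", "occupancy") |>
    dplyr::arrange(.data$clade, dplyr::desc(.data$frequency))
}
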