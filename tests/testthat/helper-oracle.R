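# Test helpers: random instance generators and brute-force oracles that are
# independent of the package's own algorithms.

# random ultrametric bifurcating tree via the coalescent (ape), ages rescaled
random_dated_tree <- function(n, height = 10) {
  phy <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
  phy$edge.length <- phy$edge.length * height / max(ape::node.depth.edgelength(phy))
  as_dated_tree(phy)
}

# random non-empty tip ranges over k areas as a tip-distribution tibble
random_tips <- function(tree, k) {
  alphabet <- area_alphabet(LETTERS[seq_len(k)])
  masks <- sample.int(bitwShiftL(1L, k) - 1L, length(tree$tip.label),
                      replace = TRUE)
  tips_tbl(tree$tip.label, masks, alphabet)
}

tips_tbl <- function(taxa, masks, alphabet) {
  out <- tibble::tibble(taxon = taxa,
                        range = mask_range(masks, alphabet),
                        mask = as.integer(masks))
  attr(out, "alphabet") <- alphabet
  out
}

popcount <- function(m) {
  vapply(as.integer(m), function(x) sum(bitwAnd(bitwShiftR(x, 0:11), 1L)),
         integer(1))
}

# Exhaustive DIVA oracle: enumerate every assignment of a non-empty range to
# every internal node; the cost of one assignment decomposes over internal
# nodes as the cheapest allowed split of the node's range toward the two
# child ranges (symmetric-difference branch costs; duplication only for
# single-area ranges). Returns the global minimum, the optimal root ranges
# and the optimal range set for every internal node.
diva_oracle <- function(tree, tip_mask, k) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  subsets <- seq_len(bitwShiftL(1L, k) - 1L)
  ns <- length(subsets)
  # node-cost table over (parent range, left child range, right child range)
  split_cost <- array(Inf, dim = c(ns, ns, ns))
  for (ri in seq_len(ns)) {
    R <- subsets[ri]
    areas <- which(bitwAnd(bitwShiftR(R, 0:(k - 1)), 1L) == 1L) - 1L
    pairs <- if (length(areas) == 1L) {
      list(c(R, R))
    } else {
      codes <- seq_len(bitwShiftL(1L, length(areas)) - 2L)
      lapply(codes, function(a) {
        s1 <- sum(bitwShiftL(1L,
          areas[bitwAnd(bitwShiftR(a, seq_along(areas) - 1L), 1L) == 1L]))
        c(s1, R - s1)
      })
    }
    for (ci in seq_len(ns)) for (di in seq_len(ns)) {
      best <- Inf
      for (p in pairs) {
        cost <- popcount(bitwXor(p[1], subsets[ci])) +
          popcount(bitwXor(p[2], subsets[di]))
        if (cost < best) best <- cost
      }
      split_cost[ri, ci, di] <- best
    }
  }
  phy2 <- ape::reorder.phylo(tree, "postorder")
  children <- split(phy2$edge[, 2], phy2$edge[, 1])
  internal <- unique(phy2$edge[, 1])
  assign <- as.matrix(expand.grid(rep(list(subsets), length(internal))))
  colnames(assign) <- as.character(internal)
  range_of <- function(v, assign) {
    if (v <= n_tip) rep(tip_mask[v], nrow(assign)) else assign[, as.character(v)]
  }
  total <- numeric(nrow(assign))
  for (v in internal) {
    ch <- children[[as.character(v)]]
    total <- total + split_cost[cbind(match(assign[, as.character(v)], subsets),
                                      match(range_of(ch[1], assign), subsets),
                                      match(range_of(ch[2], assign), subsets))]
  }
  opt <- min(total)
  opt_rows <- which(total == opt)
  root <- n_tip + 1L
  per_node <- lapply(internal, function(v) {
    sort(unique(assign[opt_rows, as.character(v)]))
  })
  names(per_node) <- as.character(internal)
  list(cost = opt,
       root_ranges = sort(unique(assign[opt_rows, as.character(root)])),
       per_node = per_node)
}

# brute-force shortest 95% window over all contiguous windows of sorted data
hpd_bruteforce <- function(x, mass = 0.95) {
  x <- sort(x); n <- length(x)
  need <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - need + 1L)) {
    lo <- x[i]; hi <- x[i + need - 1L]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# masks -> tip distribution for a named alphabet string like "ABC"
make_alphabet <- function(codes) area_alphabet(strsplit(codes, "")[[1]])
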