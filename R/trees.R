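#' Dated phylogenetic trees
#'
#' A `dated_tree` is an ape [ape::phylo] object augmented with per-node ages
#' in Ma, validated to be rooted, bifurcating and ultrametric. All downstream
#' stages (ancestral range reconstruction, temporal-congruence testing) operate
#' on this object. Node ages are derived from branch lengths: the age of a node
#' is the maximum root-to-tip path length minus the root-to-node path length,
#' so every tip sits at age 0 (the present) and ages increase towards the root.
#'
#' @param x A [ape::phylo] object, a Newick string, or a path to a Newick file.
#' @param tol Relative ultrametricity tolerance, as a fraction of tree height.
#'   Dating software emits rounded branch lengths, so exact equality of tip
#'   depths cannot be required.
#' @return An object of class `c("dated_tree", "phylo")` with an extra element
#'   `node_age`: a numeric vector of length `Ntip + Nnode`, ages in Ma indexed
#'   by ape node number.
#' @examples
#' tr <- read_dated_tree("((A:1,B:1):2,(C:2,D:2):1);")
#' tree_height(tr)
#' node_ages(tr)
#' @export
read_dated_tree <- function(x, tol = 1e-6) {
  phy <- if (inherits(x, "phylo")) {
    x
  } else if (is.character(x) && length(x) == 1) {
    txt <- if (grepl("\\(", x)) x else paste(readLines(x, warn = FALSE), collapse = "")
    check_newick_syntax(txt)
    ape::read.tree(text = txt)
  } else {
    stop("`x` must be a phylo object, a Newick string, or a file path.", call. = FALSE)
  }
  if (is.null(phy)) stop("Newick parse failed: no tree found in input.", call. = FALSE)
  as_dated_tree(phy, tol = tol)
}

# Pre-scan a Newick string so malformed input fails with a character offset,
# which ape's parser does not report.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unmatched ')' at character offset %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf(
      "malformed Newick: %d unclosed '(' at end of string (offset %d)",
      depth, length(chars)), call. = FALSE)
  }
  if (!grepl(";", txt)) {
    stop(sprintf("malformed Newick: missing ';' terminator (offset %d)",
                 nchar(txt)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname read_dated_tree
#' @export
as_dated_tree <- function(x, tol = 1e-6) {
  phy <- x
  if (!inherits(phy, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; a dated tree requires them (Myr).",
         call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(phy$tip.label))) stop("empty tip labels are not allowed.", call. = FALSE)
  if (any(phy$edge.length < 0)) stop("negative branch lengths.", call. = FALSE)
  if (any(tabulate(phy$edge[, 1]) > 2L)) {
    stop("tree contains polytomies; DIVA requires a fully bifurcating tree. ",
         "Resolve polytomies (e.g. ape::multi2di) before use.", call. = FALSE)
  }
  depth <- node_depths(phy)
  n_tip <- length(phy$tip.label)
  height <- max(depth[seq_len(n_tip)])
  dev <- abs(depth[seq_len(n_tip)] - height)
  if (height > 0 && max(dev) > tol * height) {
    worst <- phy$tip.label[which.max(dev)]
    stop(sprintf(
      "tree is not ultrametric: tip '%s' deviates by %.6g from tree height %.6g (tolerance %.3g relative)",
      worst, max(dev), height, tol), call. = FALSE)
  }
  phy$node_age <- height - depth
  # tips are exactly the present once validated
  phy$node_age[seq_len(n_tip)] <- 0
  class(phy) <- c("dated_tree", "phylo")
  phy
}

# Root-to-node path lengths, indexed by ape node number.
node_depths <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  depth <- numeric(n)
  # edges in ape cladewise order are parent-before-child after reorder
  phy2 <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(phy2$edge))) {
    depth[phy2$edge[i, 2]] <- depth[phy2$edge[i, 1]] + phy2$edge.length[i]
  }
  depth
}

#' @rdname read_dated_tree
#' @param tree A `dated_tree`.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  tree$node_age
}

#' @rdname read_dated_tree
#' @export
tree_height <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  max(tree$node_age)
}

#' @rdname read_dated_tree
#' @export
write_dated_tree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Clade identity across topologies
#'
#' A clade key is the sorted, `;`-joined set of tip labels subtended by a node.
#' It gives nodes a stable identity that can be compared across topologies
#' with the same tip set, which is what the "same clade in all topologies"
#' consensus criterion needs.
#'
#' @param labels Character vector of tip labels.
#' @return A single string, the canonical clade key.
#' @examples
#' clade_key(c("B", "A"))
#' @export
clade_key <- function(labels) {
  paste(sort(unique(as.character(labels))), collapse = ";")
}

#' @rdname clade_key
#' @param key A clade key string.
#' @export
clade_key_taxa <- function(key) strsplit(key, ";", fixed = TRUE)[[1]]

#' All clades of a tree
#'
#' Returns the clade key of every node (tips included). For a bifurcating tree
#' of `n` tips this is `2n - 1` keys.
#'
#' @param tree A `dated_tree` (or plain `phylo`).
#' @param internal_only If `TRUE`, return only keys of internal nodes.
#' @return Character vector of clade keys, named by ape node number.
#' @export
clade_set <- function(tree, internal_only = FALSE) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  tips_below <- vector("list", n)
  for (i in seq_len(n_tip)) tips_below[[i]] <- tree$tip.label[i]
  phy2 <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[i, 1]; ch <- phy2$edge[i, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  keys <- vapply(tips_below, clade_key, character(1))
  names(keys) <- as.character(seq_len(n))
  if (internal_only) keys[(n_tip + 1L):n] else keys
}

#' Most recent common ancestor of a taxon set
#'
#' @param tree A `dated_tree`.
#' @param taxa Character vector of tip labels, length at least 2.
#' @return The clade key of the smallest clade containing all of `taxa`.
#' @examples
#' tr <- read_dated_tree("((A:1,B:1):2,(C:2,D:2):1);")
#' mrca_clade(tr, c("C", "D"))
#' @export
mrca_clade <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(taxa) < 2) stop("need at least 2 taxa for an MRCA.", call. = FALSE)
  node <- ape::getMRCA(tree, taxa)
  keys <- clade_set(tree)
  unname(keys[as.character(node)])
}

#' Age of a clade's MRCA in Ma
#'
#' @inheritParams mrca_clade
#' @export
mrca_age <- function(tree, taxa) {
  key <- mrca_clade(tree, taxa)
  keys <- clade_set(tree)
  node <- as.integer(names(keys)[match(key, keys)])
  tree$node_age[node]
}

#' Taxa whose placement differs between two topologies
#'
#' Greedy search for a small taxon set whose removal makes the clade sets of
#' two trees identical: repeatedly remove the single taxon whose removal most
#' reduces the symmetric difference of (non-trivial) clade sets, breaking ties
#' alphabetically, until the difference is empty. This approximates the
#' "Disagree" style of topology comparison, which reports the discordant taxa
#' rather than just a distance.
#'
#' @param t1,t2 Trees over an identical tip set.
#' @return Character vector of discordant tip labels (possibly empty), sorted.
#' @export
discordant_taxa <- function(t1, t2) {
  s1 <- sort(t1$tip.label); s2 <- sort(t2$tip.label)
  if (!identical(s1, s2)) {
    stop("tip sets differ: ", paste(
      c(setdiff(s1, s2), setdiff(s2, s1)), collapse = ", "), call. = FALSE)
  }
  c1 <- clade_list(t1); c2 <- clade_list(t2)
  removed <- character(0)
  repeat {
    d <- sym_diff_size(c1, c2)
    if (d == 0L) break
    cand <- sort(setdiff(s1, removed))
    best_tax <- NA_character_; best_d <- d
    for (tax in cand) {
      d_tax <- sym_diff_size(drop_taxon(c1, tax), drop_taxon(c2, tax))
      if (d_tax < best_d) { best_d <- d_tax; best_tax <- tax }
    }
    if (is.na(best_tax)) {
      # no single removal helps; remove the alphabetically first taxon that
      # appears in a disagreeing clade so the loop always terminates
      keys1 <- vapply(c1, clade_key, character(1))
      keys2 <- vapply(c2, clade_key, character(1))
      bad <- c(c1[!keys1 %in% keys2], c2[!keys2 %in% keys1])
      best_tax <- sort(unique(unlist(bad)))[1]
    }
    removed <- c(removed, best_tax)
    c1 <- drop_taxon(c1, best_tax)
    c2 <- drop_taxon(c2, best_tax)
  }
  sort(removed)
}

# internal clades as a list of label vectors (non-trivial only)
clade_list <- function(tree) {
  keys <- clade_set(tree, internal_only = TRUE)
  lapply(keys, clade_key_taxa)
}

drop_taxon <- function(clades, tax) {
  out <- lapply(clades, function(cl) setdiff(cl, tax))
  out <- out[vapply(out, length, integer(1)) >= 2]
  out[!duplicated(vapply(out, clade_key, character(1)))]
}

sym_diff_size <- function(c1, c2) {
  k1 <- unique(vapply(c1, clade_key, character(1)))
  k2 <- unique(vapply(c2, clade_key, character(1)))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Read a sample of dated trees with burn-in
#'
#' Reads a posterior sample of trees (a NEXUS trees block, honoring the
#' translate table, or multi-line Newick) and discards the first
#' `floor(burnin * n)` trees, the usual treatment of MCMC tree samples.
#'
#' @param x Path to a NEXUS or Newick file, or a list of `dated_tree`s.
#' @param burnin Fraction of initial trees to discard, in `[0, 1)`. Defaults to
#'   0.25, the standard burn-in for Bayesian dating runs.
#' @param tol Ultrametricity tolerance passed to [as_dated_tree()].
#' @return A list of `dated_tree`s with attributes `burnin` (fraction) and
#'   `n_discarded`.
#' @export
read_tree_sample <- function(x, burnin = 0.25, tol = 1e-6) {
  stopifnot(burnin >= 0, burnin < 1)
  trees <- if (is.list(x) && !inherits(x, "phylo")) {
    x
  } else if (is.character(x)) {
    txt <- readLines(x, warn = FALSE)
    if (any(grepl("#NEXUS", txt, ignore.case = TRUE))) {
      trs <- ape::read.nexus(x)
      if (inherits(trs, "multiPhylo")) trs <- ape::.uncompressTipLabel(trs)
      if (inherits(trs, "phylo")) list(trs) else unclass(trs)
    } else {
      trs <- ape::read.tree(x)
      if (inherits(trs, "phylo")) list(trs) else unclass(trs)
    }
  } else {
    stop("`x` must be a file path or a list of trees.", call. = FALSE)
  }
  if (length(trees) == 0) stop("no trees found.", call. = FALSE)
  trees <- lapply(trees, as_dated_tree, tol = tol)
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tipsets, identical, logical(1), tipsets[[1]]))) {
    stop("trees in a sample must share one tip set.", call. = FALSE)
  }
  n_drop <- floor(burnin * length(trees))
  kept <- trees[seq.int(n_drop + 1L, length(trees))]
  attr(kept, "burnin") <- burnin
  attr(kept, "n_discarded") <- n_drop
  kept
}
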