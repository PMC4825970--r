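#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: tree shape (birth and
#' death rates per Myr, number of extant tips), range evolution (area
#' alphabet, per-area gain/loss rates per Myr, root range, nodes at which a
#' vicariant split is implanted), and the pseudo-posterior noise model
#' (per-analysis lognormal scales, strictly decreasing from B1 to B3 to
#' emulate precision growing with the number of fossil calibrations).
#'
#' Defaults describe a Triatominae-sized toy problem: 20 extant tips from a
#' birth-death process (birth 0.15/Myr, death 0.05/Myr, so tree heights of a
#' few tens of Myr), three areas with gain and loss at 0.02/Myr (about one
#' range change per area along a root-to-tip path), and coefficient-of-
#' variation noise scales 0.4/0.25/0.15 for B1/B2/B3.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Speciation/extinction rates per Myr.
#' @param alphabet An [area_alphabet()].
#' @param gain,loss Per-area range gain/loss rates per Myr (scalar or
#'   per-area vector).
#' @param root_range Root range (letter string over `alphabet`).
#' @param implant_vicariance Clade keys (or internal node numbers) at which a
#'   forced disjoint split is implanted.
#' @param posterior_n Samples per node in each pseudo-posterior.
#' @param noise Named numeric, lognormal coefficient-of-variation per
#'   analysis label; must be strictly decreasing from B1 to B3.
#' @param seed Integer seed; mandatory.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 20L, birth = 0.15, death = 0.05,
                       alphabet = area_alphabet(c("A", "B", "C")),
                       gain = 0.02, loss = 0.02, root_range = "AB",
                       implant_vicariance = character(0),
                       posterior_n = 1000L,
                       noise = c(B1 = 0.4, B2 = 0.25, B3 = 0.15),
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  if (n_tips < 2) stop("n_tips must be >= 2.", call. = FALSE)
  if (birth <= 0 || death < 0 || any(gain < 0) || any(loss < 0)) {
    stop("rates must be non-negative (birth > 0).", call. = FALSE)
  }
  if (is.null(names(noise)) || any(diff(noise) >= 0)) {
    stop("noise scales must be named and strictly decreasing (B1 > B2 > B3).",
         call. = FALSE)
  }
  structure(list(n_tips = as.integer(n_tips), birth = birth, death = death,
                 alphabet = alphabet, gain = gain, loss = loss,
                 root_range = root_range,
                 implant_vicariance = implant_vicariance,
                 posterior_n = as.integer(posterior_n), noise = noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ultrametric birth-death tree
#'
#' Forward birth-death simulation stopped at the moment the extant lineage
#' count first reaches `n_tips`; full-extinction draws are resampled up to a
#' retry cap of 1,000. Branch durations are in Myr and tips sit at age 0, so
#' the result is a valid `dated_tree`. Identical config and seed give a
#' byte-identical Newick string.
#'
#' @param config A [sim_config()].
#' @return A `dated_tree` with `config$n_tips` tips labeled `t1, t2, ...`.
#' @export
simulate_dated_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  for (try in seq_len(1000L)) {
    tr <- bd_forward(config$n_tips, config$birth, config$death)
    if (!is.null(tr)) return(as_dated_tree(tr))
  }
  stop("birth-death simulation went extinct in 1000 consecutive attempts; ",
       "lower the death rate.", call. = FALSE)
}

# forward birth-death; returns phylo with n extant tips or NULL on extinction
bd_forward <- function(n, birth, death) {
  # lineage records: id, parent id, birth time, death time (NA while alive)
  id <- 1L; parent <- NA_integer_; t_birth <- 0; t_death <- NA_real_
  alive <- 1L
  t <- 0
  next_id <- 2L
  while (length(alive) < n) {
    k <- length(alive)
    if (k == 0L) return(NULL)
    rate <- k * (birth + death)
    t <- t + stats::rexp(1, rate)
    who <- alive[sample.int(k, 1)]
    if (stats::runif(1) < birth / (birth + death)) {
      # speciation: `who` dies as a lineage record, two children born
      t_death[who] <- t
      for (j in 1:2) {
        id <- c(id, next_id); parent <- c(parent, who)
        t_birth <- c(t_birth, t); t_death <- c(t_death, NA_real_)
        alive <- c(alive, next_id)
        next_id <- next_id + 1L
      }
      alive <- setdiff(alive, who)
    } else {
      t_death[who] <- t
      alive <- setdiff(alive, who)
    }
  }
  # freeze one (event-free) waiting time after the n-th lineage appears, so
  # terminal branches have positive length; extant lineages run to t_end
  t_end <- t + stats::rexp(1, length(alive) * (birth + death))
  t_death[alive] <- NA_real_
  # build the genealogy of the extant sample: keep lineages with extant
  # descendants, suppress unary nodes
  has_extant <- rep(FALSE, length(id))
  children <- split(id, factor(parent, levels = id))
  mark <- function(v) {
    ch <- children[[as.character(v)]]
    if (v %in% alive) { has_extant[v] <<- TRUE }
    for (c in ch %||% integer(0)) {
      mark(c)
      if (has_extant[c]) has_extant[v] <<- TRUE
    }
  }
  mark(1L)
  if (!has_extant[1L]) return(NULL)
  # collapse to a binary tree on extant tips
  build <- function(v, start_time) {
    ch <- children[[as.character(v)]] %||% integer(0)
    ch <- ch[has_extant[ch]]
    if (v %in% alive && length(ch) == 0L) {
      return(list(newick = sprintf("L%d:%.10f", v, t_end - start_time)))
    }
    if (length(ch) == 1L) return(build(ch, start_time))
    stopifnot(length(ch) == 2L)
    sub <- lapply(ch, function(c) build(c, t_death[v]))
    list(newick = sprintf("(%s,%s):%.10f", sub[[1]]$newick, sub[[2]]$newick,
                          t_death[v] - start_time))
  }
  root <- build(1L, 0)
  phy <- ape::read.tree(text = paste0(root$newick, ";"))
  if (is.null(phy) || length(phy$tip.label) != n) return(NULL)
  phy$tip.label <- paste0("t", seq_len(n))
  phy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate binary range evolution with implanted vicariance
#'
#' Evolves per-area presence independently along the branches of a dated tree
#' by a gain/loss (two-state) process, starting from `config$root_range`. At
#' each implanted vicariance node the parent's range is split into two
#' disjoint non-empty subsets, inherited by the two children, before branch
#' evolution resumes. Lineage ranges are kept non-empty along branches (a
#' loss that would empty a range is suppressed), so observed tip ranges are
#' always valid DIVA input; suppressed losses are counted in the returned
#' log.
#'
#' @param tree A `dated_tree`.
#' @param config A [sim_config()]; `implant_vicariance` entries may be clade
#'   keys or internal node numbers, and each implanted node's range must have
#'   at least 2 areas when reached (otherwise an error: a singleton cannot
#'   split).
#' @return A list: `tips` (tip-distribution tibble usable by the
#'   reconstruction functions), `truth` (tibble `clade`, `range` of true
#'   ancestral ranges), `events` (tibble `clade`, `event` of true
#'   cladogenetic events, `"vicariance"` at implanted nodes), and
#'   `n_suppressed_losses`.
#' @export
simulate_range_evolution <- function(tree, config) {
  stopifnot(inherits(tree, "dated_tree"), inherits(config, "sim_config"))
  alphabet <- config$alphabet
  k <- length(alphabet)
  gain <- rep(config$gain, length.out = k)
  loss <- rep(config$loss, length.out = k)
  set.seed(config$seed + 1L)
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  keys <- clade_set(tree)
  implant_nodes <- resolve_nodes(tree, config$implant_vicariance, keys)
  root <- n_tip + 1L
  range_at <- integer(n)
  range_at[root] <- range_mask(config$root_range, alphabet)
  split_at <- list()  # node -> list(left mask, right mask)
  suppressed <- 0L
  phy2 <- ape::reorder.phylo(tree, "cladewise")
  children <- split(phy2$edge[, 2], phy2$edge[, 1])
  edge_len <- numeric(n)
  for (i in seq_len(nrow(phy2$edge))) edge_len[phy2$edge[i, 2]] <- phy2$edge.length[i]
  # preorder: assign inherited masks at nodes, then evolve along branches
  for (v in unique(phy2$edge[, 1])) {
    R <- range_at[v]
    ch <- children[[as.character(v)]]
    if (v %in% implant_nodes) {
      areas <- which(bitwAnd(bitwShiftR(R, seq_len(k) - 1L), 1L) == 1L)
      if (length(areas) < 2) {
        stop("implanted vicariance at node with singleton range ",
             mask_range(R, alphabet), " (clade ", keys[as.character(v)],
             "): cannot split.", call. = FALSE)
      }
      n_left <- sample.int(length(areas) - 1L, 1)
      left_areas <- sample(areas, n_left)
      left <- sum(bitwShiftL(1L, left_areas - 1L))
      inherit <- c(as.integer(left), as.integer(R - left))
      split_at[[as.character(v)]] <- inherit
    } else {
      inherit <- c(R, R)
    }
    for (j in 1:2) {
      res <- evolve_branch(inherit[j], edge_len[ch[j]], gain, loss, k)
      range_at[ch[j]] <- res$mask
      suppressed <- suppressed + res$suppressed
    }
  }
  tips_tbl <- tibble::tibble(
    taxon = tree$tip.label,
    range = mask_range(range_at[seq_len(n_tip)], alphabet),
    mask = range_at[seq_len(n_tip)])
  attr(tips_tbl, "alphabet") <- alphabet
  truth <- tibble::tibble(clade = unname(keys[as.character(seq_len(n))]),
                          range = mask_range(range_at, alphabet))
  internal <- (n_tip + 1L):n
  events <- tibble::tibble(
    clade = unname(keys[as.character(internal)]),
    event = ifelse(internal %in% implant_nodes, "vicariance", "duplication"))
  list(tips = tips_tbl, truth = truth, events = events,
       n_suppressed_losses = suppressed)
}

resolve_nodes <- function(tree, spec, keys) {
  if (length(spec) == 0) return(integer(0))
  n_tip <- length(tree$tip.label)
  vapply(spec, function(s) {
    if (is.numeric(s)) return(as.integer(s))
    hit <- match(s, keys)
    if (is.na(hit)) stop("implant clade not found in tree: ", s, call. = FALSE)
    as.integer(names(keys)[hit])
  }, integer(1), USE.NAMES = FALSE)
}

# gain/loss evolution of one range bitmask over duration t (Gillespie);
# losses that would empty the range are suppressed and counted
evolve_branch <- function(mask, t, gain, loss, k) {
  now <- 0
  suppressed <- 0L
  repeat {
    bits <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    rates <- ifelse(bits == 1L, loss, gain)
    total <- sum(rates)
    if (total <= 0) break
    now <- now + stats::rexp(1, total)
    if (now > t) break
    a <- sample.int(k, 1, prob = rates)
    if (bits[a] == 1L) {
      if (sum(bits) == 1L) { suppressed <- suppressed + 1L; next }
      mask <- mask - bitwShiftL(1L, a - 1L)
    } else {
      mask <- mask + bitwShiftL(1L, a - 1L)
    }
  }
  list(mask = as.integer(mask), suppressed = suppressed)
}

#' Simulate pseudo-posterior node-age samples
#'
#' Emulates the structure of node-age posteriors from dating analyses with
#' increasing numbers of calibrations: for each internal node of true age `a`
#' and each analysis label, samples are drawn from a lognormal with mean `a`
#' and coefficient of variation equal to the label's noise scale, so interval
#' widths grow proportionally with node age and shrink from B1 to B3.
#'
#' @param tree A `dated_tree`.
#' @param config A [sim_config()].
#' @return A tibble with columns `label`, `clade`, `age` (one row per
#'   sample; `config$posterior_n` samples per node and label).
#' @export
simulate_age_posteriors <- function(tree, config) {
  stopifnot(inherits(tree, "dated_tree"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_tip <- length(tree$tip.label)
  keys <- clade_set(tree)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  ages <- tree$node_age[internal]
  m <- config$posterior_n
  purrr::imap(as.list(config$noise), function(cv, lab) {
    sdlog <- sqrt(log(1 + cv^2))
    purrr::map2(internal, ages, function(v, a) {
      draws <- if (cv == 0 || a == 0) rep(a, m) else
        stats::rlnorm(m, meanlog = log(a) - sdlog^2 / 2, sdlog = sdlog)
      tibble::tibble(label = lab, clade = unname(keys[as.character(v)]),
                     age = draws)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Perturb the node ages of a dated tree
#'
#' Produces a pseudo-replicate dating of the same topology: internal node
#' ages are redrawn top-down with logit-normal noise on each child/parent age
#' ratio (and lognormal noise on the root age), which preserves the topology,
#' ultrametricity and parent-older-than-child ordering. Used to emulate the
#' near-identical trees returned by dating analyses run under different
#' calibration sets.
#'
#' @param tree A `dated_tree`.
#' @param sd Noise scale on the log/logit age scale.
#' @param seed Integer seed.
#' @return A `dated_tree` with the same topology and perturbed ages.
#' @export
perturb_node_ages <- function(tree, sd = 0.1, seed) {
  stopifnot(inherits(tree, "dated_tree"))
  set.seed(as.integer(seed))
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  age <- tree$node_age
  new_age <- numeric(n)
  root <- n_tip + 1L
  new_age[root] <- age[root] * exp(stats::rnorm(1, 0, sd))
  phy2 <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[i, 1]; ch <- phy2$edge[i, 2]
    if (ch <= n_tip) { new_age[ch] <- 0; next }
    ratio <- age[ch] / age[p]
    ratio <- stats::plogis(stats::qlogis(ratio) + stats::rnorm(1, 0, sd))
    new_age[ch] <- ratio * new_age[p]
  }
  out <- tree
  for (i in seq_len(nrow(out$edge))) {
    out$edge.length[i] <- new_age[out$edge[i, 1]] - new_age[out$edge[i, 2]]
  }
  out$node_age <- new_age
  out
}

#' Internal nodes whose children are both tips
#'
#' Convenience for building implantation scenarios: cherries are safe hosts
#' for an implanted vicariant split because their subtrees are disjoint.
#'
#' @param tree A `dated_tree`.
#' @return Integer vector of internal node numbers.
#' @export
cherry_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  internal[vapply(as.character(internal), function(v) {
    all(children[[v]] <= n_tip)
  }, logical(1))]
}
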