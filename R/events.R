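#' Annotate cladogenetic events and route strings
#'
#' Classifies each internal node of a reconstruction by the event implied by
#' its modal ancestral range and the modal ranges of its children, and emits
#' the corresponding textual "route": `|` separates the two inherited subsets
#' of a vicariant split, `->` marks areas gained on a branch (dispersal) and
#' `^` marks a within-node range expansion. Modal ranges break ties toward
#' the lexicographically smallest bitmask, so annotation is deterministic.
#'
#' Events:
#' \describe{
#'   \item{vicariance}{the children's ranges are disjoint and their union is
#'     the parent range, e.g. `AB|A^B`.}
#'   \item{dispersal}{a child gains at least one area relative to the parent
#'     range, e.g. `A->B`.}
#'   \item{extinction}{a child loses areas and none are gained.}
#'   \item{duplication}{both children inherit the parent range unchanged.}
#' }
#'
#' @param recon An `ancestral_recon`.
#' @param tree The `dated_tree` the reconstruction was computed on.
#' @return The reconstruction with `events` (tibble `clade`, `event`) and
#'   `routes` (tibble `clade`, `route`) filled in.
#' @export
annotate_events <- function(recon, tree = recon$tree) {
  stopifnot(inherits(recon, "ancestral_recon"))
  alphabet <- recon$alphabet
  keys <- clade_set(tree)
  modal <- modal_masks(recon)
  n_tip <- length(tree$tip.label)
  phy2 <- ape::reorder.phylo(tree, "postorder")
  children <- split(phy2$edge[, 2], phy2$edge[, 1])
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  rows <- purrr::map(internal, function(v) {
    key <- unname(keys[as.character(v)])
    R <- modal[[key]]
    ch <- children[[as.character(v)]]
    cm <- vapply(ch, function(c) modal[[unname(keys[as.character(c)])]], integer(1))
    disjoint <- bitwAnd(cm[1], cm[2]) == 0L
    covers <- bitwOr(cm[1], cm[2]) == R
    if (disjoint && covers && cm[1] != 0L && cm[2] != 0L && mask_size(R) >= 2) {
      lr <- sort(cm)  # deterministic order: smaller mask first
      return(tibble::tibble(
        clade = key, event = "vicariance",
        route = paste0(mask_range(R, alphabet), "|",
                       mask_range(lr[1], alphabet), "^",
                       mask_range(lr[2], alphabet))))
    }
    gains <- vapply(cm, function(c) bitwAnd(c, bitwNot(R)), integer(1))
    losses <- vapply(cm, function(c) bitwAnd(R, bitwNot(c)), integer(1))
    route <- mask_range(R, alphabet)
    for (g in gains[gains != 0L]) route <- paste0(route, "->", mask_range(g, alphabet))
    event <- if (any(gains != 0L)) "dispersal"
             else if (any(losses != 0L)) "extinction"
             else "duplication"
    tibble::tibble(clade = key, event = event, route = route)
  })
  ann <- dplyr::bind_rows(rows)
  recon$events <- dplyr::select(ann, "clade", "event")
  recon$routes <- dplyr::select(ann, "clade", "route")
  recon
}

# modal range per clade: highest weight, ties to the smallest bitmask
modal_masks <- function(recon) {
  rr <- recon$ranges
  if (!"mask" %in% names(rr)) {
    rr$mask <- vapply(rr$range, range_mask, integer(1), alphabet = recon$alphabet)
  }
  split_rr <- split(rr, rr$clade)
  out <- lapply(split_rr, function(df) {
    df <- df[order(-df$weight, df$mask), ]
    as.integer(df$mask[1])
  })
  out
}

#' Parse and serialize route strings
#'
#' The route grammar is
#' `<parent-range> ( "|" <left> "^" <right> | "->" <gained> | "^" <gained> )*`
#' with ranges written as concatenated area letters. [parse_route()] and
#' [serialize_route()] are exact inverses on any route the package emits.
#'
#' @param text A route string, e.g. `"AB|A^B"` or `"A->B"`.
#' @return For `parse_route()`, a list with `parent` (range string) and
#'   `tokens`, a list of lists with `type` one of `"vicariance"`,
#'   `"dispersal"`, `"expansion"` and the associated range strings.
#' @examples
#' parse_route("AB|A^B")
#' serialize_route(parse_route("A->B"))
#' @export
parse_route <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regexpr("^[A-Za-z]+", text)
  if (m == -1) stop("route must start with a range: ", text, call. = FALSE)
  parent <- regmatches(text, m)
  rest <- substring(text, attr(m, "match.length") + 1L)
  tokens <- list()
  while (nzchar(rest)) {
    if (startsWith(rest, "|")) {
      mm <- regexec("^\\|([A-Za-z]+)\\^([A-Za-z]+)", rest)[[1]]
      if (mm[1] == -1) stop("malformed vicariance token in route: ", text, call. = FALSE)
      parts <- regmatches(rest, regexec("^\\|([A-Za-z]+)\\^([A-Za-z]+)", rest))[[1]]
      tokens[[length(tokens) + 1L]] <-
        list(type = "vicariance", left = parts[2], right = parts[3])
      rest <- substring(rest, nchar(parts[1]) + 1L)
    } else if (startsWith(rest, "->")) {
      parts <- regmatches(rest, regexec("^->([A-Za-z]+)", rest))[[1]]
      if (length(parts) == 0) stop("malformed dispersal token in route: ", text, call. = FALSE)
      tokens[[length(tokens) + 1L]] <- list(type = "dispersal", gained = parts[2])
      rest <- substring(rest, nchar(parts[1]) + 1L)
    } else if (startsWith(rest, "^")) {
      parts <- regmatches(rest, regexec("^\\^([A-Za-z]+)", rest))[[1]]
      if (length(parts) == 0) stop("malformed expansion token in route: ", text, call. = FALSE)
      tokens[[length(tokens) + 1L]] <- list(type = "expansion", gained = parts[2])
      rest <- substring(rest, nchar(parts[1]) + 1L)
    } else {
      stop("unparseable route suffix '", rest, "' in: ", text, call. = FALSE)
    }
  }
  list(parent = parent, tokens = tokens)
}

#' @rdname parse_route
#' @param route A parsed route as returned by [parse_route()].
#' @export
serialize_route <- function(route) {
  out <- route$parent
  for (tok in route$tokens) {
    out <- switch(tok$type,
      vicariance = paste0(out, "|", tok$left, "^", tok$right),
      dispersal = paste0(out, "->", tok$gained),
      expansion = paste0(out, "^", tok$gained),
      stop("unknown token type: ", tok$type, call. = FALSE))
  }
  out
}
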