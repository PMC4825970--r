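#' Area alphabets and range sets
#'
#' Geographic ranges are subsets of a fixed, ordered alphabet of area codes
#' (by default the twelve Neotropical/Nearctic units A-L used for Triatominae:
#' Mexican Transition Zone through North America). Internally a range is a
#' bitmask integer over the alphabet; user-facing functions accept and return
#' concatenated letter strings such as `"AB"`.
#'
#' @param codes Character vector of unique single-character area codes.
#' @return For `area_alphabet()`, a character vector of class `area_alphabet`.
#' @examples
#' ab <- area_alphabet(c("A", "B", "C"))
#' range_mask("AC", ab)
#' mask_range(5L, ab)
#' @export
area_alphabet <- function(codes = LETTERS[1:12]) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("area codes must be unique.", call. = FALSE)
  if (any(nchar(codes) != 1)) stop("area codes must be single characters.", call. = FALSE)
  if (length(codes) > 12) stop("at most 12 areas are supported.", call. = FALSE)
  structure(codes, class = "area_alphabet")
}

#' @rdname area_alphabet
#' @param range A range as a string of area letters (e.g. `"AB"`), a character
#'   vector of letters, or an integer bitmask (returned unchanged).
#' @param alphabet An [area_alphabet()].
#' @export
range_mask <- function(range, alphabet) {
  if (is.numeric(range)) return(as.integer(range))
  letters_ <- if (length(range) == 1) strsplit(range, "")[[1]] else as.character(range)
  idx <- match(letters_, alphabet)
  if (anyNA(idx)) {
    stop("unknown area code(s): ", paste(letters_[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  as.integer(sum(bitwShiftL(1L, unique(idx) - 1L)))
}

#' @rdname area_alphabet
#' @param mask Integer bitmask.
#' @export
mask_range <- function(mask, alphabet) {
  vapply(as.integer(mask), function(m) {
    paste(alphabet[bitwAnd(bitwShiftR(m, seq_along(alphabet) - 1L), 1L) == 1L],
          collapse = "")
  }, character(1))
}

mask_size <- function(mask) {
  vapply(as.integer(mask), function(m) sum(bitwAnd(bitwShiftR(m, 0:11), 1L)), integer(1))
}

#' Read a taxon-by-area presence/absence matrix
#'
#' The distribution matrix is tab-separated: first column the taxon label,
#' then one 0/1 column per area, with a header row giving the area codes.
#'
#' @param x Path to the matrix file, or a data frame in the same layout.
#' @param alphabet Optional [area_alphabet()]; defaults to the codes found in
#'   the header.
#' @return A tibble with columns `taxon`, `range` (letter string) and `mask`
#'   (integer bitmask), with the alphabet attached as attribute `alphabet`.
#' @export
read_tip_distribution <- function(x, alphabet = NULL) {
  df <- if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    readr::read_tsv(x, col_types = readr::cols(), progress = FALSE)
  }
  if (ncol(df) < 2) stop("distribution matrix needs a taxon column plus area columns.",
                         call. = FALSE)
  codes <- colnames(df)[-1]
  if (is.null(alphabet)) alphabet <- area_alphabet(codes)
  if (!setequal(codes, alphabet)) {
    stop("matrix columns do not match the area alphabet.", call. = FALSE)
  }
  pres <- as.matrix(df[, as.character(alphabet), drop = FALSE])
  if (!all(pres %in% c(0, 1))) stop("presence matrix entries must be 0 or 1.", call. = FALSE)
  taxon <- as.character(df[[1]])
  if (anyDuplicated(taxon)) stop("duplicate taxa in distribution matrix.", call. = FALSE)
  masks <- as.integer(pres %*% bitwShiftL(1L, seq_along(alphabet) - 1L))
  if (any(masks == 0L)) {
    stop("taxa with empty ranges: ",
         paste(taxon[masks == 0L], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(taxon = taxon,
                        range = mask_range(masks, alphabet),
                        mask = masks)
  attr(out, "alphabet") <- alphabet
  out
}

#' @rdname read_tip_distribution
#' @param tips A tip-distribution tibble.
#' @param file Output path.
#' @export
write_tip_distribution <- function(tips, file) {
  alphabet <- attr(tips, "alphabet")
  stopifnot(!is.null(alphabet))
  pres <- t(vapply(tips$mask, function(m) {
    as.integer(bitwAnd(bitwShiftR(m, seq_along(alphabet) - 1L), 1L))
  }, integer(length(alphabet))))
  df <- tibble::as_tibble(as.data.frame(pres))
  colnames(df) <- as.character(alphabet)
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(taxon = tips$taxon), df), file,
                   progress = FALSE)
  invisible(file)
}

# tip masks aligned to a tree's tip order; errors if coverage is not exact
tip_masks_for_tree <- function(tree, tips) {
  missing <- setdiff(tree$tip.label, tips$taxon)
  extra <- setdiff(tips$taxon, tree$tip.label)
  if (length(missing) > 0) {
    stop("tip distribution missing taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra) > 0) {
    stop("tip distribution has taxa absent from tree: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  tips$mask[match(tree$tip.label, tips$taxon)]
}
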