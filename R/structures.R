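# Secondary structures as sets of non-crossing base pairs.

#' Create a secondary structure
#'
#' A secondary structure is a set of non-crossing base pairs `(i, j)`, `i < j`,
#' over `1..length` (alignment columns or sequence positions, 1-based).
#'
#' @param length Number of positions (columns) the structure covers.
#' @param pairs Two-column integer matrix of base pairs (one row per pair),
#'   or `NULL`/zero-row matrix for the open chain.
#' @param validate If `TRUE` (default) enforce the structural invariants:
#'   unique positions, non-crossing pairs, and hairpin loops of at least
#'   3 unpaired bases. Refolding-path intermediates are built with the same
#'   checks; projections of consensus structures onto gapped rows use
#'   `validate = FALSE` because removing gap columns can shrink loops.
#' @return An object of class `rna_structure` with elements `length` and
#'   `pairs` (sorted by opening position).
#' @export
rna_structure <- function(length, pairs = NULL, validate = TRUE) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L)
    stop("structure length must be a non-negative integer")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
  }
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs)) {
    if (any(pairs[, 1L] >= pairs[, 2L]))
      stop("base pairs must satisfy i < j")
    if (any(pairs < 1L) || any(pairs > length))
      stop("base pair outside 1..length")
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    if (validate) {
      pos <- c(pairs[, 1L], pairs[, 2L])
      if (anyDuplicated(pos))
        stop("a position occurs in more than one base pair")
      if (nrow(pairs) > 1L) {
        for (a in seq_len(nrow(pairs) - 1L)) {
          i <- pairs[a, 1L]; j <- pairs[a, 2L]
          b <- (a + 1L):nrow(pairs)
          k <- pairs[b, 1L]; l <- pairs[b, 2L]
          # sorted by i, so i < k; crossing iff i < k < j < l
          if (any(k < j & l > j))
            stop("crossing base pairs (pseudoknots are not supported)")
        }
      }
      hp <- hairpin_sizes(pairs)
      if (any(hp < 3L))
        stop("hairpin loop with fewer than 3 unpaired bases")
    }
  }
  structure(list(length = length, pairs = pairs), class = "rna_structure")
}

# unpaired span inside each innermost (child-less) pair
hairpin_sizes <- function(pairs) {
  if (!nrow(pairs)) return(integer(0))
  out <- integer(0)
  for (a in seq_len(nrow(pairs))) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    inside <- pairs[, 1L] > i & pairs[, 2L] < j
    if (!any(inside)) out <- c(out, j - i - 1L)
  }
  out
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(write_dotbracket(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) write_dotbracket(x)

#' Parse a dot-bracket string
#'
#' @param text A string over `(`, `)` and `.`.
#' @param validate Enforce the hairpin-size invariant (default `TRUE`).
#' @return An [rna_structure()].
#' @examples
#' parse_dotbracket("((...))")$pairs
#' @export
parse_dotbracket <- function(text, validate = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad))
    stop("invalid dot-bracket character(s): ", paste(bad, collapse = " "))
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      open <- c(open, p)
    } else if (chars[p] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket: unmatched ')' at ", p)
      i <- open[length(open)]
      open <- open[-length(open)]
      pairs <- rbind(pairs, c(i, p))
    }
  }
  if (length(open))
    stop("unbalanced dot-bracket: unmatched '(' at ", open[1])
  rna_structure(length(chars), pairs, validate = validate)
}

#' Write a structure as a dot-bracket string
#'
#' Inverse of [parse_dotbracket()]: `parse_dotbracket(write_dotbracket(s))`
#' recovers `s` for every valid structure.
#'
#' @param s An [rna_structure()].
#' @return A dot-bracket string.
#' @export
write_dotbracket <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  chars <- rep(".", s$length)
  chars[s$pairs[, 1L]] <- "("
  chars[s$pairs[, 2L]] <- ")"
  paste(chars, collapse = "")
}

# canonical key for pair sets (used for dedup / tie-breaking)
pairs_key <- function(pairs) {
  if (!nrow(pairs)) return("open")
  paste(pairs[, 1L], pairs[, 2L], sep = ":", collapse = ",")
}

# number of base pairs two structures differ by
bp_distance <- function(a, b) {
  ka <- paste(a$pairs[, 1L], a$pairs[, 2L])
  kb <- paste(b$pairs[, 1L], b$pairs[, 2L])
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
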