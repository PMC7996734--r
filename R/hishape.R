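# Position-aware structure abstraction: helices, helix indices, hishapes.

#' Decompose a structure into helices
#'
#' A helix is a maximal run of directly stacked base pairs (an interruption
#' by any loop starts a new helix; stacking loops only elongate helices and
#' are not counted as a loop type). Each helix is labeled by the loop type on
#' its inner side: hairpin, bulge, internal or multiloop.
#'
#' @param s An [rna_structure()].
#' @return A list of helices, each a list with `outer` (p, q), `inner` (i, j),
#'   `length` (number of stacked pairs), `type`
#'   (`"hairpin"`, `"bulge"`, `"internal"`, `"multiloop"`) and, for
#'   multiloop-closing helices, `branches` (number of direct branches of the
#'   closed multiloop).
#' @export
decompose_helices <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  pairs <- s$pairs
  if (!nrow(pairs)) return(list())
  key <- paste(pairs[, 1L], pairs[, 2L])
  has_pair <- function(i, j) paste(i, j) %in% key
  tree <- loop_tree(pairs)
  helices <- list()
  for (a in seq_len(nrow(pairs))) {
    i <- unname(pairs[a, 1L]); j <- unname(pairs[a, 2L])
    # helix start: no pair stacked directly outside
    if (has_pair(i - 1L, j + 1L)) next
    k <- 1L
    while (has_pair(i + k, j - k)) k <- k + 1L
    inner <- c(i + k - 1L, j - k + 1L)
    b <- which(pairs[, 1L] == inner[1] & pairs[, 2L] == inner[2])
    kids <- tree$children[[b]]
    if (!length(kids)) {
      type <- "hairpin"; branches <- NULL
    } else if (length(kids) == 1L) {
      ki <- pairs[kids, 1L]; kj <- pairs[kids, 2L]
      type <- if (ki == inner[1] + 1L || kj == inner[2] - 1L) "bulge" else "internal"
      branches <- NULL
    } else {
      type <- "multiloop"; branches <- length(kids)
    }
    helices[[length(helices) + 1L]] <-
      list(outer = c(i, j), inner = inner, length = k, type = type,
           branches = branches)
  }
  # 5' -> 3' by opening position
  helices[order(vapply(helices, function(h) h$outer[1], numeric(1)))]
}

#' Helix index of a helix
#'
#' The position of a helix is the central position of its innermost base pair
#' `(i, j)`, i.e. `(i + j) / 2` (a half-integer when `i + j` is odd). Helices
#' closing a multiloop, bulge or internal loop are marked `m`, `b` or `i`;
#' hairpin helices carry no marker.
#'
#' @param h A helix from [decompose_helices()].
#' @return A list with `value` (numeric, multiple of 0.5) and `marker`
#'   (`""`, `"m"`, `"b"` or `"i"`).
#' @export
helix_index <- function(h) {
  marker <- switch(h$type, hairpin = "", multiloop = "m", bulge = "b",
                   internal = "i")
  list(value = (h$inner[1] + h$inner[2]) / 2, marker = marker)
}

#' Map a structure to its helix-index shape (hishape)
#'
#' A hishape is the ordered list of helix indices a structure retains at a
#' given abstraction level:
#' \describe{
#'   \item{`"h"`}{hairpin helices only;}
#'   \item{`"h+"`}{hairpin helices plus multiloop-closing helices whose
#'     multiloop has at least `hplus_min_branches` direct branches (marked
#'     `m`), tracking the nesting within multiloops;}
#'   \item{`"m"`}{hairpin plus all multiloop-closing helices (marked `m`);}
#'   \item{`"a"`}{all helices, with markers `m`/`b`/`i` on non-hairpin ones.}
#' }
#' Indices are ordered 5' to 3' by helix opening position. The open chain maps
#' to the distinguished empty hishape, rendered `"[_]"`.
#'
#' @param s An [rna_structure()].
#' @param level Abstraction level, one of `"h"`, `"h+"`, `"m"`, `"a"`.
#' @param hplus_min_branches Minimum number of direct multiloop branches for a
#'   multiloop helix to be retained at level `"h+"`. At the default 2 every
#'   multiloop qualifies and `"h+"` coincides with `"m"`; raising it restricts
#'   `"h+"` to higher-order junctions.
#' @return An object of class `hishape` with `indices`, `markers` and `level`.
#' @examples
#' format(abstract_hishape(parse_dotbracket("(((...)))"), "h"))  # "[5]"
#' @export
abstract_hishape <- function(s, level = c("h", "h+", "m", "a"),
                             hplus_min_branches = 2L) {
  level <- match.arg(level)
  helices <- decompose_helices(s)
  keep <- vapply(helices, function(h) {
    switch(h$type,
           hairpin = TRUE,
           multiloop = switch(level,
                              a = TRUE, m = TRUE,
                              `h+` = h$branches >= hplus_min_branches,
                              h = FALSE),
           level == "a")
  }, logical(1))
  helices <- helices[keep]
  idx <- lapply(helices, helix_index)
  structure(list(indices = vapply(idx, `[[`, numeric(1), "value"),
                 markers = vapply(idx, `[[`, character(1), "marker"),
                 level = level),
            class = "hishape")
}

#' Render a hishape as text
#'
#' Comma-separated helix indices in square brackets; half-integers with one
#' decimal, markers suffixed (e.g. `"[12.5m,8,17]"`); the open chain is
#' `"[_]"`.
#'
#' @param x A `hishape`.
#' @param ... Unused.
#' @return A string.
#' @export
format.hishape <- function(x, ...) {
  if (!length(x$indices)) return("[_]")
  num <- ifelse(x$indices == round(x$indices),
                sprintf("%d", as.integer(round(x$indices))),
                sprintf("%.1f", x$indices))
  paste0("[", paste0(num, x$markers, collapse = ","), "]")
}

#' @export
print.hishape <- function(x, ...) {
  cat(format(x), " (level ", x$level, ")\n", sep = "")
  invisible(x)
}

#' @export
`==.hishape` <- function(e1, e2) {
  identical(format(e1), format(e2)) && identical(e1$level, e2$level)
}

#' Project a hishape from alignment columns to sequence positions
#'
#' Helix indices computed on alignment columns are shifted relative to the
#' individual sequences whenever the alignment introduced gaps. This
#' recomputes each retained helix index as `(pos(i) + pos(j)) / 2` using one
#' row's coordinate map.
#'
#' @param hs A `hishape` computed from `s` in alignment coordinates.
#' @param s The [rna_structure()] (over alignment columns) `hs` was derived
#'   from.
#' @param cmap A [coordinate_map()] for the target row.
#' @return A `hishape` in the row's sequence coordinates.
#' @export
project_hishape <- function(hs, s, cmap) {
  stopifnot(inherits(hs, "hishape"), inherits(s, "rna_structure"),
            inherits(cmap, "coordinate_map"))
  helices <- decompose_helices(s)
  idx <- lapply(helices, helix_index)
  full <- vapply(idx, `[[`, numeric(1), "value")
  marks <- vapply(idx, `[[`, character(1), "marker")
  keep <- match(paste0(hs$indices, hs$markers), paste0(full, marks))
  if (anyNA(keep))
    stop("hishape does not match the supplied structure")
  new_idx <- numeric(length(keep))
  for (t in seq_along(keep)) {
    h <- helices[[keep[t]]]
    pi_ <- cmap$col_to_pos[h$inner[1]]
    pj <- cmap$col_to_pos[h$inner[2]]
    if (is.na(pi_) || is.na(pj))
      stop("projection error: innermost pair of helix at index ",
           hs$indices[t], " touches a gap column in row ", cmap$row)
    new_idx[t] <- (pi_ + pj) / 2
  }
  structure(list(indices = new_idx, markers = hs$markers, level = hs$level),
            class = "hishape")
}
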