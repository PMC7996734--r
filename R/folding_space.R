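# Consensus folding-space enumeration and k-best hishape classes.

#' Folding-space configuration
#'
#' @param k Number of hishape classes requested.
#' @param level Abstraction level (see [abstract_hishape()]).
#' @param bp_threshold Minimum [pair_fraction()] for a candidate column pair
#'   (default 0.5).
#' @param x_filter Optional maximum pseudo free energy (kcal/mol) allowed for
#'   a substructure inserted in the external loop; structures with an
#'   external-loop component strictly above this value are excluded
#'   (see [apply_x_filter()]). `NULL` disables the filter.
#' @param energy_band Optional maximum pseudo energy above the constrained
#'   minimum; structures above the band are dropped before classification.
#'   `NULL` keeps everything.
#' @param min_helix_length Minimum helix length of candidate structures
#'   (canonical grammar, default 2: no lonely pairs).
#' @param min_hairpin_unpaired Minimum unpaired bases in a hairpin loop
#'   (default 3).
#' @param max_structures Guard on the enumeration size.
#' @return A list of class `folding_space_config`.
#' @export
folding_space_config <- function(k = 10L, level = "h", bp_threshold = 0.5,
                                 x_filter = NULL, energy_band = NULL,
                                 min_helix_length = 2L,
                                 min_hairpin_unpaired = 3L,
                                 max_structures = 2e5) {
  stopifnot(k >= 1L, bp_threshold >= 0, bp_threshold <= 1,
            min_helix_length >= 1L, min_hairpin_unpaired >= 0L)
  level <- match.arg(level, c("h", "h+", "m", "a"))
  structure(list(k = as.integer(k), level = level,
                 bp_threshold = bp_threshold, x_filter = x_filter,
                 energy_band = energy_band,
                 min_helix_length = as.integer(min_helix_length),
                 min_hairpin_unpaired = as.integer(min_hairpin_unpaired),
                 max_structures = max_structures),
            class = "folding_space_config")
}

# Logical L x L matrix of column pairs passing the base-pairing filter and
# the minimum hairpin span.
allowed_pairs <- function(aln, cfg) {
  L <- aln$L
  ok <- matrix(FALSE, L, L)
  span <- cfg$min_hairpin_unpaired + 1L
  if (L > span) {
    for (i in seq_len(L - span)) {
      for (j in (i + span):L) {
        if (pair_fraction(aln, i, j) >= cfg$bp_threshold) ok[i, j] <- TRUE
      }
    }
  }
  ok
}

# Grammar-style enumeration of canonical structures on a region: a structure
# is a sequence of components; each component is a maximal helix (length >=
# min_helix_length) with an arbitrary canonical interior that does not stack
# directly onto the helix (maximality => non-ambiguity: every structure is
# produced exactly once).
enumerate_pair_sets <- function(ok, min_helix_length, max_structures) {
  L <- nrow(ok)
  memo <- new.env(parent = emptyenv())
  count <- 0L
  bump <- function(n) {
    count <<- count + n
    if (count > max_structures)
      stop("folding space larger than max_structures = ", max_structures)
  }
  empty <- matrix(integer(0), ncol = 2L)

  helix_structs <- function(p, q) {
    out <- list()
    kmax <- 0L
    while (p + kmax < q - kmax && ok[p + kmax, q - kmax]) kmax <- kmax + 1L
    if (kmax < min_helix_length) return(out)
    for (k in min_helix_length:kmax) {
      hp <- cbind(p + 0:(k - 1L), q - 0:(k - 1L))
      lo <- p + k; hi <- q - k
      interior <- if (lo <= hi) gen_region(lo, hi) else list(empty)
      for (s in interior) {
        if (nrow(s) && any(s[, 1L] == lo & s[, 2L] == hi)) next  # not maximal
        out[[length(out) + 1L]] <- rbind(hp, s)
      }
    }
    out
  }

  gen_region <- function(lo, hi) {
    key <- paste0(lo, "_", hi)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- list(empty)
    if (hi - lo >= 4L) {
      for (p in lo:(hi - 4L)) {
        qs <- which(ok[p, ])
        qs <- qs[qs <= hi]
        for (q in qs) {
          hs <- helix_structs(p, q)
          if (!length(hs)) next
          rest <- if (q < hi) gen_region(q + 1L, hi) else list(empty)
          for (h in hs) for (r in rest) {
            res[[length(res) + 1L]] <- rbind(h, r)
          }
        }
      }
    }
    bump(length(res))
    memo[[key]] <- res
    res
  }

  if (L >= 1L) gen_region(1L, L) else list(empty)
}

#' Enumerate the consensus folding space of an alignment
#'
#' Yields every secondary structure over alignment columns that is
#' non-crossing, has hairpin loops with at least `min_hairpin_unpaired`
#' unpaired columns, helices of at least `min_helix_length` stacked pairs,
#' and whose every pair passes the base-pairing filter — together with its
#' consensus pseudo free energy. Each structure appears exactly once; the
#' open chain is always included.
#'
#' @param aln An [rna_alignment()].
#' @param cfg A [folding_space_config()].
#' @param backend Energy backend.
#' @param params [covariance_params()].
#' @return A list with `structures` (list of [rna_structure()]), `energies`
#'   (numeric vector of pseudo energies) and `pseudo` (list of full
#'   `pseudo_energy` objects).
#' @export
enumerate_structures <- function(aln, cfg = folding_space_config(),
                                 backend = toy_backend(),
                                 params = covariance_params()) {
  stopifnot(inherits(aln, "rna_alignment"))
  ok <- allowed_pairs(aln, cfg)
  sets <- enumerate_pair_sets(ok, cfg$min_helix_length, cfg$max_structures)
  structures <- lapply(sets, function(p) rna_structure(aln$L, p, validate = FALSE))
  ctx <- energy_context(aln, backend, params)
  pseudo <- lapply(structures, ctx$evaluate)
  energies <- vapply(pseudo, `[[`, numeric(1), "total")
  if (!is.null(cfg$x_filter)) {
    keep <- vapply(structures, function(s)
      passes_x_filter(s, cfg$x_filter, ctx), logical(1))
    structures <- structures[keep]; pseudo <- pseudo[keep]
    energies <- energies[keep]
  }
  if (!is.null(cfg$energy_band)) {
    keep <- energies <= min(energies) + cfg$energy_band
    structures <- structures[keep]; pseudo <- pseudo[keep]
    energies <- energies[keep]
  }
  list(structures = structures, energies = energies, pseudo = pseudo)
}

# TRUE if every external-loop component of s has pseudo energy <= e.
passes_x_filter <- function(s, e, ctx) {
  if (!nrow(s$pairs)) return(TRUE)  # the open chain has no components
  tree <- loop_tree(s$pairs)
  for (a in tree$top) {
    p <- s$pairs[a, 1L]; q <- s$pairs[a, 2L]
    comp <- s$pairs[s$pairs[, 1L] >= p & s$pairs[, 2L] <= q, , drop = FALSE]
    cs <- rna_structure(s$length, comp, validate = FALSE)
    if (ctx$total(cs) > e) return(FALSE)
  }
  TRUE
}

#' Filter structures by external-loop component pseudo energy
#'
#' A substructure in the external loop with high (in particular non-negative)
#' pseudo free energy is unlikely to form; this filter removes structures
#' containing an external-loop component (a maximal substructure whose
#' outermost helix sits in the external loop) with pseudo energy strictly
#' greater than `e`. The open chain is always retained.
#'
#' @param aln An [rna_alignment()].
#' @param structures List of [rna_structure()] over alignment columns.
#' @param e Maximum component pseudo energy (kcal/mol), e.g. 0.
#' @param backend Energy backend.
#' @param params [covariance_params()].
#' @return Logical vector: which structures pass.
#' @export
apply_x_filter <- function(aln, structures, e, backend = toy_backend(),
                           params = covariance_params()) {
  ctx <- energy_context(aln, backend, params)
  vapply(structures, function(s) passes_x_filter(s, e, ctx), logical(1))
}

#' k best hishape classes of the consensus folding space
#'
#' Partitions the constrained folding space into hishape classes at the
#' configured abstraction level and returns the `k` classes with the lowest
#' class-minimum pseudo free energies, each with its minimum-energy
#' representative (the hishrep). Ties between classes are broken by
#' lexicographic hishape text; ties within a class by lexicographic
#' dot-bracket, so output is deterministic.
#'
#' @inheritParams enumerate_structures
#' @return A data frame of class `hishape_classes` with columns `rank`,
#'   `hishape`, `energy`, `mean_energy`, `covariance_term` and `hishrep`
#'   (dot-bracket). Attribute `"structures"` holds the representative
#'   [rna_structure()] objects, attribute `"level"` the abstraction level.
#'   Fewer than `k` rows are returned iff the space has fewer classes.
#' @export
kbest_hishapes <- function(aln, cfg = folding_space_config(),
                           backend = toy_backend(),
                           params = covariance_params()) {
  enum <- enumerate_structures(aln, cfg, backend, params)
  classify_kbest(enum, cfg, k = cfg$k)
}

# shared classification: enumeration result -> ranked class table
classify_kbest <- function(enum, cfg, k) {
  labels <- vapply(enum$structures, function(s)
    format(abstract_hishape(s, cfg$level)), character(1))
  dbs <- vapply(enum$structures, write_dotbracket, character(1))
  cls <- split(seq_along(labels), labels)
  rows <- lapply(names(cls), function(lab) {
    idx <- cls[[lab]]
    e <- enum$energies[idx]
    best <- idx[order(e, dbs[idx])][1]
    list(hishape = lab, energy = enum$energies[best],
         mean_energy = enum$pseudo[[best]]$mean_energy,
         covariance_term = enum$pseudo[[best]]$covariance_term,
         hishrep = dbs[best], structure = enum$structures[[best]])
  })
  if (!length(rows)) {
    out <- data.frame(rank = integer(0), hishape = character(0),
                      energy = numeric(0), mean_energy = numeric(0),
                      covariance_term = numeric(0), hishrep = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "structures") <- list()
    attr(out, "level") <- cfg$level
    class(out) <- c("hishape_classes", class(out))
    return(out)
  }
  e <- vapply(rows, `[[`, numeric(1), "energy")
  h <- vapply(rows, `[[`, character(1), "hishape")
  ord <- order(e, h)
  ord <- utils::head(ord, k)
  out <- data.frame(
    rank = seq_along(ord),
    hishape = h[ord],
    energy = e[ord],
    mean_energy = vapply(rows, `[[`, numeric(1), "mean_energy")[ord],
    covariance_term = vapply(rows, `[[`, numeric(1), "covariance_term")[ord],
    hishrep = vapply(rows, `[[`, character(1), "hishrep")[ord],
    stringsAsFactors = FALSE)
  attr(out, "structures") <- lapply(rows[ord], `[[`, "structure")
  attr(out, "level") <- cfg$level
  class(out) <- c("hishape_classes", class(out))
  out
}

#' @export
print.hishape_classes <- function(x, ...) {
  cat("k-best hishape classes (level ", attr(x, "level"), ")\n", sep = "")
  for (r in seq_len(nrow(x))) {
    cat(sprintf("%3d  %-20s %8.2f  %s\n", x$rank[r], x$hishape[r],
                x$energy[r], x$hishrep[r]))
  }
  invisible(x)
}
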