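# Synthetic alignments with controlled covariation, and exact brute-force
# oracles for validating the enumeration and pathway heuristics.

#' Specification for a synthetic alignment
#'
#' Describes a family of homologous sequences evolved from a reference around
#' a conserved ("planted") structure: paired positions undergo joint
#' compensatory replacement (the covariation signal the conservation score
#' rewards), unpaired positions mutate independently, and gaps follow one of
#' two policies.
#'
#' @param reference Ungapped reference sequence (ACGU).
#' @param planted An [rna_structure()] on the reference: the conserved
#'   structure.
#' @param n_rows Number of alignment rows.
#' @param comp_rate Probability that a planted pair in a row is jointly
#'   replaced by a uniformly chosen different member of
#'   `{AU, UA, GC, CG, GU, UG}`.
#' @param mut_rate Per-position substitution probability at unpaired
#'   positions.
#' @param gap_rate Per-position gap probability (see `gap_policy`).
#' @param gap_policy `"terminal"` (default): gaps only in the unpaired flanks
#'   outside the planted pairs, keeping planted pair columns intact;
#'   `"interior"`: extra columns are inserted at random points, each row
#'   independently receiving a random base or a gap (shifts coordinates, for
#'   projection tests).
#' @param seed Integer seed; generation is reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(reference, planted, n_rows = 8L, comp_rate = 0.5,
                           mut_rate = 0.05, gap_rate = 0,
                           gap_policy = c("terminal", "interior"),
                           seed = 1L) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(planted, "rna_structure"),
            nchar(reference) == planted$length,
            comp_rate >= 0, comp_rate <= 1, mut_rate >= 0, mut_rate <= 1,
            gap_rate >= 0, gap_rate <= 1, n_rows >= 1)
  structure(list(reference = toupper(gsub("T", "U", reference, fixed = TRUE)),
                 planted = planted, n_rows = as.integer(n_rows),
                 comp_rate = comp_rate, mut_rate = mut_rate,
                 gap_rate = gap_rate, gap_policy = gap_policy,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic alignment with planted covariation
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `aln` (an [rna_alignment()]) and `truth` (list:
#'   `pair_cols` — alignment columns of the planted pairs, `structure` — the
#'   planted structure in alignment columns, `hishape` — its level-h hishape
#'   text).
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "U")
  ref <- strsplit(spec$reference, "", fixed = TRUE)[[1]]
  n <- length(ref)
  pairs <- spec$planted$pairs
  paired_pos <- if (nrow(pairs)) c(pairs[, 1L], pairs[, 2L]) else integer(0)
  unpaired <- setdiff(seq_len(n), paired_pos)
  rows <- matrix(rep(ref, spec$n_rows), nrow = spec$n_rows, byrow = TRUE)
  for (k in seq_len(spec$n_rows)) {
    if (nrow(pairs)) {
      for (a in seq_len(nrow(pairs))) {
        if (stats::runif(1) < spec$comp_rate) {
          cur <- paste0(rows[k, pairs[a, 1L]], rows[k, pairs[a, 2L]])
          alt <- setdiff(BP_SET, cur)
          pick <- alt[sample.int(length(alt), 1L)]
          rows[k, pairs[a, 1L]] <- substr(pick, 1, 1)
          rows[k, pairs[a, 2L]] <- substr(pick, 2, 2)
        }
      }
    }
    for (p in unpaired) {
      if (stats::runif(1) < spec$mut_rate) {
        alt <- setdiff(bases, rows[k, p])
        rows[k, p] <- alt[sample.int(3L, 1L)]
      }
    }
  }
  pair_cols <- pairs
  if (spec$gap_rate > 0 && spec$gap_policy == "terminal") {
    lo <- if (nrow(pairs)) min(pairs) - 1L else n
    hi <- if (nrow(pairs)) n - max(pairs) else 0L
    for (k in seq_len(spec$n_rows)) {
      g5 <- if (lo > 0L) stats::rbinom(1L, lo, spec$gap_rate) else 0L
      g3 <- if (hi > 0L) stats::rbinom(1L, hi, spec$gap_rate) else 0L
      if (g5) rows[k, seq_len(g5)] <- "-"
      if (g3) rows[k, (n - g3 + 1L):n] <- "-"
    }
  } else if (spec$gap_rate > 0 && spec$gap_policy == "interior") {
    n_ins <- stats::rbinom(1L, n, spec$gap_rate)
    if (n_ins > 0L) {
      at <- sort(sample.int(n + 1L, n_ins, replace = TRUE))  # before column
      for (pos in rev(at)) {  # right to left keeps earlier positions valid
        col <- ifelse(stats::runif(spec$n_rows) < 0.5,
                      bases[sample.int(4L, spec$n_rows, replace = TRUE)], "-")
        L <- ncol(rows)
        rows <- if (pos > L) cbind(rows, col)
                else cbind(rows[, seq_len(pos - 1L), drop = FALSE], col,
                           rows[, pos:L, drop = FALSE])
        if (nrow(pair_cols)) pair_cols <- pair_cols + (pair_cols >= pos)
      }
    }
  }
  aln <- rna_alignment(apply(rows, 1L, paste, collapse = ""),
                       ids = paste0("synth", seq_len(spec$n_rows)))
  planted_cols <- rna_structure(aln$L, pair_cols, validate = FALSE)
  list(aln = aln,
       truth = list(pair_cols = pair_cols, structure = planted_cols,
                    hishape = format(abstract_hishape(planted_cols, "h"))))
}

#' Exhaustive hishape classification (oracle)
#'
#' Brute-force oracle for [kbest_hishapes()]: enumerates every
#' constraint-satisfying structure over the filtered candidate pairs by plain
#' interval backtracking (no memoization, no shared code with the grammar
#' enumerator), classifies them and takes per-class minima. Exact but
#' exponential; guarded by `cfg$max_structures`.
#'
#' @inheritParams kbest_hishapes
#' @return The same `hishape_classes` data frame as [kbest_hishapes()],
#'   truncated to the same `cfg$k` classes and ordered by the same rules.
#' @export
brute_force_hishapes <- function(aln, cfg = folding_space_config(),
                                 backend = toy_backend(),
                                 params = covariance_params()) {
  ok <- allowed_pairs(aln, cfg)
  L <- aln$L
  count <- 0L
  empty <- matrix(integer(0), ncol = 2L)
  min_hel <- cfg$min_helix_length
  # plain interval backtracking: position lo is either unpaired or opens a
  # maximal helix run of >= min_hel stacked admissible pairs; inner and outer
  # intervals are then independent
  bf_region <- function(lo, hi) {
    if (hi - lo < 4L) return(list(empty))
    res <- bf_region(lo + 1L, hi)  # lo unpaired
    qs <- which(ok[lo, ])
    for (q in qs[qs <= hi]) {
      kmax <- 1L
      while (lo + kmax < q - kmax && ok[lo + kmax, q - kmax]) kmax <- kmax + 1L
      if (kmax < min_hel) next
      outer <- bf_region(q + 1L, hi)
      for (k in min_hel:kmax) {
        hp <- cbind(lo + 0:(k - 1L), q - 0:(k - 1L))
        inner <- if (lo + k <= q - k) bf_region(lo + k, q - k) else list(empty)
        for (ip in inner) {
          # run of stacked pairs must be maximal, else double counting
          if (nrow(ip) && any(ip[, 1L] == lo + k & ip[, 2L] == q - k)) next
          for (op in outer) res[[length(res) + 1L]] <- rbind(hp, ip, op)
        }
      }
    }
    count <<- count + length(res)
    if (count > cfg$max_structures)
      stop("folding space larger than max_structures = ", cfg$max_structures)
    res
  }
  results <- bf_region(1L, L)
  structures <- lapply(results, function(p)
    rna_structure(L, p, validate = FALSE))
  ctx <- energy_context(aln, backend, params)
  pseudo <- lapply(structures, ctx$evaluate)
  energies <- vapply(pseudo, `[[`, numeric(1), "total")
  if (!is.null(cfg$x_filter)) {
    ok2 <- vapply(structures, function(s)
      passes_x_filter(s, cfg$x_filter, ctx), logical(1))
    structures <- structures[ok2]; pseudo <- pseudo[ok2]
    energies <- energies[ok2]
  }
  enum <- list(structures = structures, energies = energies, pseudo = pseudo)
  classify_kbest(enum, cfg, k = cfg$k)
}

#' Exact minimax barrier between two structures (oracle)
#'
#' Best-first minimax search over the complete move graph spanned by the
#' direct move set (pairs unique to either endpoint may be added or removed
#' in any order, shared pairs are fixed). Returns the exact minimum over all
#' paths of the maximum pseudo energy. Exponential in the number of differing
#' pairs; guarded.
#'
#' @inheritParams direct_path
#' @param max_states Guard on the number of expanded states.
#' @return The exact barrier (kcal/mol).
#' @export
minimax_barrier_oracle <- function(aln, a, b, backend = toy_backend(),
                                   params = covariance_params(),
                                   max_states = 1e6) {
  stopifnot(a$length == aln$L, b$length == aln$L)
  ctx <- energy_context(aln, backend, params)
  key_b <- pairs_key(b$pairs)
  # priority "queue": environment of best-known saddle per state
  best <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())  # key -> structure
  e_a <- ctx$total(a)
  ka <- pairs_key(a$pairs)
  best[[ka]] <- e_a
  store[[ka]] <- a
  open <- c(ka)
  closed <- character(0)
  expanded <- 0L
  while (length(open)) {
    sad <- vapply(open, function(k) best[[k]], numeric(1))
    cur <- open[which.min(sad)][1]
    open <- setdiff(open, cur)
    if (identical(cur, key_b)) return(best[[cur]])
    closed <- c(closed, cur)
    expanded <- expanded + 1L
    if (expanded > max_states)
      stop("minimax oracle exceeded max_states = ", max_states)
    s <- store[[cur]]
    ms <- move_set(s, b)
    # the full toggle graph: also allow re-adding pairs of `a` that were
    # removed, and removing pairs of `b` that were added
    back <- move_set(s, a)
    steps <- rbind(if (nrow(ms$add)) cbind(ms$add, 1L),
                   if (nrow(ms$remove)) cbind(ms$remove, 0L),
                   if (nrow(back$add)) cbind(back$add, 1L),
                   if (nrow(back$remove)) cbind(back$remove, 0L))
    if (is.null(steps) || !nrow(steps)) next
    steps <- unique(steps)
    for (t in seq_len(nrow(steps))) {
      s2 <- apply_move(s, steps[t, 1:2], steps[t, 3L] == 1L)
      k2 <- pairs_key(s2$pairs)
      if (k2 %in% closed) next
      sad2 <- max(best[[cur]], ctx$total(s2))
      known <- best[[k2]]
      if (is.null(known) || sad2 < known) {
        best[[k2]] <- sad2
        store[[k2]] <- s2
        if (!(k2 %in% open)) open <- c(open, k2)
      }
    }
  }
  stop("target not reachable in the direct move graph")
}
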