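# Covariance scoring of alignment column pairs and the consensus
# pseudo free energy (mean free energy + weighted covariance term).

#' Covariance scoring parameters
#'
#' @param lam Weighting factor lambda balancing free energy and covariance
#'   contribution (kcal/mol per score unit). The default `-1` makes
#'   covariation lower the pseudo free energy, the usual covariation-bonus
#'   convention of alignment folding; any sign is accepted.
#' @param phi Scaling factor for the inconsistency penalty Q, `phi >= 0`.
#' @param normalization `"per_M"` (1/M prefactor on the conservation sum) or
#'   `"per_pairs"` (2/(M(M-1)), averaging over row pairs).
#' @return A list of class `covariance_params`.
#' @export
covariance_params <- function(lam = -1.0, phi = 1.0,
                              normalization = c("per_M", "per_pairs")) {
  normalization <- match.arg(normalization)
  if (phi < 0) stop("phi must be non-negative")
  structure(list(lam = lam, phi = phi, normalization = normalization),
            class = "covariance_params")
}

check_columns <- function(aln, i, j) {
  if (i < 1L || j > aln$L || i >= j)
    stop("column pair out of range: (", i, ",", j, ") with L = ", aln$L)
}

#' Conservation score V of an alignment column pair
#'
#' For every pair of alignment rows (k, l) in which both rows can form a
#' valid base pair `(s_ik, s_jk)` and `(s_il, s_jl)` in
#' `BP = {AU, UA, GC, CG, GU, UG}`, the score counts the Hamming distance
#' between the two rows' pairing bases, `h(s_ik, s_il) + h(s_jk, s_jl)`;
#' row pairs where either row cannot pair contribute 0. Compensatory
#' (covarying) base pairs therefore score 2, consistent pairs with one
#' changed base 1, identical pairs 0. The sum is divided by M
#' (`per_M`) or by the number of row pairs (`per_pairs`).
#'
#' @param aln An [rna_alignment()].
#' @param i,j Alignment columns, `1 <= i < j <= L`.
#' @param params A [covariance_params()].
#' @return Non-negative conservation score.
#' @export
conservation_score_V <- function(aln, i, j, params = covariance_params()) {
  check_columns(aln, i, j)
  si <- aln$mat[, i]; sj <- aln$mat[, j]
  can_pair <- is_valid_pair(si, sj)
  idx <- which(can_pair)
  total <- 0
  if (length(idx) >= 2L) {
    for (a in seq_len(length(idx) - 1L)) {
      k <- idx[a]
      l <- idx[(a + 1L):length(idx)]
      total <- total + sum((si[k] != si[l]) + (sj[k] != sj[l]))
    }
  }
  M <- aln$M
  denom <- if (params$normalization == "per_M") M else M * (M - 1) / 2
  if (denom == 0) return(0)
  total / denom
}

#' Gap/inconsistency penalty Q of an alignment column pair
#'
#' Each row contributes 0 if it has gaps at both columns or forms a valid
#' base pair, and 1 otherwise; the sum is divided by M.
#'
#' @inheritParams conservation_score_V
#' @return Penalty in `[0, 1]`.
#' @export
gap_penalty_Q <- function(aln, i, j) {
  check_columns(aln, i, j)
  si <- aln$mat[, i]; sj <- aln$mat[, j]
  ok <- (si == "-" & sj == "-") | is_valid_pair(si, sj)
  sum(!ok) / aln$M
}

#' Covariance score C = V - phi * Q
#'
#' @inheritParams conservation_score_V
#' @return Covariance score (any sign).
#' @export
covariance_C <- function(aln, i, j, params = covariance_params()) {
  conservation_score_V(aln, i, j, params) - params$phi * gap_penalty_Q(aln, i, j)
}

#' Fraction of rows forming a valid base pair at a column pair
#'
#' The base-pairing filter of the consensus folding space keeps a candidate
#' column pair only if this fraction reaches a threshold (default 0.5).
#'
#' @inheritParams conservation_score_V
#' @return Fraction in `[0, 1]`.
#' @export
pair_fraction <- function(aln, i, j) {
  check_columns(aln, i, j)
  sum(is_valid_pair(aln$mat[, i], aln$mat[, j])) / aln$M
}

#' Project a consensus structure onto one alignment row
#'
#' Drops pairs with a gap in the row and pairs the row cannot form (the
#' inconsistency is already penalized through Q), then re-indexes the
#' remaining pairs to ungapped sequence positions. The result may contain
#' lonely pairs or short loops; it is meant for energy evaluation.
#'
#' @param aln An [rna_alignment()].
#' @param row Row index.
#' @param s An [rna_structure()] over alignment columns.
#' @param cmap Optional precomputed [coordinate_map()] for `row`.
#' @return An [rna_structure()] over sequence positions of the row.
#' @export
project_structure <- function(aln, row, s, cmap = coordinate_map(aln, row)) {
  stopifnot(inherits(s, "rna_structure"))
  if (s$length != aln$L)
    stop("structure covers ", s$length, " columns, alignment has ", aln$L)
  pairs <- s$pairs
  if (nrow(pairs)) {
    ci <- aln$mat[row, pairs[, 1L]]
    cj <- aln$mat[row, pairs[, 2L]]
    keep <- is_valid_pair(ci, cj)  # excludes gaps and invalid pairs
    pairs <- pairs[keep, , drop = FALSE]
    pairs <- cbind(cmap$col_to_pos[pairs[, 1L]], cmap$col_to_pos[pairs[, 2L]])
  }
  rna_structure(nchar(cmap$seq), pairs, validate = FALSE)
}

#' Consensus pseudo free energy of a structure on an alignment
#'
#' The pseudo free energy combines the mean single-sequence free energy of
#' the structure over all rows (each row evaluated on its ungapped sequence
#' after projection) with a weighted covariance term:
#' `total = mean_energy + lam * sum(C_ij over pairs)`.
#'
#' @param aln An [rna_alignment()].
#' @param s An [rna_structure()] over alignment columns.
#' @param backend Energy backend, e.g. [toy_backend()] or [turner_backend()].
#' @param params A [covariance_params()].
#' @return A list of class `pseudo_energy` with `total`, `mean_energy` and
#'   `covariance_term` (kcal/mol); `total == mean_energy + covariance_term`.
#' @export
consensus_pseudo_energy <- function(aln, s, backend = toy_backend(),
                                    params = covariance_params()) {
  stopifnot(inherits(aln, "rna_alignment"))
  if (s$length != aln$L)
    stop("structure covers ", s$length, " columns, alignment has ", aln$L)
  cmaps <- lapply(seq_len(aln$M), function(k) coordinate_map(aln, k))
  mean_energy <- mean(vapply(seq_len(aln$M), function(k) {
    sequence_energy(cmaps[[k]]$seq, project_structure(aln, k, s, cmaps[[k]]),
                    backend)
  }, numeric(1)))
  cov_sum <- 0
  if (nrow(s$pairs)) {
    cov_sum <- sum(vapply(seq_len(nrow(s$pairs)), function(a) {
      covariance_C(aln, s$pairs[a, 1L], s$pairs[a, 2L], params)
    }, numeric(1)))
  }
  covariance_term <- params$lam * cov_sum
  structure(list(total = mean_energy + covariance_term,
                 mean_energy = mean_energy,
                 covariance_term = covariance_term),
            class = "pseudo_energy")
}

# Precomputed evaluation context: coordinate maps, row character matrices and
# a lazily filled C_{ij} cache. Used by enumeration and path search, where the
# same alignment is scored for thousands of structures.
energy_context <- function(aln, backend, params) {
  cmaps <- lapply(seq_len(aln$M), function(k) coordinate_map(aln, k))
  C_cache <- new.env(parent = emptyenv())
  get_C <- function(i, j) {
    key <- paste0(i, "_", j)
    v <- C_cache[[key]]
    if (is.null(v)) {
      v <- covariance_C(aln, i, j, params)
      C_cache[[key]] <- v
    }
    v
  }
  evaluate <- function(s) {
    me <- mean(vapply(seq_len(aln$M), function(k) {
      sequence_energy(cmaps[[k]]$seq, project_structure(aln, k, s, cmaps[[k]]),
                      backend)
    }, numeric(1)))
    cov_sum <- 0
    if (nrow(s$pairs))
      cov_sum <- sum(vapply(seq_len(nrow(s$pairs)),
                            function(a) get_C(s$pairs[a, 1L], s$pairs[a, 2L]),
                            numeric(1)))
    ct <- params$lam * cov_sum
    structure(list(total = me + ct, mean_energy = me, covariance_term = ct),
              class = "pseudo_energy")
  }
  list(aln = aln, backend = backend, params = params, cmaps = cmaps,
       evaluate = evaluate, total = function(s) evaluate(s)$total)
}

#' @export
print.pseudo_energy <- function(x, ...) {
  cat(sprintf("pseudo free energy: %.2f kcal/mol (mean %.2f + covariance %.2f)\n",
              x$total, x$mean_energy, x$covariance_term))
  invisible(x)
}
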