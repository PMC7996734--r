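# Refolding pathways between consensus structures: width-limited
# breadth-first heuristic over the direct move set, plus indirect routes
# through intermediate hishreps.

#' Legal single base-pair moves towards a target structure
#'
#' Moves are restricted to base pairs unique to either the current or the
#' target structure: removable pairs are those in `current` but not `target`;
#' addable pairs are those in `target` but not `current` that are compatible
#' with `current` (both positions unpaired, non-crossing). Every move
#' decreases the base-pair distance to the target by exactly one.
#'
#' @param current,target [rna_structure()] objects on the same coordinate
#'   system.
#' @return A list with integer matrices `add` and `remove` (two columns).
#' @export
move_set <- function(current, target) {
  stopifnot(current$length == target$length)
  kc <- paste(current$pairs[, 1L], current$pairs[, 2L])
  kt <- paste(target$pairs[, 1L], target$pairs[, 2L])
  removable <- current$pairs[!(kc %in% kt), , drop = FALSE]
  cand <- target$pairs[!(kt %in% kc), , drop = FALSE]
  if (nrow(cand)) {
    okv <- vapply(seq_len(nrow(cand)), function(a) {
      i <- cand[a, 1L]; j <- cand[a, 2L]
      if (any(current$pairs == i) || any(current$pairs == j)) return(FALSE)
      cp <- current$pairs
      if (nrow(cp)) {
        # crossing iff exactly one endpoint of (i,j) lies inside (k,l)
        ins_i <- cp[, 1L] < i & i < cp[, 2L]
        ins_j <- cp[, 1L] < j & j < cp[, 2L]
        if (any(xor(ins_i, ins_j))) return(FALSE)
      }
      TRUE
    }, logical(1))
    addable <- cand[okv, , drop = FALSE]
  } else {
    addable <- cand
  }
  list(add = addable, remove = removable)
}

apply_move <- function(s, pair, add) {
  if (add) {
    rna_structure(s$length, rbind(s$pairs, pair), validate = FALSE)
  } else {
    keep <- !(s$pairs[, 1L] == pair[1] & s$pairs[, 2L] == pair[2])
    rna_structure(s$length, s$pairs[keep, , drop = FALSE], validate = FALSE)
  }
}

new_path <- function(dotbrackets, energies, moves) {
  structure(list(states = dotbrackets, energies = energies,
                 barrier = max(energies), moves = moves),
            class = "refolding_path")
}

#' @export
print.refolding_path <- function(x, ...) {
  for (t in seq_along(x$states))
    cat(sprintf("%3d  %s  %8.2f\n", t - 1L, x$states[t], x$energies[t]))
  cat(sprintf("barrier: %.2f kcal/mol\n", x$barrier))
  invisible(x)
}

#' Direct refolding path between two structures (beam search)
#'
#' Width-limited breadth-first heuristic: a frontier of at most `width`
#' partial paths is advanced one move per round, where moves add or remove
#' only base pairs unique to start or target, so a completed path has
#' base-pair distance + 1 states. The frontier is ranked by lowest saddle
#' energy so far (the running maximum of pseudo energies), ties by current
#' state energy, then by lexicographic dot-bracket; paths reaching the same
#' structure are merged keeping the best. Returns the completed path with the
#' lowest barrier found. The barrier is non-increasing in `width`.
#'
#' @param aln An [rna_alignment()]; intermediate structures are scored with
#'   the same consensus pseudo free energy as the folding space.
#' @param a,b Start and target [rna_structure()] over alignment columns.
#' @param width Beam width (default 16).
#' @param backend Energy backend.
#' @param params [covariance_params()].
#' @return A `refolding_path`: `states` (dot-brackets), `energies`, `barrier`
#'   (max energy along the path) and `moves` (per-step `"+i:j"`/`"-i:j"`).
#' @export
direct_path <- function(aln, a, b, width = 16L, backend = toy_backend(),
                        params = covariance_params()) {
  stopifnot(width >= 1L, a$length == aln$L, b$length == aln$L)
  ctx <- energy_context(aln, backend, params)
  cache <- new.env(parent = emptyenv())
  energy_of <- function(s, db) {
    v <- cache[[db]]
    if (is.null(v)) { v <- ctx$total(s); cache[[db]] <- v }
    v
  }
  db_a <- write_dotbracket(a); db_b <- write_dotbracket(b)
  e_a <- energy_of(a, db_a)
  if (identical(db_a, db_b))
    return(new_path(db_a, e_a, character(0)))
  frontier <- list(list(s = a, db = db_a, energy = e_a, saddle = e_a,
                        states = db_a, energies = e_a, moves = character(0)))
  d <- bp_distance(a, b)
  for (round in seq_len(d)) {
    cand <- list()
    for (f in frontier) {
      ms <- move_set(f$s, b)
      steps <- rbind(if (nrow(ms$add)) cbind(ms$add, 1L),
                     if (nrow(ms$remove)) cbind(ms$remove, 0L))
      if (is.null(steps) || !nrow(steps)) next
      for (t in seq_len(nrow(steps))) {
        pair <- steps[t, 1:2]
        add <- steps[t, 3L] == 1L
        s2 <- apply_move(f$s, pair, add)
        db2 <- write_dotbracket(s2)
        e2 <- energy_of(s2, db2)
        cand[[length(cand) + 1L]] <- list(
          s = s2, db = db2, energy = e2, saddle = max(f$saddle, e2),
          states = c(f$states, db2), energies = c(f$energies, e2),
          moves = c(f$moves, paste0(if (add) "+" else "-",
                                    pair[1], ":", pair[2])))
      }
    }
    if (!length(cand)) stop("search stalled before reaching the target")
    # merge paths reaching the same structure: keep the best saddle
    dbs <- vapply(cand, `[[`, character(1), "db")
    sad <- vapply(cand, `[[`, numeric(1), "saddle")
    en <- vapply(cand, `[[`, numeric(1), "energy")
    ord <- order(sad, en, dbs)
    cand <- cand[ord][!duplicated(dbs[ord])]
    frontier <- utils::head(cand, width)
  }
  done <- frontier[vapply(frontier, function(f) identical(f$db, db_b),
                          logical(1))]
  if (!length(done)) stop("target not reached (internal error)")
  f <- done[[1]]
  new_path(f$states, f$energies, f$moves)
}

#' Best refolding path allowing single intermediate hishreps
#'
#' Compares the direct path `a -> b` with, for each intermediate `m`, the
#' concatenation `a -> m -> b` whose barrier is the maximum of the two legs,
#' and returns the minimum-barrier path (never worse than the direct one).
#'
#' @inheritParams direct_path
#' @param intermediates List of [rna_structure()] (e.g. other hishreps of the
#'   same folding space).
#' @return A `refolding_path`.
#' @export
indirect_barrier <- function(aln, a, b, intermediates = list(), width = 16L,
                             backend = toy_backend(),
                             params = covariance_params()) {
  best <- direct_path(aln, a, b, width, backend, params)
  db_a <- write_dotbracket(a); db_b <- write_dotbracket(b)
  for (m in intermediates) {
    db_m <- write_dotbracket(m)
    if (identical(db_m, db_a) || identical(db_m, db_b)) next
    leg1 <- direct_path(aln, a, m, width, backend, params)
    if (leg1$barrier >= best$barrier) next  # cannot improve
    leg2 <- direct_path(aln, m, b, width, backend, params)
    barrier <- max(leg1$barrier, leg2$barrier)
    if (barrier < best$barrier) {
      best <- new_path(c(leg1$states, leg2$states[-1L]),
                       c(leg1$energies, leg2$energies[-1L]),
                       c(leg1$moves, leg2$moves))
    }
  }
  best
}
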