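# Arrhenius transition rates between hishape classes and master-equation
# folding kinetics.

GAS_CONSTANT <- 0.0019872  # kcal/(mol K)

#' Build an Arrhenius transition-rate matrix
#'
#' For states a, b with pseudo energies `E_a`, `E_b` and saddle (barrier)
#' energy `B_ab >= max(E_a, E_b)`, the rate of the transition a -> b is
#' `R[a,b] = A * exp(-(B_ab - E_a) / RT)`. Barriers are symmetrized to the
#' best (lowest) value found in either direction before rate construction,
#' which guarantees detailed balance with respect to the Boltzmann
#' distribution of the state energies. Diagonal entries are set so every row
#' sums to zero. `NA` barriers mark state pairs with no path found; they get
#' rate 0 (disconnected) with a message.
#'
#' @param energies Named numeric vector of state pseudo energies (kcal/mol);
#'   names identify the states (e.g. hishape strings).
#' @param barriers Square numeric matrix of saddle energies (kcal/mol);
#'   `barriers[a, b]` for the transition a -> b. Diagonal is ignored. `NA`
#'   off-diagonal entries mean "disconnected"; an entry below both endpoint
#'   energies is a contract violation and raises an error.
#' @param temperature Temperature in kelvin (default 310.15).
#' @param prefactor Arrhenius prefactor A, fixing the (arbitrary) time unit.
#' @return A list of class `rate_matrix` with `R`, `states`, `energies`,
#'   `temperature`, `prefactor`.
#' @export
build_rate_matrix <- function(energies, barriers, temperature = 310.15,
                              prefactor = 1.0) {
  n <- length(energies)
  if (is.null(names(energies))) names(energies) <- paste0("S", seq_len(n))
  stopifnot(is.matrix(barriers), nrow(barriers) == n, ncol(barriers) == n)
  RT <- GAS_CONSTANT * temperature
  B <- pmin(barriers, t(barriers), na.rm = TRUE)  # best direction
  diag(B) <- NA_real_
  R <- matrix(0, n, n, dimnames = list(names(energies), names(energies)))
  disconnected <- 0L
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      if (is.na(B[a, b])) { disconnected <- disconnected + 1L; next }
      if (B[a, b] < max(energies[a], energies[b]) - 1e-9)
        stop("barrier between states ", a, " and ", b,
             " lies below an endpoint energy")
      R[a, b] <- prefactor * exp(-(B[a, b] - energies[a]) / RT)
    }
  }
  if (disconnected)
    message(disconnected / 2, " state pair(s) disconnected (no barrier); rate 0")
  diag(R) <- -rowSums(R)
  structure(list(R = R, states = names(energies), energies = energies,
                 temperature = temperature, prefactor = prefactor),
            class = "rate_matrix")
}

#' Default simulation time grid
#'
#' @param from,to Time range (arbitrary units set by the Arrhenius prefactor).
#' @param points Number of log-spaced instants.
#' @return Increasing numeric vector.
#' @export
kinetics_times <- function(from = 1e-2, to = 1e10, points = 60L) {
  exp(seq(log(from), log(to), length.out = points))
}

#' Simulate folding kinetics (master equation)
#'
#' Integrates `dp/dt = p R` from the initial distribution `p0`, i.e.
#' `p(t) = p0 exp(R t)`. Because the Arrhenius rates satisfy detailed balance
#' with respect to the Boltzmann weights of the state energies, the
#' propagator is computed by a symmetrized eigendecomposition
#' (stiff-safe for arbitrary time spans).
#'
#' @param rm A [build_rate_matrix()] result.
#' @param p0 Initial distribution (non-negative, sums to 1); by name or in
#'   state order.
#' @param times Increasing positive time points (default [kinetics_times()]).
#' @return A list of class `trajectory` with `times` and `populations`
#'   (matrix, one row per time, one named column per state).
#' @export
simulate_kinetics <- function(rm, p0, times = kinetics_times()) {
  stopifnot(inherits(rm, "rate_matrix"))
  n <- length(rm$states)
  if (!is.null(names(p0))) {
    v <- rep(0, n); names(v) <- rm$states
    if (!all(names(p0) %in% rm$states))
      stop("unknown state in p0: ",
           paste(setdiff(names(p0), rm$states), collapse = ", "))
    v[names(p0)] <- p0
    p0 <- v
  }
  if (length(p0) != n) stop("p0 must have one entry per state")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("p0 must be a probability distribution")
  if (any(diff(times) <= 0) || any(times <= 0))
    stop("times must be positive and increasing")
  if (any(!is.finite(rm$R))) stop("non-finite rate matrix")
  RT <- GAS_CONSTANT * rm$temperature
  w <- exp(-(rm$energies - min(rm$energies)) / RT)  # unnormalized Boltzmann
  sq <- sqrt(w)
  S <- diag(sq, nrow = n) %*% rm$R %*% diag(1 / sq, nrow = n)
  S <- (S + t(S)) / 2  # symmetric under detailed balance; average off rounding
  es <- eigen(S, symmetric = TRUE)
  # a generator has spectrum <= 0 with one exact zero mode; roundoff in the
  # near-zero eigenvalue would blow up as exp(lambda * t) at large t
  tol <- 1e-12 * max(abs(es$values), 1)
  es$values[es$values > -tol] <- 0
  V <- es$vectors
  # p(t) = p0 D^{-1/2} V exp(L t) V' D^{1/2}, D = diag(w)
  left <- as.numeric((p0 / sq) %*% V)
  pop <- matrix(0, length(times), n, dimnames = list(NULL, rm$states))
  for (ti in seq_along(times)) {
    pop[ti, ] <- (V %*% (left * exp(es$values * times[ti]))) * sq
  }
  structure(list(times = times, populations = pop, states = rm$states),
            class = "trajectory")
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi R = 0`, `sum(pi) = 1`. For a reducible rate matrix (disconnected
#' state groups) the stationary distribution is not unique; each connected
#' component is then solved and normalized separately, with a warning, and a
#' list of per-component distributions is returned.
#'
#' @param rm A [build_rate_matrix()] result.
#' @return Named numeric vector (irreducible case), or a list of named
#'   vectors, one per connected component.
#' @export
equilibrium <- function(rm) {
  stopifnot(inherits(rm, "rate_matrix"))
  n <- length(rm$states)
  adj <- (rm$R > 0) | (t(rm$R) > 0)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  solve_component <- function(idx) {
    Rc <- rm$R[idx, idx, drop = FALSE]
    A <- rbind(t(Rc), rep(1, length(idx)))
    b <- c(rep(0, length(idx)), 1)
    pi_ <- qr.solve(A, b)
    pi_[pi_ < 0 & pi_ > -1e-12] <- 0
    pi_ <- pi_ / sum(pi_)
    names(pi_) <- rm$states[idx]
    pi_
  }
  if (cid == 1L) return(solve_component(seq_len(n)))
  warning("rate matrix is reducible: ", cid,
          " components; returning per-component distributions")
  lapply(seq_len(cid), function(cc) solve_component(which(comp == cc)))
}

#' Group trajectory populations
#'
#' Sums member-state populations per group at each time point, e.g. to pool
#' functionally similar hishapes across homologs. Groups must be disjoint;
#' ungrouped states pass through unchanged. Conservation is preserved.
#'
#' @param traj A [simulate_kinetics()] result.
#' @param groups Named list mapping group name to a character vector of state
#'   names (or integer indices).
#' @return A `trajectory` over groups (and passed-through states).
#' @export
group_populations <- function(traj, groups) {
  stopifnot(inherits(traj, "trajectory"))
  states <- colnames(traj$populations)
  members <- lapply(groups, function(g) {
    if (is.numeric(g)) states[g] else g
  })
  flat <- unlist(members)
  if (anyDuplicated(flat))
    stop("state assigned to two groups: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "))
  if (!all(flat %in% states))
    stop("unknown state(s) in groups: ",
         paste(setdiff(flat, states), collapse = ", "))
  rest <- setdiff(states, flat)
  pop <- cbind(
    do.call(cbind, lapply(members, function(m)
      rowSums(traj$populations[, m, drop = FALSE]))),
    traj$populations[, rest, drop = FALSE])
  colnames(pop) <- c(names(groups), rest)
  structure(list(times = traj$times, populations = pop,
                 states = colnames(pop)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", length(x$times), " time points, ",
      ncol(x$populations), " state(s)\n", sep = "")
  show <- unique(round(seq(1, length(x$times), length.out = 5)))
  df <- data.frame(time = signif(x$times[show], 3),
                   signif(x$populations[show, , drop = FALSE], 4),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a trajectory as a TSV table
#'
#' Column 1 is time, then one column per state (or group), header naming the
#' hishapes; the layout of coarse-grained kinetics tools.
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = format(traj$times, digits = 8, scientific = TRUE),
                   format(traj$populations, digits = 8),
                   check.names = FALSE)
  names(df) <- c("time", colnames(traj$populations))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
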