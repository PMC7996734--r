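RT <- 0.0019872 * 310.15

two_state <- function(barrier = 3.0, energies = c(A = 0, B = 0), ...) {
  build_rate_matrix(energies,
                    matrix(c(NA, barrier, barrier, NA), 2, 2), ...)
}

test_that("Arrhenius rates follow the barrier heights", {
  rm <- two_state(barrier = 0, energies = c(A = 0, B = 0))
  expect_equal(rm$R["A", "B"], 1.0)  # zero activation: rate = prefactor
  rm2 <- two_state(barrier = 3.0)
  expect_equal(rm2$R["A", "B"], exp(-3.0 / RT))
  expect_equal(rm2$R["A", "B"], rm2$R["B", "A"])  # equal energies: symmetric
  expect_equal(unname(rowSums(rm2$R)), c(0, 0), tolerance = 1e-12)
  rm3 <- two_state(barrier = 3.0, prefactor = 10)
  expect_equal(rm3$R["A", "B"], 10 * exp(-3.0 / RT))
})

test_that("invalid barriers are rejected, missing ones disconnect", {
  expect_error(two_state(barrier = -1, energies = c(A = 0, B = 0)),
               "below an endpoint")
  expect_message(
    rm <- build_rate_matrix(c(A = 0, B = 0), matrix(NA_real_, 2, 2)),
    "disconnected")
  expect_equal(rm$R["A", "B"], 0)
})

test_that("asymmetric barrier inputs are symmetrized to the best direction", {
  B <- matrix(c(NA, 5, 3, NA), 2, 2)  # 3 found one way, 5 the other
  rm <- build_rate_matrix(c(A = 0, B = 0), B)
  expect_equal(rm$R["A", "B"], exp(-3 / RT))
  expect_equal(rm$R["B", "A"], exp(-3 / RT))
})

test_that("a zero rate matrix leaves populations unchanged", {
  rm <- suppressMessages(
    build_rate_matrix(c(A = 0, B = 0), matrix(NA_real_, 2, 2)))
  traj <- simulate_kinetics(rm, c(A = 0.3, B = 0.7), times = c(1, 10, 100))
  expect_equal(unname(traj$populations[3, ]), c(0.3, 0.7))
})

test_that("two-state kinetics match the analytic solution to 1e-8", {
  rm <- two_state(barrier = 3.0)
  times <- 10^seq(-2, 6, length.out = 60)
  traj <- simulate_kinetics(rm, c(A = 1, B = 0), times)
  r <- exp(-3.0 / RT)
  analytic <- 0.5 * (1 + exp(-2 * r * times))
  expect_lt(max(abs(traj$populations[, "A"] - analytic)), 1e-8)
  expect_lt(max(abs(rowSums(traj$populations) - 1)), 1e-8)
  expect_true(all(traj$populations > -1e-10))
})

test_that("spectral propagation agrees with stiff ODE integration", {
  energies <- c(X = 0, Y = -1.2, Z = 0.4)
  B <- matrix(c(NA, 2.5, 3.1,
                2.5, NA, 1.9,
                3.1, 1.9, NA), 3, 3)
  rm <- build_rate_matrix(energies, B)
  times <- 10^seq(-1, 7, length.out = 25)
  traj <- simulate_kinetics(rm, c(X = 1, Y = 0, Z = 0), times)
  ode <- deSolve::lsoda(
    y = c(1, 0, 0), times = c(0, times),
    func = function(t, y, p) list(as.numeric(y %*% rm$R)),
    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(traj$populations - ode[-1, -1])), 1e-7)
})

test_that("equilibrium is Boltzmann and the long-time limit of simulate", {
  rm <- two_state(barrier = 1.0)
  expect_equal(unname(equilibrium(rm)), c(0.5, 0.5))
  rm2 <- build_rate_matrix(c(A = 0, B = -1),
                           matrix(c(NA, 0.5, 0.5, NA), 2, 2))
  eq <- equilibrium(rm2)
  expect_equal(unname(eq["B"] / eq["A"]), exp(1 / RT), tolerance = 1e-9)
  # detailed-balance 3-state system: simulate(t = 1e9) ~ equilibrium
  energies <- c(X = 0, Y = -1, Z = 1)
  B <- matrix(c(NA, 2, 3, 2, NA, 2.5, 3, 2.5, NA), 3, 3)
  rm3 <- build_rate_matrix(energies, B)
  eq3 <- equilibrium(rm3)
  traj <- simulate_kinetics(rm3, c(X = 1, Y = 0, Z = 0), times = c(1, 1e9))
  expect_lt(max(abs(traj$populations[2, ] - eq3)), 1e-6)
  expect_equal(unname(eq3 / eq3[1]),
               unname(exp(-(energies - energies[1]) / RT)), tolerance = 1e-9)
})

test_that("reducible rate matrices give per-component distributions", {
  rm <- suppressMessages(
    build_rate_matrix(c(A = 0, B = 0, C = 0),
                      matrix(c(NA, 1, NA,
                               1, NA, NA,
                               NA, NA, NA), 3, 3)))
  expect_warning(eq <- equilibrium(rm), "reducible")
  expect_length(eq, 2L)
  expect_equal(unname(eq[[1]]), c(0.5, 0.5))
})

test_that("grouping sums populations and preserves conservation", {
  rm <- build_rate_matrix(c(A = 0, B = 0.5, C = -0.5),
                          matrix(c(NA, 2, 2, 2, NA, 2, 2, 2, NA), 3, 3))
  traj <- simulate_kinetics(rm, c(A = 1, B = 0, C = 0),
                            times = 10^seq(-2, 8, length.out = 20))
  g1 <- group_populations(traj, list(A = "A", B = "B", C = "C"))
  expect_equal(g1$populations[, c("A", "B", "C")],
               traj$populations[, c("A", "B", "C")])
  gall <- group_populations(traj, list(all = c("A", "B", "C")))
  expect_equal(unname(gall$populations[, "all"]),
               rep(1, 20), tolerance = 1e-8)
  g2 <- group_populations(traj, list(AB = c("A", "B")))
  expect_equal(g2$populations[, "AB"],
               traj$populations[, "A"] + traj$populations[, "B"])
  expect_error(group_populations(traj, list(g1 = "A", g2 = c("A", "B"))),
               "two groups")
  expect_error(group_populations(traj, list(g = "nope")), "unknown state")
})

test_that("simulate validates its inputs", {
  rm <- two_state()
  expect_error(simulate_kinetics(rm, c(A = 0.5, B = 0.2)), "probability")
  expect_error(simulate_kinetics(rm, c(A = 1, Q = 0)), "unknown state")
  expect_error(simulate_kinetics(rm, c(A = 1, B = 0), times = c(3, 2, 1)),
               "increasing")
})
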