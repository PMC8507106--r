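test_that("integration matches linear closed forms", {
  decay <- rate_field(function(t, x) -x, 1)
  tr <- integrate_field(decay, 1, horizon = 10, n_save = 500)
  for (tt in c(1, 2, 5)) {
    i <- which.min(abs(tr$times - tt))
    expect_equal(unname(tr$states[i, 1]), exp(-tr$times[i]), tolerance = 1e-6)
  }
  # birth-death settles at s/d and reports convergence
  m <- birth_death_model()
  f <- assemble(m, rn_parameters(c(s = 3, d = 0.25)))
  for (x0 in c(0, 5, 80)) {
    tr <- integrate_field(f, x0)
    expect_true(tr$converged)
    expect_equal(unname(tr$final_state), 12, tolerance = 1e-6)
  }
})

test_that("two-node integration from the origin reaches the quadratic root", {
  tn <- build_two_node(1.3, 0.4, 2.1, 0.9, 0.6, 1.7)
  f <- assemble(tn$model, tn$params)
  tr <- integrate_field(f, c(0, 0))
  want <- two_node_oracle(1.3, 0.4, 2.1, 0.9, 0.6, 1.7)
  expect_equal(unname(tr$final_state), unname(want), tolerance = 1e-7)
})

test_that("integrate_field validates input and flags divergence", {
  f <- assemble(birth_death_model(), rn_parameters(c(s = 1, d = 1)))
  expect_error(integrate_field(f, c(1, 2)), "length")
  expect_error(integrate_field(f, -1), "nonnegative")
  expect_error(integrate_field(f, 1, horizon = -5), "horizon")
  blow <- rate_field(function(t, x) x^2, 1) # finite-time blow-up
  tr <- integrate_field(blow, 2, horizon = 10)
  expect_true(tr$diverged)
  expect_false(tr$converged)
})

test_that("steady-state location refines and classifies stability", {
  f <- assemble(birth_death_model(), rn_parameters(c(s = 2, d = 0.5)))
  ss <- find_steady_state(f, 0)
  expect_equal(unname(ss$state), 4, tolerance = 1e-9)
  expect_true(ss$stable)
  expect_equal(Re(ss$eigenvalues), -0.5, tolerance = 1e-5)
  expect_lt(ss$residual_norm, 1e-10)

  cub <- cubic_factory(0)  # dx/dt = x - x^3
  ss1 <- find_steady_state(cub, 0.1)
  expect_equal(unname(ss1$state), 1, tolerance = 1e-8)
  expect_true(ss1$stable)
  # from exactly the unstable point, classification reports instability
  ss0 <- find_steady_state(cub, 0)
  expect_equal(unname(ss0$state), 0, tolerance = 1e-10)
  expect_false(ss0$stable)
  expect_gt(max(Re(ss0$eigenvalues)), 0.5)
})

test_that("Newton refinement never increases the residual max-norm", {
  b <- build_initial_model()
  f <- assemble(b$model, b$params)
  set.seed(9)
  for (i in 1:10) {
    x <- 10^runif(11, -1, 1)
    r0 <- max(abs(f$f(0, x)))
    res <- newton_refine(f, x)
    expect_lte(res$residual_norm, r0)
  }
})

test_that("stable attractors re-converge after 1% perturbations", {
  b <- build_initial_model()
  f <- assemble(b$model, b$params)
  ext <- extreme_initializations(f$species)
  set.seed(21)
  for (x0 in ext) {
    ss <- find_steady_state(f, unname(x0[f$species]))
    expect_true(ss$stable)
    for (i in 1:5) {
      pert <- ss$state * (1 + 0.01 * runif(11, -1, 1))
      back <- find_steady_state(f, pmax(pert, 0))
      expect_lt(state_distance(back$state, ss$state), 1e-3)
    }
  }
})

test_that("final states are insensitive to 10x tighter integrator tolerances", {
  b <- build_initial_model()
  f <- assemble(b$model, b$params)
  x0 <- rep(1, 11)
  loose <- integrate_field(f, x0, tol = rn_tolerances())
  tight <- integrate_field(f, x0, tol = rn_tolerances(rtol = 1e-9, atol = 1e-9))
  expect_lt(max(abs(loose$final_state - tight$final_state)) /
              max(abs(tight$final_state)), 1e-3)
})

test_that("trajectories export to CSV and respect the time grid contract", {
  f <- assemble(birth_death_model(), rn_parameters(c(s = 1, d = 0.2)))
  tr <- integrate_field(f, 0, horizon = 50, n_save = 40)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(nrow(tr$states), length(tr$times))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  got <- read.csv(path)
  expect_equal(names(got), c("time", "X"))
  expect_equal(got$X, unname(tr$states[, "X"]))
})
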