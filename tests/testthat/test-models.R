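test_that("two-node model structure and decoupled/symmetric steady states", {
  tn <- build_two_node()
  expect_equal(count_reactions(tn$model), 6L)
  # decoupled: plain birth-death ratios
  dec <- build_two_node(2, 0.5, 3, 1.5, kiA = 0, kiB = 0)
  f <- assemble(dec$model, dec$params)
  ss <- find_steady_state(f, c(0, 0))
  expect_equal(unname(ss$state), c(2 / 0.5, 3 / 1.5), tolerance = 1e-8)
  # fully symmetric constants give A* = B*
  sym <- two_node_steady_state(2, 1, 2, 1, 0.7, 0.7)
  expect_equal(sym[["A"]], sym[["B"]], tolerance = 1e-12)
})

test_that("two-node closed form matches the independent quadratic oracle", {
  set.seed(5)
  for (i in 1:200) {
    k <- 10^runif(6, -2, 2)
    got <- two_node_steady_state(k[1], k[2], k[3], k[4], k[5], k[6])
    want <- two_node_oracle(k[1], k[2], k[3], k[4], k[5], k[6])
    expect_equal(got, want, tolerance = 1e-9)
    expect_true(all(got >= 0))
  }
})

test_that("two-node mass action is monostable across a log-spaced grid", {
  # closed form: the quadratic's root product is negative, so exactly one
  # nonnegative equilibrium exists; verify it is linearly stable everywhere
  # on a 5-points-per-decade grid, and dynamically on a subsample
  vals <- 10^seq(-2, 2, length.out = 5)
  grid <- expand.grid(sA = vals, dA = vals, sB = vals, dB = vals,
                      kiA = vals, kiB = vals)
  A <- B <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ss <- two_node_steady_state(g$sA, g$dA, g$sB, g$dB, g$kiA, g$kiB)
    A[i] <- ss[["A"]]; B[i] <- ss[["B"]]
  }
  expect_true(all(is.finite(A)) && all(A >= 0) && all(B >= 0))
  # residuals vanish at the closed-form point
  magA <- grid$sA + grid$dA * A + grid$kiB * A * B
  magB <- grid$sB + grid$dB * B + grid$kiA * A * B
  resA <- (grid$sA - grid$dA * A - grid$kiB * A * B) / magA
  resB <- (grid$sB - grid$dB * B - grid$kiA * A * B) / magB
  expect_lt(max(abs(resA), abs(resB)), 1e-10)
  # Jacobian stability: trace < 0 always; det > 0 => unique attractor
  tr <- -(grid$dA + grid$kiB * B) - (grid$dB + grid$kiA * A)
  dt <- (grid$dA + grid$kiB * B) * (grid$dB + grid$kiA * A) -
    (grid$kiB * A) * (grid$kiA * B)
  expect_true(all(tr < 0))
  expect_true(all(dt > 0))
  # dynamic spot-check: the multistart classifier sees exactly one attractor
  set.seed(7)
  for (i in sample(nrow(grid), 8)) {
    g <- grid[i, ]
    tn <- build_two_node(g$sA, g$dA, g$sB, g$dB, g$kiA, g$kiB)
    cl <- classify_attractors(tn$model, tn$params, n_starts = 12, seed = i)
    expect_equal(length(cl$attractors), 1L)
    want <- two_node_oracle(g$sA, g$dA, g$sB, g$dB, g$kiA, g$kiB)
    expect_equal(unname(cl$attractors[[1]]$state), unname(want),
                 tolerance = 1e-6)
  }
})

test_that("the biochemical model has the documented structure", {
  b <- build_initial_model()
  expect_equal(count_reactions(b$model), 31L)
  expect_equal(length(species_names(b$model)), 11L)
  expect_equal(assemble(b$model, b$params)$dimension, 11L)
  expect_equal(length(perturbable_parameters(b)), 32L)
  expect_true(all(paste0("k", 1:15) %in% names(b$params$values)))
  expect_true(all(c("ki1", "ki2", "Kmcgmp", "kdeg4", "k12") %in%
                    names(b$params$values)))
  expect_equal(unname(b$model$inputs["HGF"]), 1)
})

test_that("the tension-extended model adds one state and four rate constants", {
  bx <- build_extended_model()
  expect_equal(assemble(bx$model, bx$params)$dimension, 12L)
  expect_equal(length(perturbable_parameters(bx)), 36L)
  expect_equal(count_reactions(bx$model), 34L)
  expect_true("Tension" %in% species_names(bx$model))
})

test_that("the extended model reduces to the initial model on shared coordinates", {
  b <- build_initial_model(); bx <- build_extended_model()
  f <- assemble(b$model, b$params)
  fx <- assemble(bx$model, bx$params)
  shared <- match(f$species, fx$species)
  set.seed(3)
  for (i in 1:20) {
    x11 <- 10^runif(11, -2, 2)
    x12 <- numeric(12); x12[shared] <- x11
    x12[fx$species == "Tension"] <- 0 # no tension: feedback terms vanish
    expect_equal(fx$f(0, x12)[shared], f$f(0, x11), tolerance = 1e-12)
  }
})

test_that("both RhoA-NO baselines are bistable with finite nonnegative attractors", {
  for (built in list(build_initial_model(), build_extended_model())) {
    cl <- classify_attractors(built$model, built$params, n_starts = 25, seed = 2)
    expect_equal(length(cl$attractors), 2L)
    expect_equal(sum(cl$basin_counts) + cl$nonconverged, 25L)
    for (a in cl$attractors) {
      expect_true(all(is.finite(a$state)))
      expect_true(all(a$state >= 0))
      expect_true(a$stable)
    }
  }
})
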