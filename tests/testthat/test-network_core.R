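test_that("one-species synthesis/decay assembles to the closed-form rate law", {
  m <- birth_death_model()
  p <- rn_parameters(c(s = 2.5, d = 0.5))
  f <- assemble(m, p)
  expect_equal(f$dimension, 1L)
  for (x in c(0, 0.3, 1, 10, 400)) {
    expect_equal(f$f(0, x), 2.5 - 0.5 * x)
  }
  expect_equal(count_reactions(m), 2L)
})

test_that("rate-law kinds evaluate per their definitions", {
  m <- rn_model("kinds", list(rn_species("X", 0), rn_species("Y", 0)), list(
    rn_reaction("mm", "michaelis_menten", substrates = c(X = 1),
                products = c(Y = 1), params = c(vmax = "v", km = "km")),
    rn_reaction("hill", "hill", products = c(Y = 1),
                modifiers = list(list(species = "X", type = "driver")),
                params = c(vmax = "v", km = "km", n = "nh")),
    rn_reaction("inh", "synthesis", products = c(X = 1),
                modifiers = list(list(species = "Y", type = "inhibitor",
                                      param = "ki")),
                params = c(k = "s"))
  ))
  p <- rn_parameters(c(v = 2, km = 3, nh = 2, ki = 0.5, s = 4))
  f <- assemble(m, p)
  x <- c(X = 1.5, Y = 2)
  mm <- 2 * 1.5 / (3 + 1.5)
  hill <- 2 * 1.5^2 / (3^2 + 1.5^2)
  inh <- 4 / (1 + 0.5 * 2)
  expect_equal(f$f(0, x), c(-mm + inh, mm + hill))
})

test_that("assembly validates names, parameters and kinds", {
  m <- birth_death_model()
  expect_error(assemble(m, rn_parameters(c(s = 1))), "missing parameter 'd'")
  expect_error(rn_reaction("bad", "exotic", params = c(k = "k")),
               "unknown rate-law kind")
  expect_error(rn_model("dup", list(rn_species("X"), rn_species("X")), list()),
               "unique")
  # species/parameter name collision
  expect_error(assemble(m, rn_parameters(c(s = 1, d = 1, X = 2))), "collision")
  # clamped input cannot collide with species or be consumed
  expect_error(rn_model("clash", list(rn_species("X")), list(),
                        inputs = c(X = 1)), "collides")
  m2 <- rn_model("consume_input", list(rn_species("X")), list(
    rn_reaction("r", "decay", substrates = c(H = 1), params = c(k = "k"))),
    inputs = c(H = 1))
  expect_error(assemble(m2, rn_parameters(c(k = 1))), "clamped")
  expect_error(rn_parameters(c(a = 1, b = -2)), "strictly positive")
})

test_that("nothing is produced from nothing beyond the stated syntheses", {
  for (built in list(build_initial_model(), build_extended_model(),
                     build_two_node())) {
    f <- assemble(built$model, built$params)
    dx0 <- f$f(0, rep(0, f$dimension))
    expect_true(all(dx0 >= 0))
    # species with only consumption terms have exactly zero derivative at 0
    v <- built$params$values
    if ("k1" %in% names(v)) {
      prod0 <- dx0[match(c("RhoAp", "ROCK", "pAkt", "eNOS", "peNOS", "NO",
                           "cGMP", "PKG"), f$species, nomatch = 0)]
      # ROCK and Akt have basal synthesis; the pure conversion products are 0
      expect_equal(unname(dx0[match("RhoAp", f$species)]), 0)
      expect_equal(unname(dx0[match("peNOS", f$species)]), 0)
    }
  }
})

test_that("finite-difference Jacobian agrees with an independent computation", {
  skip_if_not_installed("pracma")
  built <- build_initial_model()
  f <- assemble(built$model, built$params)
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    x <- 10^runif(f$dimension, -2, 2)
    J1 <- f$jacobian(x)
    J2 <- pracma::jacobian(function(z) f$f(0, z), x)
    worst <- max(worst, max(abs(J1 - J2)) / max(1, max(abs(J2))))
  }
  expect_lt(worst, 1e-4)
})

test_that("assembly is deterministic", {
  b <- build_initial_model()
  f1 <- assemble(b$model, b$params)
  f2 <- assemble(b$model, b$params)
  set.seed(2)
  for (i in 1:10) {
    x <- 10^runif(11, -2, 2)
    expect_identical(f1$f(0, x), f2$f(0, x))
  }
})

test_that("raw rate fields wrap arbitrary ODEs", {
  fld <- rate_field(function(t, x) c(-x[1], x[1] - x[2]), 2)
  expect_equal(fld$dimension, 2)
  expect_equal(fld$f(0, c(1, 0)), c(-1, 1))
  J <- fld$jacobian(c(1, 1))
  expect_equal(J, matrix(c(-1, 1, 0, -1), 2, 2), tolerance = 1e-6)
})
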