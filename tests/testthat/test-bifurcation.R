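test_that("a linear system sweeps to a single stable branch without folds", {
  lin <- linear_factory(2) # dx/dt = r - 2x, x* = r/2
  dg <- continue_branch(lin, NULL, "r", c(0.5, 3), anchors = list(0.25, 1.5))
  expect_equal(nrow(dg$folds), 0L)
  expect_null(dg$bistable_interval)
  for (b in dg$branches) {
    expect_true(all(b$stability == "stable"))
    expect_equal(b$x1, b$param / 2, tolerance = 1e-6)
  }
  hy <- hysteresis_sweep(lin, NULL, "r", c(0.5, 3), n_steps = 25,
                         anchors = list(0.25, 1.5))
  expect_null(hy$bistable_interval)
  expect_equal(hy$up, hy$down, tolerance = 1e-7)
})

test_that("continuation reproduces the cubic normal form's folds", {
  dg <- continue_branch(cubic_factory, NULL, "r", c(-0.6, 0.6),
                        anchors = list(-1.2, 1.2))
  rstar <- 2 / (3 * sqrt(3))
  expect_equal(nrow(dg$folds), 2L)
  expect_equal(sort(dg$folds$param), c(-rstar, rstar), tolerance = 1e-4)
  expect_equal(unname(dg$bistable_interval), c(-rstar, rstar), tolerance = 1e-3)
  # the middle branch is unstable, outer branches stable
  stabs <- do.call(rbind, dg$branches)
  mid <- abs(stabs$x1) < 1 / sqrt(3) - 0.02
  outer <- abs(stabs$x1) > 1 / sqrt(3) + 0.02
  expect_true(all(stabs$stability[mid] == "unstable"))
  expect_true(all(stabs$stability[outer] == "stable"))
})

test_that("hysteresis sweeps agree with continuation within one step", {
  rstar <- 2 / (3 * sqrt(3))
  hy <- hysteresis_sweep(cubic_factory, NULL, "r", c(-0.6, 0.6), n_steps = 61,
                         anchors = list(-1.2, 1.2))
  expect_false(is.null(hy$bistable_interval))
  expect_lt(abs(hy$bistable_interval[1] - (-rstar)), hy$step)
  expect_lt(abs(hy$bistable_interval[2] - rstar), hy$step)

  # Hill toy swept over its production rate k: fold positions from the
  # discriminant (k = 2Kd) and from the transcritical-like lower anchor
  toyf <- function(p) {
    v <- hill_toy_params(k = p, K = 1, d = 1)
    assemble(hill_toy_model(), v)
  }
  dg <- continue_branch(toyf, NULL, "k", c(0.5, 4), anchors = list(0.01, 3.9))
  hy2 <- hysteresis_sweep(toyf, NULL, "k", c(0.5, 4), n_steps = 50,
                          anchors = list(0.01, 3.9))
  expect_false(is.null(dg$bistable_interval))
  expect_false(is.null(hy2$bistable_interval))
  # the saddle-node where the upper branch is born: k = 2Kd = 2
  expect_equal(unname(min(dg$folds$param)), 2, tolerance = 1e-3)
  expect_lt(abs(hy2$bistable_interval[1] - dg$bistable_interval[1]), hy2$step)
})

test_that("unstable branch points repel nearby trajectories", {
  cub <- cubic_factory(0.1)
  root <- uniroot(function(x) 0.1 + x - x^3, c(-0.5, 0.5))$root
  res <- newton_refine(cub, root)
  expect_lt(res$residual_norm, 1e-10)
  expect_gt(max(Re(eigen(cub$jacobian(res$state))$values)), 0.5) # repelling
  for (eps in c(0.02, -0.02)) {
    tr <- integrate_field(cub, res$state + eps, horizon = 100)
    expect_gt(abs(tr$final_state - res$state), 0.3)
  }
})

test_that("diagram step-control refinement leaves interval endpoints in place", {
  coarse <- continue_branch(cubic_factory, NULL, "r", c(-0.6, 0.6),
    step_control = list(initial = 0.02, min = 1e-5, max = 0.1, max_steps = 800),
    anchors = list(-1.2, 1.2))
  fine <- continue_branch(cubic_factory, NULL, "r", c(-0.6, 0.6),
    step_control = list(initial = 0.01, min = 1e-5, max = 0.05, max_steps = 1600),
    anchors = list(-1.2, 1.2))
  expect_lt(max(abs(coarse$bistable_interval - fine$bistable_interval)) /
              diff(range(fine$range)), 0.01)
})

test_that("the NO range reporter requires the bistable regime", {
  lin <- linear_factory(1)
  dg <- continue_branch(lin, NULL, "r", c(0.5, 2), anchors = list(1))
  expect_error(no_range_across_regime(dg), "NO coordinate")
  dg$species <- "NO"
  names(dg$branches[[1]])[3] <- "NO"
  expect_null(no_range_across_regime(dg)) # monostable: empty signal
})

test_that("diagrams export to CSV and JSON", {
  dg <- continue_branch(cubic_factory, NULL, "r", c(-0.6, 0.6),
                        anchors = list(-1.2, 1.2))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_diagram_csv(dg, csv)
  got <- read.csv(csv)
  expect_true(all(c("branch", "param", "stability", "x1") %in% names(got)))
  write_diagram_json(dg, js)
  meta <- jsonlite::read_json(js)
  expect_equal(length(meta$folds), 2)
})
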