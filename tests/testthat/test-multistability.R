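test_that("a single start yields a single attractor and a consistent census", {
  tn <- build_two_node()
  cl <- classify_attractors(tn$model, tn$params, n_starts = 1, seed = 3)
  expect_equal(length(cl$attractors), 1L)
  expect_equal(sum(cl$basin_counts) + cl$nonconverged, 1L)
})

test_that("the census is reproducible and attractors are pairwise separated", {
  b <- build_initial_model()
  a <- classify_attractors(b$model, b$params, n_starts = 15, seed = 17)
  b2 <- classify_attractors(b$model, b$params, n_starts = 15, seed = 17)
  expect_identical(lapply(a$attractors, `[[`, "state"),
                   lapply(b2$attractors, `[[`, "state"))
  expect_identical(a$basin_counts, b2$basin_counts)
  expect_identical(a$assignments, b2$assignments)
  if (length(a$attractors) > 1) {
    d <- state_distance(a$attractors[[1]]$state, a$attractors[[2]]$state)
    expect_gt(d, rn_tolerances()$cluster_tol)
  }
  expect_equal(a$seed, 17L)
})

test_that("extreme-initialization test distinguishes mono- from bistable systems", {
  # monostable birth-death: any two starts converge together
  m <- birth_death_model()
  p <- rn_parameters(c(s = 1, d = 0.1))
  expect_false(extreme_init_test(m, p))
  # identical start vectors are never distinct
  expect_false(extreme_init_test(m, p,
    extremes = list(c(X = 5), c(X = 5))))
  # bistable Hill toy: extreme starts split
  expect_true(extreme_init_test(hill_toy_model(), hill_toy_params(),
    extremes = list(c(X = 0.01), c(X = 10))))
  # both RhoA-NO models are bistable at baseline by the extreme test
  b <- build_initial_model()
  expect_true(extreme_init_test(b$model, b$params))
  bx <- build_extended_model()
  expect_true(extreme_init_test(bx$model, bx$params))
})

test_that("is_bistable combines ensemble and extreme evidence", {
  tn <- build_two_node()
  expect_false(is_bistable(tn$model, tn$params, n_starts = 10, seed = 2))
  expect_true(is_bistable(hill_toy_model(), hill_toy_params(),
                          n_starts = 12, seed = 2))
  # strong antagonism far outside the bistable regime is monostable
  b <- build_initial_model()
  strong <- perturb(b$params, "ki1", 4900) # ki1 -> 50x baseline
  expect_false(is_bistable(b$model, strong, n_starts = 8, seed = 2))
})

test_that("the hill-toy census matches the analytic fixed points", {
  k <- 4; K <- 1; d <- 1
  fps <- hill_toy_fixed_points(k, K, d)
  expect_equal(length(fps), 3L) # 0, unstable, upper stable
  cl <- classify_attractors(hill_toy_model(), hill_toy_params(k, K, d),
                            n_starts = 40, seed = 6)
  expect_equal(length(cl$attractors), 2L)
  got <- sort(vapply(cl$attractors, function(a) unname(a$state), numeric(1)))
  expect_equal(got, c(0, max(fps)), tolerance = 1e-6)
})

test_that("census is invariant when the ensemble doubles", {
  b <- build_initial_model()
  c1 <- classify_attractors(b$model, b$params, n_starts = 30, seed = 5)
  c2 <- classify_attractors(b$model, b$params, n_starts = 60, seed = 5)
  expect_equal(length(c1$attractors), length(c2$attractors))
  # same clusters: match attractors across runs within the clustering tol
  for (a in c1$attractors) {
    d <- vapply(c2$attractors, function(bb) state_distance(a$state, bb$state),
                numeric(1))
    expect_lt(min(d), rn_tolerances()$cluster_tol)
  }
})

test_that("parameter search returns only bistable hits with recorded provenance", {
  # budget 0 is a valid empty search
  expect_identical(search_bistable_parameters(hill_toy_model(),
    hill_toy_params(), budget = 0), list())
  # two-node: no bistability anywhere
  tn <- build_two_node()
  hits <- search_bistable_parameters(tn$model, tn$params, budget = 40,
                                     seed = 10, n_starts = 6)
  expect_identical(hits, list())
  # hill toy around a monostable baseline (k/d = 1.5 < 2K): the bistable
  # region k/d > 2K is within +/-1 decade, so a modest search finds hits
  base <- hill_toy_params(k = 1.5, K = 1, d = 1)
  hits <- search_bistable_parameters(hill_toy_model(), base, budget = 60,
                                     seed = 11, decades = 1, n_starts = 8,
                                     fixed = "nh")
  expect_gt(length(hits), 0)
  for (h in hits) {
    expect_gt(h$values[["k"]] / h$values[["d"]], 2 * h$values[["K"]])
    expect_match(h$provenance, "seed")
  }
  hits2 <- search_bistable_parameters(hill_toy_model(), base, budget = 60,
                                      seed = 11, decades = 1, n_starts = 8,
                                      fixed = "nh")
  expect_identical(lapply(hits, `[[`, "values"), lapply(hits2, `[[`, "values"))
})

test_that("bistability results serialize to JSON", {
  cl <- classify_attractors(hill_toy_model(), hill_toy_params(),
                            n_starts = 15, seed = 3)
  path <- tempfile(fileext = ".json")
  write_bistability_json(cl, path)
  got <- jsonlite::read_json(path)
  expect_equal(got$n_starts, 15)
  expect_equal(length(got$attractors), length(cl$attractors))
})
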