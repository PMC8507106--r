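# Multistart attractor census, extreme-initialization test, and
# parameter-space search for bistability.

#' Census of attractors from a multistart ensemble
#'
#' Draws `n_starts` random initial states (log-uniform per species by
#' default), integrates each to steady state, and clusters the stable final
#' states by relative max-norm distance. Starts that diverge, fail to
#' converge, or land on a marginal/unstable point are counted as
#' `nonconverged`, so `sum(basin_counts) + nonconverged == n_starts`.
#'
#' @param model An [rn_model()].
#' @param params An [rn_parameters()].
#' @param n_starts Ensemble size, >= 1.
#' @param seed Integer seed for the initial-condition draw.
#' @param ic Optional [ic_spec()]; its seed is overridden by `seed`.
#' @param horizon,tol Passed to [find_steady_state()].
#' @param keep_trajectories If TRUE, full trajectories are retained for
#'   plotting the ensemble fan.
#' @return An object of class `rn_bistability`: `attractors` (list of
#'   `rn_steady_state`), `basin_counts`, `nonconverged`, `n_starts`, `seed`,
#'   `assignments`, and optionally `trajectories`.
#' @export
classify_attractors <- function(model, params, n_starts = 100, seed = 1L,
                                ic = NULL, horizon = 1e6,
                                tol = rn_tolerances(),
                                keep_trajectories = FALSE) {
  stopifnot(n_starts >= 1)
  field <- assemble(model, params)
  if (is.null(ic)) ic <- default_ic_spec(field, seed = seed, tol = tol)
  else ic$seed <- as.integer(seed)
  x0s <- draw_initial_conditions(ic, n_starts, field$dimension)
  fits <- vector("list", n_starts)
  trajs <- if (keep_trajectories) vector("list", n_starts) else NULL
  for (i in seq_len(n_starts)) {
    if (keep_trajectories) {
      trajs[[i]] <- integrate_field(field, x0s[[i]], horizon = horizon, tol = tol)
      fits[[i]] <- find_steady_state(field, x0s[[i]], horizon = horizon, tol = tol)
    } else {
      fits[[i]] <- find_steady_state(field, x0s[[i]], horizon = horizon, tol = tol)
    }
  }
  ok <- vapply(fits, function(s) isTRUE(s$stable) && isTRUE(s$converged) &&
                 !isTRUE(s$diverged), logical(1))
  if (!any(ok)) stop("no attractors found: all starts nonconvergent")
  stable_states <- lapply(fits[ok], `[[`, "state")
  cl <- cluster_states(stable_states, cluster_tol = tol$cluster_tol)
  k <- max(cl)
  reps <- lapply(seq_len(k), function(j) fits[ok][[which(cl == j)[1]]])
  assignments <- rep(NA_integer_, n_starts)
  assignments[ok] <- cl
  structure(list(attractors = reps,
                 basin_counts = tabulate(cl, nbins = k),
                 nonconverged = sum(!ok), n_starts = n_starts,
                 seed = as.integer(seed), assignments = assignments,
                 trajectories = trajs, species = field$species),
            class = "rn_bistability")
}

#' @export
print.rn_bistability <- function(x, ...) {
  cat("<rn_bistability> ", length(x$attractors), " attractor(s) from ",
      x$n_starts, " starts (basins: ",
      paste(x$basin_counts, collapse = ", "), "; nonconverged: ",
      x$nonconverged, ")\n", sep = "")
  invisible(x)
}

#' Default initial-condition specification for a model
#'
#' Random levels of all species are drawn log-uniformly from a per-species
#' box spanning the attractors the model actually visits: the steady states
#' reached from the two extreme initializations define a span, and each
#' protein pool is sampled over `[min/100, max*10]` of its span (floored at
#' 1e-4 nM). The rapidly equilibrating messenger activities (NO, cGMP, PKG)
#' are sampled only up to the geometric mid of their span, reflecting that
#' second messengers are transient activities rather than stores. Bounds are
#' fully configurable through [ic_spec()].
#'
#' @param field An `rn_rate_field`.
#' @param seed Integer seed for the draw.
#' @param tol Tolerances used when locating the span-defining steady states.
#' @return An [ic_spec()] with per-species bounds.
#' @export
default_ic_spec <- function(field, seed = 1L, tol = rn_tolerances()) {
  ext <- extreme_initializations(field$species)
  ss <- lapply(ext, function(x0)
    try(find_steady_state(field, pmax(unname(x0[field$species]), 0), tol = tol),
        silent = TRUE))
  ok <- !vapply(ss, inherits, logical(1), "try-error")
  states <- if (any(ok)) {
    do.call(rbind, lapply(ss[ok], function(s) abs(s$state)))
  } else matrix(1, 1, field$dimension)
  ic_bounds_from_states(states, field$species, seed = seed)
}

# Sampling box spanning the located attractors with a decade of margin:
# pools over [min/100, max*10] (floored), messenger activities (NO, cGMP,
# PKG) from basal up to the geometric mid of their attractor levels.
ic_bounds_from_states <- function(states, species, seed = 1L) {
  lo <- pmax(apply(states, 2, min) * 1e-2, 1e-4)
  hi <- pmax(apply(states, 2, max) * 10, lo * 10)
  messengers <- species %in% c("NO", "cGMP", "PKG")
  mid <- exp(colMeans(log(pmax(states, 1e-3))))
  hi[messengers] <- pmax(mid[messengers], lo[messengers] * 10)
  ic_spec(bounds = cbind(lo, hi), seed = seed)
}

#' Synthetic extreme initializations for the RhoA-NO models
#'
#' Two opposed corner states standing in for "NO-high" and "RhoA-high"
#' extreme initializations: the NO-high start puts the relaxation-arm species
#' (Akt/pAkt, eNOS expression, NO, cGMP, PKG) at `hi` and the contractility
#' arm (RhoA, ROCK, tension) at `lo`; the RhoA-high start is the mirror
#' image. These are synthetic constructions of the package, not transcribed
#' measurements.
#'
#' @param species Character vector of state names (from the model).
#' @param lo,hi Low/high concentrations (nM).
#' @return A list with elements `no_high` and `rhoa_high`.
#' @export
extreme_initializations <- function(species, lo = 0.01, hi = 100) {
  relax <- c("Akt", "pAkt", "eNOSm", "eNOS", "peNOS", "NO", "cGMP", "PKG")
  contract <- c("RhoA", "RhoAp", "ROCK", "Tension")
  no_high <- setNames(ifelse(species %in% relax, hi,
                             ifelse(species %in% contract, lo, lo)), species)
  rhoa_high <- setNames(ifelse(species %in% contract, hi,
                               ifelse(species %in% relax, lo, lo)), species)
  if (!any(species %in% c(relax, contract))) {
    # generic model: use opposite corners of the default concentration range
    no_high <- setNames(rep(lo, length(species)), species)
    rhoa_high <- setNames(rep(hi, length(species)), species)
  }
  list(no_high = no_high, rhoa_high = rhoa_high)
}

#' Extreme-initialization bistability test
#'
#' Integrates from two opposed extreme starts and reports whether they reach
#' distinct stable steady states (separation above the clustering tolerance).
#' Nonconvergence of either start yields `NA` ("inconclusive"), distinct
#' from `FALSE`.
#'
#' @param model,params Model and parameters.
#' @param extremes Optional list of two named start vectors; defaults to
#'   [extreme_initializations()] over the model's species.
#' @param horizon,tol As in [find_steady_state()].
#' @return `TRUE`, `FALSE`, or `NA` (inconclusive).
#' @export
extreme_init_test <- function(model, params, extremes = NULL,
                              horizon = 1e6, tol = rn_tolerances()) {
  field <- assemble(model, params)
  .extreme_test(field, extremes, horizon, tol)$distinct
}

# shared worker: returns the verdict and the located steady states, so
# callers can reuse them (e.g. to scale the random-initialization box)
.extreme_test <- function(field, extremes = NULL, horizon = 1e6,
                          tol = rn_tolerances()) {
  if (is.null(extremes)) extremes <- extreme_initializations(field$species)
  stopifnot(length(extremes) == 2L)
  ss <- lapply(extremes, function(x0)
    try(find_steady_state(field, pmax(unname(x0[field$species]), 0),
                          horizon = horizon, tol = tol), silent = TRUE))
  ok <- vapply(ss, function(s) !inherits(s, "try-error") && isTRUE(s$stable) &&
                 isTRUE(s$converged) && !isTRUE(s$diverged), logical(1))
  if (!all(ok)) return(list(distinct = NA, states = ss[ok]))
  list(distinct = state_distance(ss[[1]]$state, ss[[2]]$state) >= tol$cluster_tol,
       states = ss)
}

#' Is the model bistable?
#'
#' The conjunction of two independent lines of evidence: the multistart
#' ensemble reports at least two distinct stable attractors AND the
#' extreme-initialization test reaches two distinct states. The conjunction
#' is stricter than either test alone and guards against missed basins.
#'
#' @param model,params Model and parameters.
#' @param n_starts Ensemble size for the multistart census.
#' @param seed Integer seed.
#' @param horizon,tol Numerical controls.
#' @return `TRUE`, `FALSE`, or `NA` when the evidence is inconclusive
#'   (extreme starts did not converge).
#' @export
is_bistable <- function(model, params, n_starts = 100, seed = 1L,
                        horizon = 1e6, tol = rn_tolerances()) {
  field <- assemble(model, params)
  ext <- .extreme_test(field, horizon = horizon, tol = tol)
  if (is.na(ext$distinct)) return(NA)
  if (!ext$distinct) return(FALSE) # conjunction already decided
  # reuse the extreme steady states as the span of the sampling box
  states <- do.call(rbind, lapply(ext$states, function(s) abs(s$state)))
  ic <- ic_bounds_from_states(states, field$species, seed = seed)
  # a second ensemble cannot create a false positive (a monostable system
  # never yields two stable clusters), so retry once before concluding the
  # random starts all fell into one basin
  for (attempt in 1:2) {
    cls <- try(classify_attractors(model, params, n_starts = n_starts,
                                   seed = seed + (attempt - 1L) * 7919L,
                                   ic = ic, horizon = horizon, tol = tol),
               silent = TRUE)
    if (inherits(cls, "try-error")) return(NA)
    if (length(cls$attractors) >= 2) return(TRUE)
  }
  FALSE
}

#' Search parameter space for bistability
#'
#' Samples parameter sets log-uniformly around the baseline and returns those
#' for which [is_bistable()] is `TRUE`. Every returned set carries its draw
#' seed in its provenance, so any hit can be regenerated exactly.
#'
#' @param model An [rn_model()].
#' @param baseline An [rn_parameters()] to sample around.
#' @param budget Number of sampled sets, >= 0.
#' @param seed Integer root seed.
#' @param decades Sampling half-width in decades.
#' @param n_starts Ensemble size used inside [is_bistable()].
#' @param fixed Parameter names held at baseline (structural constants).
#' @param horizon,tol Numerical controls.
#' @return List of bistable [rn_parameters()] (possibly empty).
#' @export
search_bistable_parameters <- function(model, baseline, budget, seed = 1L,
                                       decades = 2, n_starts = 24,
                                       fixed = "npkg",
                                       horizon = 1e6, tol = rn_tolerances()) {
  stopifnot(budget >= 0)
  if (budget == 0) return(list())
  sets <- sample_parameter_sets(baseline, decades = decades, n = budget,
                                seed = seed, fixed = fixed)
  hits <- list()
  for (i in seq_along(sets)) {
    bi <- try(is_bistable(model, sets[[i]], n_starts = n_starts,
                          seed = split_seed(seed, paste0("search", i)),
                          horizon = horizon, tol = tol), silent = TRUE)
    if (isTRUE(bi)) hits[[length(hits) + 1L]] <- sets[[i]]
  }
  hits
}

#' Serialize a bistability result to JSON
#'
#' @param result An `rn_bistability`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bistability_json <- function(result, path) {
  obj <- list(
    n_starts = result$n_starts, seed = result$seed,
    nonconverged = result$nonconverged,
    basin_counts = result$basin_counts,
    attractors = lapply(result$attractors, function(a) list(
      state = as.list(a$state), residual_norm = a$residual_norm,
      stable = a$stable))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export an ensemble trajectory fan to CSV
#'
#' Long format: run index, time, one column per species. Requires
#' `keep_trajectories = TRUE` in [classify_attractors()].
#'
#' @param result An `rn_bistability` with trajectories.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(result, path) {
  if (is.null(result$trajectories)) stop("ensemble was run without keep_trajectories")
  dfs <- lapply(seq_along(result$trajectories), function(i) {
    tr <- result$trajectories[[i]]
    data.frame(run = i, time = tr$times, tr$states, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' Plot a multistart trajectory fan
#'
#' One line per ensemble run for a chosen species, coloured by attractor
#' assignment (the style of a multistart convergence figure).
#'
#' @param result An `rn_bistability` with trajectories.
#' @param species Species to plot (default "RhoA" if present).
#' @param log_time Use log10 time axis.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_ensemble <- function(result, species = NULL, log_time = TRUE, ...) {
  if (is.null(result$trajectories)) stop("ensemble was run without keep_trajectories")
  if (is.null(species)) {
    species <- if ("RhoA" %in% result$species) "RhoA" else result$species[1]
  }
  cols <- ifelse(is.na(result$assignments), "grey",
                 c("firebrick", "steelblue", "darkgreen", "orange")[
                   ((result$assignments - 1) %% 4) + 1])
  tmax <- max(vapply(result$trajectories, function(t) max(t$times), numeric(1)))
  ymax <- max(vapply(result$trajectories, function(t) max(t$states[, species]),
                     numeric(1)))
  plot(NA, xlim = c(if (log_time) 1e-2 else 0, tmax), ylim = c(0, ymax * 1.05),
       log = if (log_time) "x" else "", xlab = "time (model units)",
       ylab = paste(species, "(nM)"), ...)
  for (i in seq_along(result$trajectories)) {
    tr <- result$trajectories[[i]]
    tt <- tr$times; if (log_time) tt <- pmax(tt, 1e-2)
    graphics::lines(tt, tr$states[, species], col = cols[i])
  }
  invisible(result)
}
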