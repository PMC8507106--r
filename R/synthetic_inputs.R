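# Generators for everything the analysis consumes: random initial-condition
# ensembles, single-parameter percentage perturbations, and log-uniform
# parameter-set samples. All generation is seed-deterministic; one root seed
# per experiment is split into independent per-task streams.

#' Specify how initial conditions are drawn
#'
#' @param bounds Two-column matrix (lo, hi) with one row per species, or a
#'   single `c(lo, hi)` recycled to all species. Concentrations in nM.
#' @param scale `"logarithmic"` (default; concentrations span decades) or
#'   `"linear"`.
#' @param seed Integer seed.
#' @return An object of class `rn_ic_spec`.
#' @export
ic_spec <- function(bounds = c(1e-2, 1e2), scale = c("logarithmic", "linear"),
                    seed = 1L) {
  scale <- match.arg(scale)
  if (is.null(dim(bounds))) bounds <- matrix(bounds, nrow = 1)
  if (ncol(bounds) != 2 || any(!is.finite(bounds))) {
    stop("bounds must be finite (lo, hi) pairs")
  }
  if (any(bounds[, 1] > bounds[, 2])) stop("invalid bounds: lo > hi")
  if (scale == "logarithmic" && any(bounds[, 1] <= 0)) {
    stop("logarithmic scale requires strictly positive lower bounds")
  }
  if (scale == "linear" && any(bounds[, 1] < 0)) {
    stop("initial concentrations must be nonnegative")
  }
  structure(list(bounds = bounds, scale = scale, seed = as.integer(seed)),
            class = "rn_ic_spec")
}

# Derive a reproducible child seed from a root seed and a stream label.
# Keeps results below 2^31 and independent across labels.
split_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483563) + 1L
}

#' Draw a random initial-condition ensemble
#'
#' Each component is drawn independently within its bounds, uniformly on the
#' stated scale (log-uniform by default). Reproducible under a fixed seed.
#'
#' @param spec An [ic_spec()].
#' @param n Number of state vectors, >= 1.
#' @param dimension State dimension (bounds rows are recycled to it).
#' @return List of `n` numeric vectors.
#' @export
draw_initial_conditions <- function(spec, n, dimension) {
  stopifnot(inherits(spec, "rn_ic_spec"), n >= 1, dimension >= 1)
  b <- spec$bounds
  if (nrow(b) == 1) b <- b[rep(1, dimension), , drop = FALSE]
  if (nrow(b) != dimension) stop("bounds rows must be 1 or match dimension")
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  lapply(seq_len(n), function(i) {
    r <- runif(dimension)
    if (spec$scale == "logarithmic") {
      exp(log(b[, 1]) + r * (log(b[, 2]) - log(b[, 1])))
    } else {
      b[, 1] + r * (b[, 2] - b[, 1])
    }
  })
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Perturb one parameter by a signed percentage
#'
#' Returns a copy of `params` with `values[name] * (1 + percent/100)` and all
#' other entries unchanged; provenance is annotated.
#'
#' @param params An [rn_parameters()].
#' @param name Parameter to perturb.
#' @param percent Signed percentage; must be > -100.
#' @return A new [rn_parameters()].
#' @export
perturb <- function(params, name, percent) {
  stopifnot(inherits(params, "rn_parameters"))
  if (!name %in% names(params$values)) stop("unknown parameter: ", name)
  if (percent <= -100) stop("perturbation must keep the value positive (percent > -100)")
  v <- params$values
  v[[name]] <- v[[name]] * (1 + percent / 100)
  rn_parameters(v, units = params$units,
                provenance = sprintf("%s; %s %+g%%", params$provenance, name, percent))
}

#' Sample parameter sets log-uniformly around a baseline
#'
#' Each parameter is drawn independently and log-uniformly over
#' `baseline * 10^[-decades, +decades]`. Used by the bistability
#' parameter-space search.
#'
#' @param baseline An [rn_parameters()].
#' @param decades Half-width of the sampling range in decades, > 0.
#' @param n Number of sets, >= 0.
#' @param seed Integer seed.
#' @param fixed Names never resampled (e.g. structural constants).
#' @return List of `n` [rn_parameters()].
#' @export
sample_parameter_sets <- function(baseline, decades, n, seed = 1L,
                                  fixed = "npkg") {
  stopifnot(inherits(baseline, "rn_parameters"), n >= 0, decades >= 0)
  if (n == 0) return(list())
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  free <- setdiff(names(baseline$values), fixed)
  lapply(seq_len(n), function(i) {
    v <- baseline$values
    v[free] <- v[free] * 10^runif(length(free), -decades, decades)
    rn_parameters(v, units = baseline$units,
                  provenance = sprintf("sampled (seed %d, draw %d, +/-%g decades)",
                                       seed, i, decades))
  })
}
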