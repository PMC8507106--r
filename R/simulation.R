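# Time integration (stiff-capable, with steady-state early exit) and
# steady-state location/classification.

#' Default numerical tolerances
#'
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param ss_tol Steady-state criterion: converged when
#'   `max|dx/dt| < ss_tol * (1 + max|x|)`, sustained over a trailing window
#'   of 1% of the horizon.
#' @param newton_tol Residual max-norm target of Newton refinement.
#' @param stability_margin Eigenvalue real parts below `-stability_margin`
#'   are stable, above `+stability_margin` unstable, in between marginal.
#' @param cluster_tol Relative max-norm distance below which two steady
#'   states are the same attractor.
#' @return A list of tolerances.
#' @export
rn_tolerances <- function(rtol = 1e-8, atol = 1e-8, ss_tol = 1e-9,
                          newton_tol = 1e-10, stability_margin = 1e-8,
                          cluster_tol = 1e-3) {
  list(rtol = rtol, atol = atol, ss_tol = ss_tol, newton_tol = newton_tol,
       stability_margin = stability_margin, cluster_tol = cluster_tol)
}

#' Integrate a rate field
#'
#' Stiff-capable integration (deSolve's lsoda with root-triggered early
#' termination). Integration stops early once the steady-state criterion
#' `max|f| < ss_tol * (1 + max|x|)` holds and is confirmed over a trailing
#' window of 1% of the horizon. Components dipping below `-atol` are
#' flagged, never clipped.
#'
#' @param field An `rn_rate_field` from [assemble()].
#' @param x0 Nonnegative initial state of length `field$dimension`.
#' @param horizon Final time (model time units).
#' @param tol Tolerances from [rn_tolerances()].
#' @param n_save Number of saved time points.
#' @return An object of class `rn_trajectory`: `times`, `states` (time x
#'   species matrix), `converged`, `diverged`, `negative_excursion`,
#'   `final_state`.
#' @export
integrate_field <- function(field, x0, horizon = 1e6, tol = rn_tolerances(),
                            n_save = 200) {
  stopifnot(inherits(field, "rn_rate_field"))
  if (length(x0) != field$dimension) {
    stop("x0 must have length ", field$dimension)
  }
  if (any(!is.finite(x0))) stop("x0 must be finite")
  if (isTRUE(field$nonneg) && any(x0 < 0)) {
    stop("x0 must be nonnegative for a reaction-network field")
  }
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be > 0")

  f <- field$f
  dfun <- function(t, y, parms) list(f(t, y))
  rootfun <- function(t, y, parms) {
    if (any(!is.finite(y))) return(0)
    max(abs(f(t, y))) - tol$ss_tol * (1 + max(abs(y)))
  }
  window <- 0.01 * horizon

  piece <- function(x_start, t_start, t_end) {
    times <- unique(c(t_start, seq(t_start, t_end, length.out = max(2L, n_save))))
    out <- try(suppressWarnings(
      deSolve::lsodar(y = x_start, times = times, func = dfun,
                      parms = NULL, rtol = tol$rtol, atol = tol$atol,
                      rootfunc = rootfun, maxsteps = 50000)), silent = TRUE)
    if (inherits(out, "try-error")) {
      stop("integration failed: ", attr(out, "condition")$message)
    }
    out
  }

  t_cur <- 0; x_cur <- x0
  times_all <- numeric(0); states_all <- NULL
  converged <- FALSE; diverged <- FALSE
  for (attempt in 1:6) {
    out <- piece(x_cur, t_cur, horizon)
    tt <- out[, 1]; ss <- out[, -1, drop = FALSE]
    times_all <- c(times_all, tt)
    states_all <- rbind(states_all, ss)
    x_cur <- ss[nrow(ss), ]; t_cur <- tt[length(tt)]
    if (any(!is.finite(x_cur))) { diverged <- TRUE; break }
    hit_root <- !is.null(attr(out, "iroot")) || t_cur < horizon * (1 - 1e-12)
    if (!hit_root) { # reached horizon
      converged <- rootfun(t_cur, x_cur, NULL) <= 0
      break
    }
    # confirm the criterion over a trailing window before declaring steady
    t_conf <- min(t_cur + window, horizon)
    if (t_conf <= t_cur * (1 + 1e-12)) { converged <- TRUE; break }
    conf <- try(suppressWarnings(
      deSolve::lsoda(y = x_cur, times = c(t_cur, t_conf), func = dfun,
                     parms = NULL, rtol = tol$rtol, atol = tol$atol,
                     maxsteps = 50000)), silent = TRUE)
    if (inherits(conf, "try-error")) { break }
    x_conf <- conf[nrow(conf), -1]
    if (any(!is.finite(x_conf))) { diverged <- TRUE; break }
    times_all <- c(times_all, t_conf)
    states_all <- rbind(states_all, x_conf)
    x_cur <- x_conf; t_cur <- t_conf
    if (rootfun(t_cur, x_cur, NULL) <= 0) { converged <- TRUE; break }
    if (t_cur >= horizon * (1 - 1e-12)) break
  }

  keep <- !duplicated(times_all)
  times_all <- times_all[keep]
  states_all <- states_all[keep, , drop = FALSE]
  colnames(states_all) <- field$species
  structure(list(times = times_all, states = states_all,
                 converged = converged, diverged = diverged,
                 negative_excursion = any(states_all < -tol$atol, na.rm = TRUE),
                 final_state = setNames(as.numeric(x_cur), field$species)),
            class = "rn_trajectory")
}

#' @export
print.rn_trajectory <- function(x, ...) {
  cat("<rn_trajectory> ", length(x$times), " points to t=",
      signif(max(x$times), 4),
      if (x$converged) " (converged)" else " (not converged)",
      if (x$diverged) " [DIVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Export a trajectory to CSV
#'
#' @param traj An `rn_trajectory`.
#' @param path Output file (time column plus one column per species).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Locate and classify a steady state
#'
#' Integrates from `x0` until the steady-state criterion holds, then refines
#' the final state by damped Newton iteration on the rate field (the damping
#' guarantees the residual max-norm never increases). Stability is classified
#' from the Jacobian eigenvalues: stable if all real parts are below
#' `-stability_margin`, marginal if any real part lies within the margin.
#'
#' @param field An `rn_rate_field`.
#' @param x0 Initial state.
#' @param horizon,tol As in [integrate_field()].
#' @return An object of class `rn_steady_state`: `state`, `residual_norm`,
#'   `stable`, `marginal`, `refined`, `converged`, `diverged`, `eigenvalues`.
#' @export
find_steady_state <- function(field, x0, horizon = 1e6, tol = rn_tolerances()) {
  traj <- integrate_field(field, x0, horizon = horizon, tol = tol, n_save = 5)
  if (traj$diverged) {
    return(structure(list(state = traj$final_state, residual_norm = Inf,
                          stable = FALSE, marginal = FALSE, refined = FALSE,
                          converged = FALSE, diverged = TRUE,
                          eigenvalues = complex(0)),
                     class = "rn_steady_state"))
  }
  x <- traj$final_state
  res <- newton_refine(field, x, tol = tol)
  J <- field$jacobian(res$state)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  stable <- all(re < -tol$stability_margin)
  marginal <- any(abs(re) <= tol$stability_margin)
  structure(list(state = setNames(res$state, field$species),
                 residual_norm = res$residual_norm,
                 stable = stable && !marginal, marginal = marginal,
                 refined = res$refined,
                 converged = traj$converged || res$refined,
                 diverged = FALSE, eigenvalues = ev),
            class = "rn_steady_state")
}

#' Damped Newton refinement of a near-steady state
#'
#' @param field An `rn_rate_field`.
#' @param x Starting state (near a fixed point).
#' @param tol Tolerances; iteration targets `newton_tol` residual max-norm.
#' @param max_iter Iteration budget.
#' @return List `state`, `residual_norm`, `refined` (TRUE iff the target was
#'   reached).
#' @export
newton_refine <- function(field, x, tol = rn_tolerances(), max_iter = 30) {
  f <- function(z) field$f(0, z)
  r <- f(x); rn <- max(abs(r))
  for (it in seq_len(max_iter)) {
    if (!is.finite(rn) || rn < tol$newton_tol) break
    J <- field$jacobian(x)
    step <- try(solve(J, -r), silent = TRUE)
    if (inherits(step, "try-error")) break
    lambda <- 1; improved <- FALSE
    for (h in 1:12) {
      xn <- x + lambda * step
      rnew <- f(xn); rnn <- max(abs(rnew))
      if (is.finite(rnn) && rnn < rn) {
        x <- xn; r <- rnew; rn <- rnn; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(state = x, residual_norm = rn, refined = is.finite(rn) && rn < tol$newton_tol)
}

#' @export
print.rn_steady_state <- function(x, ...) {
  cat("<rn_steady_state> residual ", signif(x$residual_norm, 3),
      if (x$stable) ", stable" else if (x$marginal) ", marginal" else ", unstable",
      if (x$diverged) " [DIVERGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Relative max-norm distance between two states
#'
#' `max|x - y| / (1 + max(|x|, |y|))`; the denominator keeps the measure
#' meaningful near the origin.
#'
#' @param x,y State vectors.
#' @return Nonnegative scalar.
#' @export
state_distance <- function(x, y) {
  max(abs(x - y)) / (1 + max(abs(x), abs(y)))
}

#' Greedy clustering of states by relative max-norm distance
#'
#' @param states List of state vectors.
#' @param cluster_tol Distance threshold.
#' @return Integer cluster assignment per state (1-based); cluster centers
#'   are the first member encountered.
#' @export
cluster_states <- function(states, cluster_tol = 1e-3) {
  centers <- list(); assign <- integer(length(states))
  for (i in seq_along(states)) {
    hit <- 0L
    for (j in seq_along(centers)) {
      if (state_distance(states[[i]], centers[[j]]) < cluster_tol) { hit <- j; break }
    }
    if (hit == 0L) { centers[[length(centers) + 1L]] <- states[[i]]; hit <- length(centers) }
    assign[i] <- hit
  }
  assign
}
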