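# One-parameter equilibrium continuation (pseudo-arclength with tangent
# prediction and damped Newton correction), fold detection by tangent
# reversal with bisection refinement, and an independent quasi-static
# hysteresis sweep used to cross-check the bistable interval.

# A rate field with one designated free parameter. `model` is either an
# rn_model (rebuilt with the swept parameter substituted) or a factory
# function(p) -> rn_rate_field for raw vector fields such as normal forms.
# Memoizes the last parameter value so finite differences over the state
# reuse one assembly.
parametric_field <- function(model, params, parameter_name, probe_p = 1) {
  cache_p <- NA_real_; cache_field <- NULL
  if (is.function(model)) {
    probe <- model(probe_p)
    at <- function(p) {
      if (!identical(p, cache_p)) { cache_field <<- model(p); cache_p <<- p }
      cache_field
    }
    sp <- probe$species; dim <- probe$dimension; nonneg <- isTRUE(probe$nonneg)
  } else {
    if (!parameter_name %in% names(params$values)) {
      stop("unknown parameter: ", parameter_name)
    }
    at <- function(p) {
      if (!identical(p, cache_p)) {
        v <- params$values; v[[parameter_name]] <- p
        cache_field <<- assemble(model, rn_parameters(v, provenance = "sweep"))
        cache_p <<- p
      }
      cache_field
    }
    sp <- species_names(model); dim <- length(sp); nonneg <- TRUE
  }
  list(at = at, fx = function(x, p) at(p)$f(0, x),
       jx = function(x, p) at(p)$jacobian(x),
       dimension = dim, species = sp, nonneg = nonneg)
}

# Tangent of the equilibrium curve at (x, p) in the scaled metric. Solved
# from the bordered system [J fp; orient] t = e_{n+1} with the previous
# tangent (or a signed unit p-direction) as the border: this keeps the
# tangent direction continuous through regions where the Jacobian is nearly
# singular, where a raw nullspace computation rotates unpredictably.
.branch_tangent <- function(pf, x, p, scale, orient) {
  n <- length(x)
  J <- pf$jx(x, p)
  hp <- 1e-6 * (1 + abs(p))
  if (isTRUE(pf$nonneg) && p - hp <= 0) hp <- p / 2
  fp <- (pf$fx(x, p + hp) - pf$fx(x, p - hp)) / (2 * hp)
  A <- rbind(cbind(J * rep(scale[1:n], each = n), fp * scale[n + 1]), orient)
  t_raw <- try(solve(A, c(rep(0, n), 1)), silent = TRUE)
  if (inherits(t_raw, "try-error")) { # singular border: fall back to nullspace
    sv <- svd(cbind(J, fp), nu = 0, nv = n + 1)
    t_raw <- sv$v[, n + 1] * scale
  }
  ts <- t_raw / sqrt(sum(t_raw^2))
  if (sum(ts * orient) < 0) ts <- -ts
  ts
}

# One predictor-corrector step of length h (in the scaled metric) from (x, p)
# along tangent ts. Returns NULL on corrector failure (including evaluation
# errors, e.g. a trial point with a nonpositive rate constant).
.plc_step <- function(pf, x, p, ts, h, scale, newton_tol = 1e-9, max_iter = 12) {
  out <- try(.plc_step_inner(pf, x, p, ts, h, scale, newton_tol, max_iter),
             silent = TRUE)
  if (inherits(out, "try-error")) NULL else out
}

.plc_step_inner <- function(pf, x, p, ts, h, scale, newton_tol, max_iter) {
  n <- length(x)
  u <- c(x / scale[1:n], p / scale[n + 1]) # scaled coordinates
  u_pred <- u + h * ts
  ucur <- u_pred
  for (it in seq_len(max_iter)) {
    xc <- ucur[1:n] * scale[1:n]; pc <- ucur[n + 1] * scale[n + 1]
    fval <- pf$fx(xc, pc)
    g <- c(fval, sum(ts * (ucur - u_pred)))
    if (max(abs(g)) < newton_tol) {
      # corrector must stay near the predictor; a distant solution means the
      # iteration jumped to another sheet of the manifold
      if (sqrt(sum((ucur - u_pred)^2)) > max(2 * abs(h), 1e-8)) return(NULL)
      return(list(x = xc, p = pc))
    }
    J <- pf$jx(xc, pc)
    hp <- 1e-6 * (1 + abs(pc))
    if (isTRUE(pf$nonneg) && pc - hp <= 0) hp <- pc / 2
    fp <- (pf$fx(xc, pc + hp) - pf$fx(xc, pc - hp)) / (2 * hp)
    # augmented Jacobian in scaled coordinates
    A <- rbind(cbind(J * rep(scale[1:n], each = n), fp * scale[n + 1]), ts)
    step <- try(solve(A, -g), silent = TRUE)
    if (inherits(step, "try-error")) return(NULL)
    ucur <- ucur + step
    if (any(!is.finite(ucur))) return(NULL)
  }
  xc <- ucur[1:n] * scale[1:n]; pc <- ucur[n + 1] * scale[n + 1]
  if (max(abs(pf$fx(xc, pc))) < 1e-7) list(x = xc, p = pc) else NULL
}

.stability_of <- function(pf, x, p, margin = 1e-8) {
  re <- Re(eigen(pf$jx(x, p), only.values = TRUE)$values)
  if (all(re < -margin)) "stable" else if (any(abs(re) <= margin)) "marginal" else "unstable"
}

#' Continue an equilibrium branch over one parameter
#'
#' Traces the steady-state manifold through folds by pseudo-arclength
#' stepping (tangent prediction, Newton correction, adaptive step control),
#' anchored at both endpoints of the range so interior folds cannot be
#' missed. Stability is labelled from Jacobian eigenvalues; folds are
#' detected by reversal of the tangent's parameter component and refined by
#' bisection to a relative parameter tolerance of 1e-6.
#'
#' @param model An [rn_model()], or a factory `function(p)` returning an
#'   `rn_rate_field` (for raw vector fields; `anchors` is then required and
#'   `params` is ignored).
#' @param params Baseline [rn_parameters()].
#' @param parameter_name Swept parameter.
#' @param range `c(lo, hi)` with `lo < hi`.
#' @param step_control List: `initial`, `min`, `max` step sizes as fractions
#'   of the range, and `max_steps`.
#' @param anchors Optional list of starting states; defaults to the extreme
#'   initializations, integrated to steady state at each endpoint.
#' @param tol Tolerances from [rn_tolerances()].
#' @return An object of class `rn_bifurcation`: `parameter_name`, `branches`
#'   (list of data.frames with `param`, `stability`, one column per species),
#'   `folds` (data.frame), `bistable_interval` (`c(lo, hi)` or `NULL`),
#'   `range`.
#' @export
continue_branch <- function(model, params, parameter_name, range,
                            step_control = list(initial = 0.01, min = 1e-5,
                                                max = 0.05, max_steps = 1500),
                            anchors = NULL, tol = rn_tolerances()) {
  stopifnot(length(range) == 2, range[1] < range[2])
  pf <- parametric_field(model, params, parameter_name,
                         probe_p = mean(range))
  n <- pf$dimension
  lo <- range[1]; hi <- range[2]; width <- hi - lo

  # anchor steady states at both endpoints (monostable endpoints give one
  # anchor each; bistable endpoints can give two)
  if (is.null(anchors)) {
    if (!pf$nonneg) stop("no anchor: raw fields require explicit anchor states")
    anchors <- extreme_initializations(pf$species)
  }
  anchor_pts <- list()
  for (p_end in c(lo, hi)) {
    fld <- pf$at(p_end)
    for (x0 in anchors) {
      x0 <- if (!is.null(names(x0)) && all(pf$species %in% names(x0))) {
        unname(x0[pf$species])
      } else as.numeric(x0)
      if (pf$nonneg) x0 <- pmax(x0, 0)
      ss <- if (pf$nonneg) {
        try(find_steady_state(fld, x0, tol = tol), silent = TRUE)
      } else {
        try(c(newton_refine(fld, x0, tol = tol), list(diverged = FALSE)),
            silent = TRUE)
      }
      if (inherits(ss, "try-error") || !ss$refined || isTRUE(ss$diverged)) next
      dup <- any(vapply(anchor_pts, function(a)
        a$p == p_end && state_distance(a$x, ss$state) < tol$cluster_tol,
        logical(1)))
      if (!dup) anchor_pts[[length(anchor_pts) + 1L]] <- list(x = unname(ss$state),
                                                              p = p_end)
    }
  }
  if (!length(anchor_pts)) stop("no anchor: no steady state located at either range endpoint")

  # per-component scaling keeps the arclength metric balanced between state
  # directions (which span orders of magnitude) and the parameter direction
  amat <- do.call(rbind, lapply(anchor_pts, function(a) abs(a$x)))
  xscale <- 1 + apply(amat, 2, max)
  scale <- c(xscale, width)

  trace_from <- function(x0, p0, dir) {
    ts <- .branch_tangent(pf, x0, p0, scale,
                          orient = c(rep(0, n), dir))
    h <- step_control$initial
    pts <- list(list(x = x0, p = p0, tp = ts[n + 1],
                     stab = .stability_of(pf, x0, p0, tol$stability_margin)))
    folds <- list()
    x <- x0; p <- p0
    for (k in seq_len(step_control$max_steps)) {
      res <- NULL
      while (is.null(res)) {
        res <- .plc_step(pf, x, p, ts, h, scale)
        if (is.null(res)) {
          h <- h / 2
          if (h < step_control$min) break
        }
      }
      if (is.null(res)) {
        warning("continuation step-size collapse at ", parameter_name,
                " = ", signif(p, 6), "; partial diagram returned")
        break
      }
      margin <- 0.02 * width
      lo_lim <- if (pf$nonneg) max(lo - margin, lo / 2) else lo - margin
      if (res$p < lo_lim || res$p > hi + margin) break # discard overshoot
      ts_new <- .branch_tangent(pf, res$x, res$p, scale, orient = ts)
      tp_old <- ts[n + 1]; tp_new <- ts_new[n + 1]
      if (sign(tp_old) != 0 && sign(tp_new) != 0 && sign(tp_old) != sign(tp_new)) {
        fold <- .refine_fold(pf, x, p, ts, h, scale, n)
        if (!is.null(fold)) folds[[length(folds) + 1L]] <- fold
      }
      x <- res$x; p <- res$p; ts <- ts_new
      pts[[length(pts) + 1L]] <- list(x = x, p = p, tp = tp_new,
                                      stab = .stability_of(pf, x, p, tol$stability_margin))
      h <- min(h * 1.3, step_control$max)
    }
    list(points = pts, folds = folds)
  }

  all_branches <- list(); all_folds <- list()
  for (a in anchor_pts) {
    dir <- if (a$p == lo) 1 else -1
    tr <- trace_from(a$x, a$p, dir)
    all_branches[[length(all_branches) + 1L]] <- tr$points
    all_folds <- c(all_folds, tr$folds)
  }

  branches <- lapply(all_branches, function(pts) {
    df <- data.frame(param = vapply(pts, `[[`, numeric(1), "p"),
                     stability = vapply(pts, `[[`, character(1), "stab"))
    states <- do.call(rbind, lapply(pts, `[[`, "x"))
    colnames(states) <- pf$species
    cbind(df, as.data.frame(states))
  })

  folds <- .dedupe_folds(all_folds, width, pf$species)
  interval <- .bistable_interval(branches, folds, c(lo, hi))
  structure(list(parameter_name = parameter_name, branches = branches,
                 folds = folds, bistable_interval = interval,
                 range = c(lo, hi), species = pf$species,
                 method = "pseudo-arclength"),
            class = "rn_bifurcation")
}

# Bisection refinement of a fold bracketed between the point (x, p) (tangent
# ts) and the accepted next point one step h away, to 1e-6 relative in the
# parameter.
.refine_fold <- function(pf, x, p, ts, h, scale, n) {
  a <- list(x = x, p = p, ts = ts); h_cur <- h
  sign_a <- sign(ts[n + 1])
  p_b <- NA_real_; x_b <- NULL
  for (it in 1:40) {
    h_cur <- h_cur / 2
    res <- .plc_step(pf, a$x, a$p, a$ts, h_cur, scale)
    if (is.null(res)) break
    ts_m <- .branch_tangent(pf, res$x, res$p, scale, orient = a$ts)
    if (sign(ts_m[n + 1]) == sign_a) {
      a <- list(x = res$x, p = res$p, ts = ts_m)
    } else {
      p_b <- res$p; x_b <- res$x
    }
    if (!is.na(p_b) && abs(p_b - a$p) <= 1e-6 * max(1, abs(a$p))) break
    if (h_cur < 1e-12) break
  }
  if (is.null(x_b)) list(p = a$p, x = a$x) else
    list(p = (a$p + p_b) / 2, x = (a$x + x_b) / 2)
}

.dedupe_folds <- function(folds, width, species) {
  if (!length(folds)) {
    return(data.frame(param = numeric(0)))
  }
  keep <- list()
  for (f in folds) {
    dup <- any(vapply(keep, function(g)
      abs(g$p - f$p) < 1e-4 * width && state_distance(g$x, f$x) < 1e-2,
      logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- f
  }
  df <- data.frame(param = vapply(keep, `[[`, numeric(1), "p"))
  st <- do.call(rbind, lapply(keep, `[[`, "x"))
  colnames(st) <- species
  cbind(df, as.data.frame(st))
}

# The parameter range over which >= 2 stable branch points coexist, measured
# from the traced branches; fold positions sharpen the endpoints.
.bistable_interval <- function(branches, folds, range) {
  pts <- do.call(rbind, lapply(branches, function(b) b[, c("param", "stability")]))
  stable_p <- sort(pts$param[pts$stability == "stable"])
  if (length(stable_p) < 2) return(NULL)
  window <- max(diff(range) / 400, stats::median(diff(stable_p), na.rm = TRUE))
  grid <- seq(range[1], range[2], length.out = 401)
  # stable segments (consecutive stable branch points), for interpolation
  segs <- do.call(rbind, lapply(branches, function(b) {
    st <- as.matrix(b[, -(1:2), drop = FALSE])
    ok <- b$stability == "stable"
    i <- which(ok[-nrow(b)] & ok[-1])
    if (!length(i)) return(NULL)
    cbind(p1 = b$param[i], p2 = b$param[i + 1], i1 = i,
          branch_offset = 0)[, , drop = FALSE]
  }))
  seg_states <- lapply(branches, function(b) as.matrix(b[, -(1:2), drop = FALSE]))
  seg_branch <- unlist(lapply(seq_along(branches), function(j) {
    b <- branches[[j]]; ok <- b$stability == "stable"
    rep(j, sum(ok[-nrow(b)] & ok[-1]))
  }))
  n_stable <- vapply(grid, function(p) {
    if (is.null(segs)) return(0L)
    lo_s <- pmin(segs[, "p1"], segs[, "p2"]); hi_s <- pmax(segs[, "p1"], segs[, "p2"])
    hit <- which(lo_s - 1e-12 <= p & p <= hi_s + 1e-12 & hi_s > lo_s)
    if (!length(hit)) return(0L)
    # interpolate each crossing segment to exactly p, then cluster: distinct
    # clusters = coexisting stable states (overlapping traces merge)
    st <- lapply(hit, function(k) {
      b <- seg_states[[seg_branch[k]]]; i <- segs[k, "i1"]
      w <- (p - segs[k, "p1"]) / (segs[k, "p2"] - segs[k, "p1"])
      (1 - w) * b[i, ] + w * b[i + 1, ]
    })
    max(cluster_states(st, cluster_tol = 1e-2))
  }, integer(1))
  if (!any(n_stable >= 2)) return(NULL)
  lo <- min(grid[n_stable >= 2]); hi <- max(grid[n_stable >= 2])
  # snap to refined folds when they bracket the same region
  fp <- folds$param
  if (length(fp)) {
    near_lo <- fp[abs(fp - lo) <= 2 * window]
    near_hi <- fp[abs(fp - hi) <= 2 * window]
    if (length(near_lo)) lo <- min(near_lo)
    if (length(near_hi)) hi <- max(near_hi)
  }
  c(lo = lo, hi = hi)
}

#' Quasi-static hysteresis sweep
#'
#' Steps the parameter up and then down across the range, integrating to
#' steady state at each step from the previous step's final state. The
#' parameter region where the up- and down-sweep states disagree delimits the
#' bistable interval; for a valid diagram it must agree with
#' [continue_branch()]'s interval to within one step width.
#'
#' @param model,params,parameter_name,range As in [continue_branch()].
#' @param n_steps Number of sweep steps.
#' @param horizon Integration horizon per step.
#' @param anchors Optional list of two starting states (up-sweep start,
#'   down-sweep start); defaults to the extreme initializations. Required for
#'   raw field factories.
#' @param tol Tolerances.
#' @return An object of class `rn_hysteresis`: `parameter_name`, `grid`,
#'   `up` and `down` state matrices, `bistable_interval`, `step`,
#'   `nonconverged` (flagged steps).
#' @export
hysteresis_sweep <- function(model, params, parameter_name, range,
                             n_steps = 80, horizon = 1e5, anchors = NULL,
                             tol = rn_tolerances()) {
  stopifnot(length(range) == 2, range[1] < range[2], n_steps >= 2)
  pf <- parametric_field(model, params, parameter_name,
                         probe_p = mean(range))
  if (is.null(anchors)) {
    if (!pf$nonneg) stop("raw fields require explicit anchor states")
    anchors <- extreme_initializations(pf$species)
  }
  clamp <- function(x) if (pf$nonneg) pmax(x, 0) else x
  grid <- seq(range[1], range[2], length.out = n_steps)
  sweep_one <- function(pseq) {
    # anchor at the first parameter value, keeping the attractor the sweep
    # direction would naturally occupy
    fld <- pf$at(pseq[1])
    x0 <- if (pseq[1] <= pseq[length(pseq)]) anchors[[1]] else anchors[[2]]
    x0 <- if (!is.null(names(x0)) && all(pf$species %in% names(x0))) {
      unname(x0[pf$species])
    } else as.numeric(x0)
    ss <- find_steady_state(fld, clamp(x0), tol = tol)
    x <- unname(ss$state)
    states <- matrix(NA_real_, length(pseq), pf$dimension)
    flagged <- logical(length(pseq))
    for (i in seq_along(pseq)) {
      fld <- pf$at(pseq[i])
      ss <- try(find_steady_state(fld, clamp(x), horizon = horizon, tol = tol),
                silent = TRUE)
      if (inherits(ss, "try-error") || ss$diverged || !ss$refined) {
        flagged[i] <- TRUE # keep last converged state and continue
      } else {
        x <- unname(ss$state)
      }
      states[i, ] <- x
    }
    list(states = states, flagged = flagged)
  }
  up <- sweep_one(grid)
  down <- sweep_one(rev(grid))
  down_states <- down$states[rev(seq_len(n_steps)), , drop = FALSE]
  colnames(up$states) <- colnames(down_states) <- pf$species
  differ <- vapply(seq_len(n_steps), function(i)
    state_distance(up$states[i, ], down_states[i, ]) >= tol$cluster_tol,
    logical(1))
  interval <- if (any(differ)) {
    c(lo = min(grid[differ]), hi = max(grid[differ]))
  } else NULL
  structure(list(parameter_name = parameter_name, grid = grid,
                 up = up$states, down = down_states,
                 bistable_interval = interval,
                 step = diff(range) / (n_steps - 1),
                 nonconverged = up$flagged | rev(down$flagged),
                 species = pf$species, method = "hysteresis"),
            class = "rn_hysteresis")
}

#' NO extremes of the stable branches over the bistable regime
#'
#' @param diagram An `rn_bifurcation` whose state includes the `NO`
#'   coordinate.
#' @param species Coordinate to report (default `"NO"`).
#' @return `c(min, max)` of the stable-branch values over the bistable
#'   interval, or `NULL` when the interval is empty.
#' @export
no_range_across_regime <- function(diagram, species = "NO") {
  stopifnot(inherits(diagram, "rn_bifurcation"))
  if (!species %in% diagram$species) {
    stop("diagram does not contain the ", species, " coordinate")
  }
  iv <- diagram$bistable_interval
  if (is.null(iv)) return(NULL)
  vals <- unlist(lapply(diagram$branches, function(b) {
    sel <- b$stability == "stable" & b$param >= iv[1] & b$param <= iv[2]
    b[sel, species]
  }))
  if (!length(vals)) return(NULL)
  c(min = min(vals), max = max(vals))
}

#' @export
print.rn_bifurcation <- function(x, ...) {
  cat("<rn_bifurcation> ", x$parameter_name, " in [",
      signif(x$range[1], 4), ", ", signif(x$range[2], 4), "]: ",
      length(x$branches), " branch trace(s), ", nrow(x$folds), " fold(s)",
      sep = "")
  if (!is.null(x$bistable_interval)) {
    cat(", bistable in [", signif(x$bistable_interval[1], 4), ", ",
        signif(x$bistable_interval[2], 4), "]", sep = "")
  } else cat(", no bistable interval")
  cat("\n")
  invisible(x)
}

#' Export a bifurcation diagram to CSV
#'
#' @param diagram An `rn_bifurcation` or `rn_hysteresis`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diagram_csv <- function(diagram, path) {
  if (inherits(diagram, "rn_bifurcation")) {
    df <- do.call(rbind, lapply(seq_along(diagram$branches), function(i)
      cbind(branch = i, diagram$branches[[i]])))
  } else {
    df <- rbind(
      data.frame(branch = "up", param = diagram$grid, stability = "swept",
                 as.data.frame(diagram$up)),
      data.frame(branch = "down", param = diagram$grid, stability = "swept",
                 as.data.frame(diagram$down)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Summarize folds and the bistable interval to JSON
#' @param diagram An `rn_bifurcation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diagram_json <- function(diagram, path) {
  obj <- list(parameter = diagram$parameter_name,
              range = as.numeric(diagram$range),
              folds = diagram$folds$param,
              bistable_interval = if (is.null(diagram$bistable_interval)) NULL
                                  else as.numeric(diagram$bistable_interval))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Plot a bifurcation diagram
#'
#' Steady-state values of one species against the swept parameter; stable
#' points solid, unstable dotted, folds marked.
#'
#' @param x An `rn_bifurcation`.
#' @param species Coordinate to plot (default `"NO"` if present).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rn_bifurcation <- function(x, species = NULL, ...) {
  if (is.null(species)) species <- if ("NO" %in% x$species) "NO" else x$species[1]
  allp <- unlist(lapply(x$branches, `[[`, "param"))
  allv <- unlist(lapply(x$branches, `[[`, species))
  plot(NA, xlim = range(allp), ylim = range(allv),
       xlab = x$parameter_name, ylab = paste(species, "(nM)"), ...)
  for (b in x$branches) {
    st <- b$stability == "stable"
    graphics::points(b$param[st], b[st, species], pch = 16, cex = 0.4)
    graphics::points(b$param[!st], b[!st, species], pch = 1, cex = 0.3, col = "grey40")
  }
  if (nrow(x$folds)) {
    graphics::points(x$folds$param, x$folds[, species], pch = 17, col = "red")
  }
  if (!is.null(x$bistable_interval)) {
    graphics::abline(v = x$bistable_interval, lty = 3, col = "blue")
  }
  invisible(x)
}
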