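# Single-parameter robustness of bistability: perturb one rate constant at a
# time by signed percentages and record whether bistability survives.

#' Single-parameter robustness grid
#'
#' For each parameter and each signed percentage level, perturbs that single
#' parameter multiplicatively and re-tests bistability. A parameter "retains
#' bistability at p%" iff both the +p% and the -p% perturbations are
#' bistable (the stricter both-signs reading); the raw signed columns are
#' kept so the one-sided convention remains computable. Nonconvergent cells
#' are recorded as `NA` ("inconclusive"), distinct from `FALSE`.
#'
#' @param model An [rn_model()].
#' @param params Baseline [rn_parameters()]; must be assembled and, for a
#'   meaningful matrix, bistable.
#' @param levels Unsigned percentage levels; 0 is always included.
#' @param parameter_names Parameters to perturb (default: all perturbable,
#'   i.e. everything except the structural Hill coefficient).
#' @param n_starts Ensemble size inside each [is_bistable()] call. The
#'   default is reduced relative to the headline census because the grid
#'   multiplies it by hundreds of cells.
#' @param seed Root seed, split per cell.
#' @param horizon,tol Numerical controls.
#' @return An object of class `rn_robustness`: `parameter_names`, `levels`
#'   (signed, sorted), `signed` (logical matrix parameter x signed level,
#'   `NA` = inconclusive), `retained` (parameter x unsigned level, both-signs
#'   rule), `baseline_bistable`.
#' @export
single_parameter_robustness <- function(model, params,
                                        levels = c(5, 10, 15, 20, 25, 30, 40),
                                        parameter_names = NULL,
                                        n_starts = 8, seed = 1L,
                                        horizon = 1e6, tol = rn_tolerances()) {
  levels <- sort(unique(abs(levels)))
  levels <- setdiff(levels, 0)
  if (is.null(parameter_names)) {
    parameter_names <- setdiff(names(params$values), "npkg")
  }
  stopifnot(all(parameter_names %in% names(params$values)))
  base <- is_bistable(model, params, n_starts = n_starts,
                      seed = split_seed(seed, "baseline"),
                      horizon = horizon, tol = tol)
  signed_levels <- c(-rev(levels), 0, levels)
  signed <- matrix(NA, length(parameter_names), length(signed_levels),
                   dimnames = list(parameter_names, paste0(signed_levels, "%")))
  for (i in seq_along(parameter_names)) {
    pm <- parameter_names[i]
    for (j in seq_along(signed_levels)) {
      lv <- signed_levels[j]
      if (lv == 0) { signed[i, j] <- isTRUE(base); next }
      pset <- perturb(params, pm, lv)
      bi <- try(is_bistable(model, pset, n_starts = n_starts,
                            seed = split_seed(seed, paste0(pm, lv)),
                            horizon = horizon, tol = tol), silent = TRUE)
      signed[i, j] <- if (inherits(bi, "try-error")) NA else bi
    }
  }
  retained <- matrix(NA, length(parameter_names), length(levels),
                     dimnames = list(parameter_names, paste0(levels, "%")))
  for (j in seq_along(levels)) {
    pos <- signed[, paste0(levels[j], "%")]
    neg <- signed[, paste0(-levels[j], "%")]
    retained[, j] <- pos & neg
  }
  structure(list(parameter_names = parameter_names, levels = levels,
                 signed_levels = signed_levels, signed = signed,
                 retained = retained, baseline_bistable = isTRUE(base),
                 seed = as.integer(seed), n_starts = n_starts),
            class = "rn_robustness")
}

#' Count parameters retaining bistability at a level
#'
#' Both-signs rule: a parameter counts iff bistability survived both the
#' positive and the negative perturbation at that level.
#'
#' @param matrix An `rn_robustness`.
#' @param level Unsigned percentage present in the matrix.
#' @return Integer count.
#' @export
count_retaining <- function(matrix, level) {
  stopifnot(inherits(matrix, "rn_robustness"))
  key <- paste0(abs(level), "%")
  if (!key %in% colnames(matrix$retained)) {
    stop("level ", level, "% not present in the robustness matrix")
  }
  sum(matrix$retained[, key], na.rm = TRUE)
}

#' Fraction of parameters retaining bistability at a level
#' @inheritParams count_retaining
#' @return Numeric fraction in [0, 1].
#' @export
retention_fraction <- function(matrix, level) {
  count_retaining(matrix, level) / length(matrix$parameter_names)
}

#' @export
print.rn_robustness <- function(x, ...) {
  cat("<rn_robustness> ", length(x$parameter_names), " parameters x levels ",
      paste(x$levels, collapse = "/"), "%; baseline bistable: ",
      x$baseline_bistable, "\n", sep = "")
  for (lv in x$levels) {
    cat(sprintf("  +/-%g%%: %d/%d retained\n", lv, count_retaining(x, lv),
                length(x$parameter_names)))
  }
  invisible(x)
}

#' Export a robustness matrix to CSV
#'
#' Rows = parameters, columns = signed levels, cells in
#' {TRUE, FALSE, inconclusive}.
#'
#' @param matrix An `rn_robustness`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_robustness_csv <- function(matrix, path) {
  cells <- apply(matrix$signed, c(1, 2), function(v)
    if (is.na(v)) "inconclusive" else if (v) "true" else "false")
  utils::write.csv(data.frame(parameter = rownames(cells), cells,
                              check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}

#' Plot a robustness matrix
#'
#' Black/white heatmap (white = bistable, black = not, grey = inconclusive)
#' with the unperturbed 0% column highlighted in red.
#'
#' @param x An `rn_robustness`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.rn_robustness <- function(x, ...) {
  m <- x$signed
  z <- t(apply(m, c(1, 2), function(v) if (is.na(v)) 0.5 else as.numeric(v)))
  np <- nrow(m); nl <- ncol(m)
  graphics::image(seq_len(nl), seq_len(np), z[, rev(seq_len(np)), drop = FALSE],
                  col = grey.colors(64, start = 0, end = 1), zlim = c(0, 1),
                  axes = FALSE, xlab = "perturbation", ylab = "", ...)
  graphics::axis(1, at = seq_len(nl), labels = colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(np), labels = rev(rownames(m)), las = 1,
                 cex.axis = 0.6)
  zero_col <- which(colnames(m) == "0%")
  graphics::abline(v = c(zero_col - 0.5, zero_col + 0.5), col = "red", lwd = 2)
  invisible(x)
}
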