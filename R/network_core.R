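#' @importFrom stats runif setNames
NULL

# Rate-law kinds understood by the assembler. "synthesis" is zeroth order,
# "decay" first order in its single substrate; "mass_action" multiplies
# substrate concentrations (with stoichiometric powers) and activator
# concentrations; "michaelis_menten" and "hill" saturate in a driver species
# (the first substrate, or a modifier of type "driver" for catalytic
# production that consumes nothing).
.rn_kinds <- c("synthesis", "decay", "mass_action", "michaelis_menten", "hill")

#' Define a species
#'
#' A named state variable of a reaction network. Concentrations are in nM
#' (tension, when present, is a dimensionless nonnegative surrogate).
#'
#' @param name Unique species identifier.
#' @param conc Initial concentration, nonnegative (nM).
#' @param role Free annotation, e.g. "enzyme", "second messenger",
#'   "mechanical surrogate".
#' @return An object of class `rn_species`.
#' @export
rn_species <- function(name, conc = 0, role = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(conc) || length(conc) != 1L || is.na(conc) || conc < 0) {
    stop("species '", name, "': concentration must be a nonnegative number")
  }
  structure(list(name = name, conc = as.numeric(conc), role = role),
            class = "rn_species")
}

#' Define a reaction
#'
#' A single production/consumption step with a typed rate law. Parameters are
#' referenced by name and resolved against a [rn_parameters()] set at
#' assembly time.
#'
#' @param id Unique reaction identifier.
#' @param kind One of `"synthesis"`, `"decay"`, `"mass_action"`,
#'   `"michaelis_menten"`, `"hill"`.
#' @param substrates Named numeric vector: species consumed, with
#'   stoichiometry. `decay` requires exactly one substrate.
#' @param products Named numeric vector: species produced, with stoichiometry.
#' @param modifiers Optional list of `list(species=, type=, param=)` entries.
#'   Type `"activator"` multiplies the rate by the modifier concentration
#'   (catalysis); `"inhibitor"` divides by `1 + ki * [I]` where `ki` is the
#'   modifier's `param`; `"driver"` names the saturating species of a
#'   Michaelis-Menten or Hill law that is not itself consumed.
#' @param params Named character vector mapping rate-law roles to parameter
#'   names. Roles: `k` (synthesis/decay/mass_action); `vmax`, `km`
#'   (michaelis_menten); `vmax`, `km`, `n` (hill).
#' @return An object of class `rn_reaction`.
#' @export
rn_reaction <- function(id, kind, substrates = numeric(), products = numeric(),
                        modifiers = list(), params = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!kind %in% .rn_kinds) {
    stop("reaction '", id, "': unknown rate-law kind '", kind, "'")
  }
  substrates <- .rn_named_num(substrates, id, "substrates")
  products <- .rn_named_num(products, id, "products")
  need <- switch(kind,
    synthesis = "k", decay = "k", mass_action = "k",
    michaelis_menten = c("vmax", "km"),
    hill = c("vmax", "km", "n"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("reaction '", id, "' (", kind, "): missing rate-law role(s) ",
         paste(missing, collapse = ", "))
  }
  if (kind == "decay" && length(substrates) != 1L) {
    stop("reaction '", id, "': first-order decay requires exactly one substrate")
  }
  for (m in modifiers) {
    if (!all(c("species", "type") %in% names(m)) ||
        !m$type %in% c("activator", "inhibitor", "driver")) {
      stop("reaction '", id, "': modifiers must have species and type ",
           "activator/inhibitor/driver")
    }
    if (m$type == "inhibitor" && is.null(m$param)) {
      stop("reaction '", id, "': inhibitor modifier requires a param")
    }
  }
  if (kind %in% c("michaelis_menten", "hill") && length(substrates) == 0L &&
      !any(vapply(modifiers, function(m) m$type == "driver", logical(1)))) {
    stop("reaction '", id, "': saturating law needs a substrate or a driver modifier")
  }
  structure(list(id = id, kind = kind, substrates = substrates,
                 products = products, modifiers = modifiers,
                 params = params),
            class = "rn_reaction")
}

.rn_named_num <- function(x, id, what) {
  if (length(x) == 0L) return(setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))) || any(x <= 0)) {
    stop("reaction '", id, "': ", what,
         " must be a named numeric vector with positive stoichiometry")
  }
  x
}

#' Define a parameter set
#'
#' @param values Named numeric vector of strictly positive rate constants.
#' @param units Optional named character vector of unit strings.
#' @param provenance Free annotation per value or for the whole set, e.g.
#'   `"search-derived"` or `"perturbed"`.
#' @return An object of class `rn_parameters`.
#' @export
rn_parameters <- function(values, units = NULL, provenance = "unspecified") {
  if (!is.numeric(values) || is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("parameter values must be a named numeric vector")
  }
  if (anyDuplicated(names(values))) stop("duplicate parameter names")
  if (any(!is.finite(values)) || any(values <= 0)) {
    bad <- names(values)[!is.finite(values) | values <= 0]
    stop("parameter(s) not strictly positive: ", paste(bad, collapse = ", "))
  }
  structure(list(values = values, units = units, provenance = provenance),
            class = "rn_parameters")
}

#' Define a model
#'
#' @param name Model identifier.
#' @param species List of [rn_species()], order defines the state vector.
#' @param reactions List of [rn_reaction()].
#' @param inputs Named numeric vector of clamped constants (e.g. the constant
#'   HGF stimulus). Clamped names never contribute an ODE.
#' @param notes Free provenance annotation.
#' @return An object of class `rn_model`.
#' @export
rn_model <- function(name, species, reactions, inputs = numeric(), notes = "") {
  sp_names <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(sp_names)) {
    stop("species names must be unique; duplicated: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))
  }
  rx_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rx_ids)) stop("reaction ids must be unique")
  if (length(inputs) && (is.null(names(inputs)) || any(!nzchar(names(inputs))))) {
    stop("inputs must be a named numeric vector")
  }
  if (any(names(inputs) %in% sp_names)) {
    stop("clamped input name collides with a species name")
  }
  structure(list(name = name, species = species, reactions = reactions,
                 inputs = inputs, notes = notes),
            class = "rn_model")
}

#' Count the reactions of a model
#'
#' @param model An [rn_model()].
#' @return Integer number of reaction records.
#' @export
count_reactions <- function(model) {
  stopifnot(inherits(model, "rn_model"))
  length(model$reactions)
}

#' Species names of a model
#' @param model An [rn_model()].
#' @return Character vector in state-vector order.
#' @export
species_names <- function(model) {
  vapply(model$species, function(s) s$name, character(1))
}

#' Assemble a model into an evaluable rate field
#'
#' Resolves every reaction's parameter names against `params`, checks species
#' references, and compiles the network into a vector field
#' `f(t, x) -> dx/dt` with one equation per non-clamped species, plus a
#' central finite-difference Jacobian.
#'
#' @param model An [rn_model()].
#' @param params An [rn_parameters()] resolving every referenced name.
#' @return An object of class `rn_rate_field` with elements `dimension`,
#'   `species` (state names), `f(t, x)`, `jacobian(x)`, `model`, `params`.
#' @export
assemble <- function(model, params) {
  stopifnot(inherits(model, "rn_model"), inherits(params, "rn_parameters"))
  sp <- species_names(model)
  n <- length(sp)
  pv <- params$values
  if (any(names(pv) %in% sp) || any(names(pv) %in% names(model$inputs))) {
    stop("species/parameter name collision: ",
         paste(intersect(names(pv), c(sp, names(model$inputs))), collapse = ", "))
  }
  idx_of <- function(nm) match(nm, sp)
  clamped <- model$inputs

  resolve <- function(pname, rid) {
    if (!pname %in% names(pv)) {
      stop("missing parameter '", pname, "' (reaction '", rid, "')")
    }
    unname(pv[[pname]])
  }

  compiled <- lapply(model$reactions, function(r) {
    all_sp <- c(names(r$substrates), names(r$products),
                vapply(r$modifiers, `[[`, character(1), "species"))
    unknown <- setdiff(all_sp, c(sp, names(clamped)))
    if (length(unknown)) {
      stop("reaction '", r$id, "' references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    if (any(names(r$substrates) %in% names(clamped))) {
      stop("reaction '", r$id, "': clamped inputs cannot be consumed")
    }
    kpar <- vapply(r$params, resolve, numeric(1), rid = r$id)
    act_i <- integer(0); act_c <- 1
    inh_i <- integer(0); inh_k <- numeric(0)
    drv_i <- NA_integer_; drv_c <- NA_real_
    for (m in r$modifiers) {
      if (m$type == "activator") {
        if (m$species %in% names(clamped)) {
          act_c <- act_c * unname(clamped[[m$species]])
        } else act_i <- c(act_i, idx_of(m$species))
      } else if (m$type == "inhibitor") {
        ki <- resolve(m$param, r$id)
        if (m$species %in% names(clamped)) {
          act_c <- act_c / (1 + ki * unname(clamped[[m$species]]))
        } else { inh_i <- c(inh_i, idx_of(m$species)); inh_k <- c(inh_k, ki) }
      } else { # driver
        if (m$species %in% names(clamped)) drv_c <- unname(clamped[[m$species]])
        else drv_i <- idx_of(m$species)
      }
    }
    if (r$kind %in% c("michaelis_menten", "hill") && is.na(drv_i) && is.na(drv_c)) {
      drv_i <- idx_of(names(r$substrates)[1])
    }
    net <- numeric(n)
    for (s in names(r$substrates)) net[idx_of(s)] <- net[idx_of(s)] - r$substrates[[s]]
    for (s in names(r$products)) {
      if (s %in% names(clamped)) next
      net[idx_of(s)] <- net[idx_of(s)] + r$products[[s]]
    }
    net_i <- which(net != 0)
    list(kind = match(r$kind, .rn_kinds), kpar = kpar,
         sub_i = idx_of(names(r$substrates)), sub_s = unname(r$substrates),
         act_i = act_i, act_c = act_c, inh_i = inh_i, inh_k = inh_k,
         drv_i = drv_i, drv_c = drv_c,
         net_i = net_i, net_s = net[net_i])
  })

  f <- function(t, x) {
    dx <- numeric(n)
    for (r in compiled) {
      a <- r$act_c
      if (length(r$act_i)) a <- a * prod(x[r$act_i])
      if (length(r$inh_i)) a <- a / prod(1 + r$inh_k * x[r$inh_i])
      kp <- r$kpar
      rate <- switch(r$kind,
        a * kp[["k"]],                                   # synthesis
        a * kp[["k"]] * x[r$sub_i[1L]],                  # decay
        a * kp[["k"]] * prod(x[r$sub_i]^r$sub_s),        # mass action
        {                                                # Michaelis-Menten
          D <- if (is.na(r$drv_i)) r$drv_c else max(x[r$drv_i], 0)
          a * kp[["vmax"]] * D / (kp[["km"]] + D)
        },
        {                                                # Hill
          D <- if (is.na(r$drv_i)) r$drv_c else max(x[r$drv_i], 0)
          Dn <- D^kp[["n"]]
          a * kp[["vmax"]] * Dn / (kp[["km"]]^kp[["n"]] + Dn)
        })
      dx[r$net_i] <- dx[r$net_i] + r$net_s * rate
    }
    dx
  }

  jac <- function(x) fd_jacobian(function(z) f(0, z), x)

  structure(list(dimension = n, species = sp, f = f, jacobian = jac,
                 model = model, params = params, nonneg = TRUE),
            class = "rn_rate_field")
}

#' Construct a rate field from a raw derivative function
#'
#' Wraps an arbitrary ODE right-hand side in the same container that
#' [assemble()] produces, so generic vector fields (normal forms, toy
#' models) can be fed to the simulation, multistability and bifurcation
#' machinery. Unlike assembled reaction networks, raw fields permit negative
#' states.
#'
#' @param f Function `(t, x) -> dx/dt` returning a vector of length
#'   `dimension`.
#' @param dimension State dimension.
#' @param species Optional state names (default `x1, x2, ...`).
#' @param jacobian Optional Jacobian `function(x)`; central finite
#'   differences of `f` by default.
#' @return An `rn_rate_field`.
#' @export
rate_field <- function(f, dimension, species = NULL, jacobian = NULL) {
  if (is.null(species)) species <- paste0("x", seq_len(dimension))
  stopifnot(length(species) == dimension)
  jac <- if (is.null(jacobian)) {
    function(x) fd_jacobian(function(z) f(0, z), x)
  } else jacobian
  structure(list(dimension = dimension, species = species, f = f,
                 jacobian = jac, model = NULL, params = NULL, nonneg = FALSE),
            class = "rn_rate_field")
}

#' Central finite-difference Jacobian
#'
#' @param fun Function mapping a state vector to a vector of equal length.
#' @param x Point of evaluation.
#' @param rel_h Relative step size.
#' @return Square numeric matrix d fun_i / d x_j.
#' @export
fd_jacobian <- function(fun, x, rel_h = 1e-6) {
  n <- length(x)
  f0 <- fun(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- rel_h * (1 + abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fun(xp) - fun(xm)) / (2 * h)
  }
  J
}

#' @export
print.rn_model <- function(x, ...) {
  cat("<rn_model> ", x$name, ": ", length(x$species), " species, ",
      length(x$reactions), " reactions", sep = "")
  if (length(x$inputs)) {
    cat(", clamped: ", paste(names(x$inputs), signif(x$inputs, 3),
                             sep = "=", collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
print.rn_parameters <- function(x, ...) {
  cat("<rn_parameters> ", length(x$values), " values (",
      paste(utils::head(names(x$values), 6), collapse = ", "),
      if (length(x$values) > 6) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' @export
print.rn_rate_field <- function(x, ...) {
  cat("<rn_rate_field> dimension", x$dimension, "over",
      paste(utils::head(x$species, 5), collapse = ", "),
      if (x$dimension > 5) "..." else "", "\n")
  invisible(x)
}
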