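# Concrete model builders: the two-node mutual-antagonism motif, the
# biochemical RhoA-NO network (31 reactions, 11 states) and its
# tension-extended variant (12 states, 36 rate parameters).

#' Two-node mutual-antagonism model
#'
#' Two species A and B with zeroth-order production, first-order degradation,
#' and mass-action mutual inhibition:
#' `dA/dt = ksynthA - kdegA*A - kiB*A*B`, `dB/dt = ksynthB - kdegB*B - kiA*A*B`
#' (`kiA` is the rate constant of A's inhibition of B, and vice versa).
#' For all strictly positive constants this system has exactly one
#' nonnegative steady state and is monostable; see [two_node_steady_state()].
#'
#' @param ksynthA,kdegA,ksynthB,kdegB Production/degradation constants, > 0.
#' @param kiA,kiB Inhibition constants, >= 0 (0 decouples the species).
#' @return A list with elements `model` and `params`.
#' @export
build_two_node <- function(ksynthA = 1, kdegA = 1, ksynthB = 1, kdegB = 1,
                           kiA = 1, kiB = 1) {
  v <- c(ksynthA = ksynthA, kdegA = kdegA, ksynthB = ksynthB, kdegB = kdegB,
         kiA = kiA, kiB = kiB)
  if (any(!is.finite(v)) || any(v[1:4] <= 0) || any(v[5:6] < 0)) {
    stop("two-node constants must be positive (kiA/kiB may be zero)")
  }
  # rn_parameters requires strictly positive values; a zero inhibition
  # constant is represented by omitting the inhibition reaction.
  rx <- list(
    rn_reaction("synthA", "synthesis", products = c(A = 1), params = c(k = "ksynthA")),
    rn_reaction("degA", "decay", substrates = c(A = 1), params = c(k = "kdegA")),
    rn_reaction("synthB", "synthesis", products = c(B = 1), params = c(k = "ksynthB")),
    rn_reaction("degB", "decay", substrates = c(B = 1), params = c(k = "kdegB"))
  )
  if (kiA > 0) rx <- c(rx, list(
    rn_reaction("inhibB_byA", "mass_action", substrates = c(B = 1),
                modifiers = list(list(species = "A", type = "activator")),
                params = c(k = "kiA"))))
  if (kiB > 0) rx <- c(rx, list(
    rn_reaction("inhibA_byB", "mass_action", substrates = c(A = 1),
                modifiers = list(list(species = "B", type = "activator")),
                params = c(k = "kiB"))))
  model <- rn_model("two_node",
                    list(rn_species("A", 0), rn_species("B", 0)),
                    rx, notes = "minimal mutual-antagonism motif, mass action")
  params <- rn_parameters(v[v > 0], provenance = "two-node constants")
  list(model = model, params = params)
}

#' Closed-form steady state of the two-node model
#'
#' Eliminating A from the steady-state conditions gives a quadratic in B,
#' `-kdegB*kiB*B^2 + (ksynthB*kiB - kdegB*kdegA - kiA*ksynthA)*B
#'  + ksynthB*kdegA = 0`, whose root product is negative, so exactly one
#' root is positive: the system is structurally monostable. Returns that
#' unique nonnegative steady state.
#'
#' @param ksynthA,kdegA,ksynthB,kdegB,kiA,kiB Constants as in
#'   [build_two_node()].
#' @return Named vector `c(A=, B=)`.
#' @export
two_node_steady_state <- function(ksynthA, kdegA, ksynthB, kdegB, kiA, kiB) {
  if (kiA == 0 && kiB == 0) {
    return(c(A = ksynthA / kdegA, B = ksynthB / kdegB))
  }
  if (kiB == 0) { # A decoupled
    A <- ksynthA / kdegA
    return(c(A = A, B = ksynthB / (kdegB + kiA * A)))
  }
  a <- -kdegB * kiB
  b <- ksynthB * kiB - kdegB * kdegA - kiA * ksynthA
  cc <- ksynthB * kdegA
  disc <- b^2 - 4 * a * cc
  # cancellation-free quadratic: q = -(b + sign(b) sqrt(disc))/2, roots q/a
  # and cc/q; the root product is negative, so exactly one is positive
  q <- -(b + sign(b) * sqrt(disc)) / 2
  if (b == 0) q <- -sqrt(disc) / 2
  roots <- c(q / a, cc / q)
  B <- max(roots)
  c(A = ksynthA / (kdegA + kiB * B), B = B)
}

# --- RhoA-NO network ---------------------------------------------------------

# Reaction table shared by the initial and extended models. One rate constant
# per reaction; ki1 (ROCK-catalyzed inactivation of phospho-Akt) and ki2
# (RhoA-catalyzed destabilization of eNOS mRNA) are the two antagonism
# constants swept in the bifurcation analyses. PKG activation by cGMP is the
# single ultrasensitive (Hill) step; its half-saturation constant is Kmcgmp
# and its Hill coefficient (npkg = 2) is structural, not a perturbable rate.
.rhono_reactions <- function() {
  act <- function(sp) list(list(species = sp, type = "activator"))
  list(
    # RhoA activation/inactivation and Ser188 phosphorylation by PKG
    rn_reaction("R01_rhoa_activation_hgf", "synthesis", products = c(RhoA = 1),
                modifiers = act("HGF"), params = c(k = "k1")),
    rn_reaction("R02_rhoa_activation_basal", "synthesis", products = c(RhoA = 1),
                params = c(k = "k2")),
    rn_reaction("R03_rhoa_inactivation", "decay", substrates = c(RhoA = 1),
                params = c(k = "kdeg1")),
    rn_reaction("R04_rhoa_phosphorylation_pkg", "mass_action",
                substrates = c(RhoA = 1), products = c(RhoAp = 1),
                modifiers = act("PKG"), params = c(k = "k3")),
    rn_reaction("R05_rhoap_dephosphorylation", "mass_action",
                substrates = c(RhoAp = 1), products = c(RhoA = 1),
                params = c(k = "k4")),
    rn_reaction("R06_rhoap_degradation", "decay", substrates = c(RhoAp = 1),
                params = c(k = "kdeg2")),
    # ROCK expression/activity driven by active RhoA
    rn_reaction("R07_rock_synthesis_rhoa", "synthesis", products = c(ROCK = 1),
                modifiers = act("RhoA"), params = c(k = "k12")),
    rn_reaction("R08_rock_synthesis_basal", "synthesis", products = c(ROCK = 1),
                params = c(k = "k5")),
    rn_reaction("R09_rock_degradation", "decay", substrates = c(ROCK = 1),
                params = c(k = "kdeg4")),
    # Akt pool and its HGF-driven phosphorylation, antagonized by ROCK (ki1)
    rn_reaction("R10_akt_synthesis", "synthesis", products = c(Akt = 1),
                params = c(k = "k6")),
    rn_reaction("R11_akt_degradation", "decay", substrates = c(Akt = 1),
                params = c(k = "kdeg3")),
    rn_reaction("R12_akt_phosphorylation_hgf", "mass_action",
                substrates = c(Akt = 1), products = c(pAkt = 1),
                modifiers = act("HGF"), params = c(k = "k7")),
    rn_reaction("R13_akt_phosphorylation_basal", "mass_action",
                substrates = c(Akt = 1), products = c(pAkt = 1),
                params = c(k = "k8")),
    rn_reaction("R14_pakt_dephosphorylation", "mass_action",
                substrates = c(pAkt = 1), products = c(Akt = 1),
                params = c(k = "k9")),
    rn_reaction("R15_pakt_inactivation_rock", "mass_action",
                substrates = c(pAkt = 1), products = c(Akt = 1),
                modifiers = act("ROCK"), params = c(k = "ki1")),
    rn_reaction("R16_pakt_degradation", "decay", substrates = c(pAkt = 1),
                params = c(k = "kdeg5")),
    # eNOS expression, antagonized at the mRNA level by RhoA (ki2)
    rn_reaction("R17_enosm_synthesis", "synthesis", products = c(eNOSm = 1),
                params = c(k = "k10")),
    rn_reaction("R18_enosm_degradation", "decay", substrates = c(eNOSm = 1),
                params = c(k = "kdeg6")),
    rn_reaction("R19_enosm_destabilization_rhoa", "mass_action",
                substrates = c(eNOSm = 1), modifiers = act("RhoA"),
                params = c(k = "ki2")),
    rn_reaction("R20_enos_translation", "synthesis", products = c(eNOS = 1),
                modifiers = act("eNOSm"), params = c(k = "k11")),
    rn_reaction("R21_enos_degradation", "decay", substrates = c(eNOS = 1),
                params = c(k = "kdeg7")),
    # eNOS Ser1177 phosphorylation by phospho-Akt
    rn_reaction("R22_enos_phosphorylation_pakt", "mass_action",
                substrates = c(eNOS = 1), products = c(peNOS = 1),
                modifiers = act("pAkt"), params = c(k = "k13")),
    rn_reaction("R23_penos_dephosphorylation", "mass_action",
                substrates = c(peNOS = 1), products = c(eNOS = 1),
                params = c(k = "k14")),
    rn_reaction("R24_penos_degradation", "decay", substrates = c(peNOS = 1),
                params = c(k = "kdeg8")),
    # NO / cGMP / PKG relaxation arm
    rn_reaction("R25_no_production_penos", "synthesis", products = c(NO = 1),
                modifiers = act("peNOS"), params = c(k = "k15")),
    rn_reaction("R26_no_production_basal", "synthesis", products = c(NO = 1),
                modifiers = act("eNOS"), params = c(k = "kb1")),
    rn_reaction("R27_no_clearance", "decay", substrates = c(NO = 1),
                params = c(k = "kdeg9")),
    rn_reaction("R28_cgmp_synthesis_no", "synthesis", products = c(cGMP = 1),
                modifiers = act("NO"), params = c(k = "kb2")),
    rn_reaction("R29_cgmp_hydrolysis", "decay", substrates = c(cGMP = 1),
                params = c(k = "kdeg10")),
    rn_reaction("R30_pkg_activation_cgmp", "hill", products = c(PKG = 1),
                modifiers = list(list(species = "cGMP", type = "driver")),
                params = c(vmax = "Vpkg", km = "Kmcgmp", n = "npkg")),
    rn_reaction("R31_pkg_deactivation", "decay", substrates = c(PKG = 1),
                params = c(k = "kdeg11"))
  )
}

.rhono_species <- function() {
  list(
    rn_species("RhoA", role = "active GTPase"),
    rn_species("RhoAp", role = "phospho-RhoA-Ser188"),
    rn_species("ROCK", role = "Rho kinase"),
    rn_species("Akt", role = "kinase, unphosphorylated"),
    rn_species("pAkt", role = "phospho-Akt"),
    rn_species("eNOSm", role = "eNOS mRNA"),
    rn_species("eNOS", role = "eNOS protein"),
    rn_species("peNOS", role = "phospho-eNOS-S1177"),
    rn_species("NO", role = "second messenger"),
    rn_species("cGMP", role = "second messenger"),
    rn_species("PKG", role = "kinase activity")
  )
}

# Baseline rate constants. Found by the package's own bistability search
# (log-uniform sampling around an order-of-magnitude sketch of the pathway,
# followed by locating the bistable regime of the ki1/ki2 diagrams with the
# steady-state reduction), scaled so NO steady states sit in the
# low-nanomolar physiological range. The baseline lies near the lower ki1
# fold of the biochemical model, which is why that model's bistability is
# brittle under parameter perturbation while the tension-extended model,
# whose bistable regime is much larger, is robust at the same point.
.rhono_baseline <- function() {
  c(
    k1 = 4.8,      # RhoA activation by HGF (nM/t per HGF unit)
    k2 = 0.2,      # basal RhoA activation (nM/t)
    kdeg1 = 0.1,   # RhoA inactivation (1/t)
    k3 = 0.3,      # PKG-catalyzed RhoA Ser188 phosphorylation (1/(nM t))
    k4 = 0.2,      # RhoAp dephosphorylation (1/t)
    kdeg2 = 0.2,   # RhoAp degradation (1/t)
    k12 = 0.25,    # ROCK synthesis driven by RhoA (1/t)
    k5 = 0.01,     # basal ROCK synthesis (nM/t)
    kdeg4 = 0.25,  # ROCK degradation (1/t)
    k6 = 1.0,      # Akt synthesis (nM/t)
    kdeg3 = 0.05,  # Akt degradation (1/t)
    k7 = 0.1,      # HGF-driven Akt phosphorylation (1/(HGF t))
    k8 = 0.01,     # basal Akt phosphorylation (1/t)
    k9 = 0.2,      # pAkt dephosphorylation (1/t)
    ki1 = 0.105,   # ROCK-catalyzed pAkt inactivation (1/(nM t))
    kdeg5 = 0.05,  # pAkt degradation (1/t)
    k10 = 0.5,     # eNOS mRNA synthesis (nM/t)
    kdeg6 = 0.1,   # eNOS mRNA degradation (1/t)
    ki2 = 0.1,     # RhoA-catalyzed eNOS mRNA destabilization (1/(nM t))
    k11 = 0.1,     # eNOS translation (1/t)
    kdeg7 = 0.05,  # eNOS degradation (1/t)
    k13 = 0.05,    # pAkt-catalyzed eNOS phosphorylation (1/(nM t))
    k14 = 0.2,     # peNOS dephosphorylation (1/t)
    kdeg8 = 0.05,  # peNOS degradation (1/t)
    k15 = 2.0,     # NO production by phospho-eNOS (1/t)
    kb1 = 0.05,    # basal NO production by eNOS (1/t)
    kdeg9 = 0.3,   # NO clearance (1/t)
    kb2 = 1.0,     # cGMP synthesis driven by NO (1/t)
    kdeg10 = 0.4,  # cGMP hydrolysis (1/t)
    Vpkg = 10.0,   # maximal PKG activation (nM/t)
    Kmcgmp = 5.0,  # cGMP half-saturation of PKG activation (nM)
    kdeg11 = 0.5   # PKG deactivation (1/t)
  )
}

.tension_baseline <- function() {
  c(
    kt1 = 0.01, # tension generation by ROCK (1/t)
    kt2 = 0.5,  # tension relaxation catalyzed by PKG (NO/cGMP arm) (1/(nM t))
    kt4 = 6.0,  # maximal RhoA activation by tension (nM/t)
    KT = 10.0   # tension half-saturation of RhoA activation (dimensionless)
  )
}

#' Build the biochemical RhoA-NO model
#'
#' The initial (tension-free) network: 31 reactions over 11 state variables
#' (RhoA, phospho-RhoA-Ser188, ROCK, Akt, phospho-Akt, eNOS mRNA, eNOS,
#' phospho-eNOS-S1177, NO, cGMP, PKG activity) with a clamped constant HGF
#' input. Mutual antagonism: ROCK inactivates phospho-Akt (ki1) and RhoA
#' destabilizes eNOS mRNA (ki2); PKG phosphorylates and inactivates RhoA.
#' Baseline parameters are search-derived (see the package vignette) and
#' bistable.
#'
#' @param hgf Clamped HGF input level (default 1).
#' @return A list with elements `model` and `params`.
#' @export
build_initial_model <- function(hgf = 1) {
  model <- rn_model("rhoa_no_initial", .rhono_species(), .rhono_reactions(),
                    inputs = c(HGF = hgf),
                    notes = "biochemical RhoA-NO mutual antagonism; rate laws: mass action for bimolecular steps, Hill (n=2) for PKG activation by cGMP")
  params <- rn_parameters(c(.rhono_baseline(), npkg = 2),
                          provenance = "search-derived baseline")
  list(model = model, params = params)
}

#' Build the tension-extended RhoA-NO model
#'
#' The initial model plus a dimensionless cytoskeletal-tension state, coupled
#' by three reactions: ROCK generates tension (T15, mass action), tension
#' feeds back to activate RhoA (T16, saturating in tension so the mechanical
#' positive feedback is bounded), and the NO/cGMP arm relaxes tension through
#' PKG (T19, mass action). 12 state variables; 36 perturbable rate
#' parameters (the Hill coefficient is structural and excluded).
#'
#' @param hgf Clamped HGF input level (default 1).
#' @return A list with elements `model` and `params`.
#' @export
build_extended_model <- function(hgf = 1) {
  act <- function(sp) list(list(species = sp, type = "activator"))
  tension_rx <- list(
    rn_reaction("T15_tension_generation_rock", "synthesis",
                products = c(Tension = 1), modifiers = act("ROCK"),
                params = c(k = "kt1")),
    rn_reaction("T16_rhoa_activation_tension", "michaelis_menten",
                products = c(RhoA = 1),
                modifiers = list(list(species = "Tension", type = "driver")),
                params = c(vmax = "kt4", km = "KT")),
    rn_reaction("T19_tension_relaxation_pkg", "mass_action",
                substrates = c(Tension = 1), modifiers = act("PKG"),
                params = c(k = "kt2"))
  )
  species <- c(.rhono_species(),
               list(rn_species("Tension", role = "mechanical surrogate")))
  model <- rn_model("rhoa_no_extended", species,
                    c(.rhono_reactions(), tension_rx),
                    inputs = c(HGF = hgf),
                    notes = "tension-extended RhoA-NO network; tension closes a positive feedback loop RhoA -> ROCK -> tension -> RhoA, opposed by PKG")
  params <- rn_parameters(c(.rhono_baseline(), .tension_baseline(), npkg = 2),
                          provenance = "search-derived baseline")
  list(model = model, params = params)
}

#' Names of the perturbable rate parameters of a model
#'
#' All strictly positive rate constants excluding the structural Hill
#' coefficient `npkg`. The initial model exposes 32, the extended model 36.
#'
#' @param built A list `(model, params)` from a builder.
#' @return Character vector of parameter names.
#' @export
perturbable_parameters <- function(built) {
  setdiff(names(built$params$values), "npkg")
}
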