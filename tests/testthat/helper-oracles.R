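# Shared fixtures and independent oracles used across the suite.

# Independent quadratic oracle for the two-node steady state: eliminate A,
# solve the quadratic in B with polyroot() (a different code path from the
# package's explicit formula), return the unique nonnegative solution.
two_node_oracle <- function(sA, dA, sB, dB, kiA, kiB) {
  if (kiB == 0 && kiA == 0) return(c(A = sA / dA, B = sB / dB))
  if (kiB == 0) {
    A <- sA / dA
    return(c(A = A, B = sB / (dB + kiA * A)))
  }
  # (sB - dB*B)(dA + kiB*B) - kiA*sA*B = 0
  co <- c(sB * dA, sB * kiB - dB * dA - kiA * sA, -dB * kiB)
  roots <- polyroot(co)
  real <- Re(roots[abs(Im(roots)) < 1e-9 * max(1, abs(roots))])
  B <- real[real >= -1e-12]
  stopifnot(length(B) == 1)
  B <- max(B, 0)
  c(A = sA / (dA + kiB * B), B = B)
}

# Raw-field toys for simulation/bifurcation tests
cubic_factory <- function(p) rate_field(function(t, x) p + x - x[1]^3, 1)

linear_factory <- function(d) {
  function(p) rate_field(function(t, x) p - d * x, 1)
}

# One-species bistable toy: Hill-activated self-production vs linear decay,
# dx/dt = k x^2/(K^2 + x^2) - d x. Fixed points besides 0 solve
# x^2 - (k/d) x + K^2 = 0; bistable iff k/d > 2K.
hill_toy_model <- function() {
  rx <- list(
    rn_reaction("auto", "hill", products = c(X = 1),
                modifiers = list(list(species = "X", type = "driver")),
                params = c(vmax = "k", km = "K", n = "nh")),
    rn_reaction("decay", "decay", substrates = c(X = 1), params = c(k = "d"))
  )
  rn_model("hill_toy", list(rn_species("X", 0)), rx)
}

hill_toy_params <- function(k = 4, K = 1, d = 1) {
  rn_parameters(c(k = k, K = K, d = d, nh = 2), provenance = "toy")
}

hill_toy_fixed_points <- function(k, K, d) {
  disc <- (k / d)^2 - 4 * K^2
  if (disc <= 0) return(0)
  c(0, ((k / d) - sqrt(disc)) / 2, ((k / d) + sqrt(disc)) / 2)
}

# one-species birth-death model via the reaction machinery
birth_death_model <- function() {
  rn_model("birth_death", list(rn_species("X", 0)), list(
    rn_reaction("syn", "synthesis", products = c(X = 1), params = c(k = "s")),
    rn_reaction("deg", "decay", substrates = c(X = 1), params = c(k = "d"))
  ))
}
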