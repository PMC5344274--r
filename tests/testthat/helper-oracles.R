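# Shared fixtures and independent oracles for the test suite.

# Baseline tumor-branch fixed point, evaluated by hand from the equilibrium
# conditions (independent of steady_states()): dM = 0 forces
# M* = (b4/a3) E*; substituting into dE = 0 and dividing by E gives
#   k E*/(1 + m E*) = a2*b4/a3 + b1 - b2 - b3 - b4 = 0.2575
#   => E* = 0.2575 / (k - m*0.2575) = 0.2575/0.001673 = 257500/1673
FIXED_POINT <- c(M = 0.125 * 257500 / 1673, E = 257500 / 1673)

# Eradication threshold at baseline: 0.0025*0.32/0.02 + 0.87 - 0.25 - 0.0025
BETA_STAR_BASELINE <- 0.6575

# Occurrence-oracle probabilities, frozen from direct arithmetic
# 1 - (1 - delta)^D:
#   single stem, g = 18, 120 generations: D = (2^19 - 1 - 19) + 101*(2^18 - 1)
#     = 27,000,711
#   residual-E start, init_E = 10, g = 18: D = 10*(2^18 - 1) = 2,621,430
ORACLE_SINGLE_STEM_D <- 27000711
ORACLE_FRAC_1E8 <- 0.2366259353
ORACLE_FRAC_1E9 <- 0.0266394498
ORACLE_RECURRENCE_G18 <- 0.2305990185

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

# Finite-difference Jacobian oracle (central differences on model_rhs).
numeric_jacobian <- function(state, p, variant = "saturated_emt", h = 1e-6) {
  f <- function(s) model_rhs(s, p, variant)
  J <- matrix(0, 2, 2, dimnames = list(c("M", "E"), c("M", "E")))
  for (j in c("M", "E")) {
    up <- state; dn <- state
    up[[j]] <- up[[j]] + h
    dn[[j]] <- max(dn[[j]] - h, 0)
    J[, j] <- (f(up) - f(dn)) / (up[[j]] - dn[[j]])
  }
  J
}
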