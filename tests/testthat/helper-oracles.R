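# Independent brute-force oracles used to cross-check closed-form code.

# 1:1 complex concentration by bisection on the mass-action equation
# K (A - x)(B - x) = x over x in [0, min(A, B)]. Kept deliberately naive
# and separate from the package's conjugate-form solution.
bisect_complex <- function(A, B, K, iter = 200L) {
  if (K == 0 || A == 0 || B == 0) return(0)
  f <- function(x) K * (A - x) * (B - x) - x
  lo <- 0; hi <- min(A, B)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Direct-equilibrium oracle for the heat of ITC injection 1: applies the
# displacement bookkeeping by hand and solves the equilibrium with uniroot.
first_injection_heat <- function(K, n, dH, design) {
  V0 <- design$cell_volume
  dV <- design$injection_volumes[1]
  f <- (1 - dV / (2 * V0)) / (1 + dV / (2 * V0))
  M1 <- design$cell_conc * f
  X1 <- design$syringe_conc * dV / V0
  g <- function(x) K * (X1 - x) * (n * M1 - x) - x
  hg <- stats::uniroot(g, c(0, min(X1, n * M1)), tol = 1e-18)$root
  dH * V0 * hg
}
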