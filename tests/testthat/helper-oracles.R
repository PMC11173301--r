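# Independent oracles used to freeze expected values.

# Tight-binding occupancy by bisection on the free-ligand mass balance
# Lf + P * Lf / (Lf + Kd) = L; theta1 = Lf / (Lf + Kd). Independent of the
# closed-form quadratic used by the generator.
bisect_occupancy <- function(P, L, Kd) {
  if (L == 0) return(0)
  f <- function(Lf) Lf + P * Lf / (Lf + Kd) - L
  lo <- 0; hi <- L
  # iterate to the floating-point fixed point (interval no longer shrinks)
  repeat {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  Lf <- (lo + hi) / 2
  Lf / (Lf + Kd)
}

# convenience: a noiseless titration with exact Stern-Volmer behaviour
exact_sv_titration <- function(Ksv, concs = default_conc_grid(), F0 = 100) {
  quench_titration(concs, F0 / (1 + Ksv * concs))
}
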