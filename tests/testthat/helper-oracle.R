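# Independent quadrature oracle: brute-force double integration of the
# piecewise-uniform charge density of a layer stack. Midpoint rule for the
# field (exact for piecewise-constant rho on boundary-aligned grids),
# trapezoid for the potential (exact for the piecewise-linear field).
# Field taken to vanish below the slab; potential pinned to zero at Z = 0.
# Shares no code with potential_profile()/transmembrane_voltages().
oracle_potential <- function(stack, dz = 1e-4) {
  kv <- memvolt::memvolt_constants()$volt_per_e_per_nm
  lb <- memvolt::layer_boundaries(stack)
  # split R2 at Z = 0 so the reference point is an exact grid edge
  segs <- rbind(
    c(lb$edges[1], lb$edges[2], lb$rho[1]),
    c(lb$edges[2], lb$edges[3], lb$rho[2]),
    c(lb$edges[3], 0,           lb$rho[3]),
    c(0,           lb$edges[4], lb$rho[3]),
    c(lb$edges[4], lb$edges[5], lb$rho[4]),
    c(lb$edges[5], lb$edges[6], lb$rho[5]))
  edges <- segs[1, 1]
  rho <- c()
  for (k in seq_len(nrow(segs))) {
    a <- segs[k, 1]; b <- segs[k, 2]
    if (b <= a) next
    n <- ceiling((b - a) / dz)
    e <- seq(a, b, length.out = n + 1L)
    edges <- c(edges, e[-1L])
    rho <- c(rho, rep(segs[k, 3], n))
  }
  h <- diff(edges)
  f <- c(0, cumsum(rho * h))                              # e/nm^2
  phi <- -(kv / stack$eps_r) * c(0, cumsum((f[-1L] + f[-length(f)]) / 2 * h))
  phi <- phi - phi[which.min(abs(edges))]
  list(z = edges, phi = phi,
       at = function(zz) approx(edges, phi, xout = zz)$y)
}

oracle_voltages <- function(stack, dz = 1e-4) {
  o <- oracle_potential(stack, dz)
  lb <- memvolt::layer_boundaries(stack)
  c(dV1 = o$at(lb$edges[5]) - o$at(lb$edges[4]),
    dV2 = o$at(lb$edges[1] + stack$H_L) - o$at(lb$edges[3]))
}

# a symmetric neutral stack from the 15% POPS default system
pops15_stack <- function(D = 4) {
  memvolt::build_stack_params(memvolt::lipid_mix_pops(0.15), D = D)
}
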