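#' Closed-form electric potential of a five-layer stack
#'
#' Solves the one-dimensional Poisson equation
#' \eqn{d^2\Phi/dZ^2 = -\rho(Z)/(\epsilon_r \epsilon_0)} for the
#' piecewise-uniform charge density of a [layer_stack()]. Within each layer
#' the potential is quadratic in Z; the potential and field are continuous at
#' the four interfaces.
#'
#' Gauge: the field is taken to vanish outside the slab system (the physical
#' boundary condition for an isolated electro-neutral stack), and the
#' potential is referenced so that \eqn{\Phi(0) = 0} at the mid-plane of R2.
#' For a mirror-symmetric stack this coincides with double integration from
#' the symmetry axis, since the field also vanishes at Z = 0 there.
#'
#' @param stack a [layer_stack()].
#' @param n_per_layer grid points per layer (at least 5).
#' @return object of class `potential_profile` with fields `z` (nm), `phi`
#'   (V) and `reference_z`.
#' @seealso [transmembrane_voltages()], [integrate_potential()]
#' @examples
#' s <- build_stack_params(lipid_mix_pops(0.15), D = 4)
#' p <- potential_profile(s)
#' range(p$phi)
#' @export
potential_profile <- function(stack, n_per_layer = 40) {
  stopifnot(inherits(stack, "layer_stack"))
  if (!is.numeric(n_per_layer) || length(n_per_layer) != 1L ||
      n_per_layer < 5)
    stop("n_per_layer must be a single number >= 5")
  lb <- layer_boundaries(stack)
  z <- unique(sort(c(0, unlist(
    lapply(seq_len(5L), function(k)
      seq(lb$edges[k], lb$edges[k + 1L], length.out = n_per_layer))))))
  phi <- eval_stack_potential(stack, z)
  new_potential_profile(z, phi, reference_z = 0)
}

new_potential_profile <- function(z, phi, reference_z) {
  stopifnot(length(z) == length(phi), !is.unsorted(z, strictly = TRUE))
  structure(list(z = z, phi = phi, reference_z = reference_z),
            class = "potential_profile")
}

#' @export
print.potential_profile <- function(x, ...) {
  cat(sprintf(
    "Electric potential profile: %d points, Z in [%.3f, %.3f] nm,\n",
    length(x$z), min(x$z), max(x$z)))
  cat(sprintf("  Phi in [%.4g, %.4g] V, reference Phi(%g) = 0\n",
              min(x$phi), max(x$phi), x$reference_z))
  invisible(x)
}

#' @export
plot.potential_profile <- function(x, ...) {
  graphics::plot(x$z, x$phi, type = "l",
                 xlab = "Z (nm)", ylab = expression(Phi ~ "(V)"), ...)
  graphics::abline(h = 0, v = x$reference_z, lty = 3, col = "grey50")
  invisible(x)
}

# Exact closed-form potential at arbitrary Z for piecewise-uniform rho.
# Phi(z) = Phi(zb) - (1/eps) \int_zb^z (z - u) rho(u) du, with E(zb) = 0,
# then shifted so Phi(0) = 0.
eval_stack_potential <- function(stack, z) {
  lb <- layer_boundaries(stack)
  scale <- .kPoissonVolt() / stack$eps_r
  raw <- function(zz) {
    acc <- numeric(length(zz))
    for (k in seq_len(5L)) {
      a <- lb$edges[k]; b <- lb$edges[k + 1L]; rho <- lb$rho[k]
      if (rho == 0) next
      upper <- pmin(zz, b)
      cover <- zz > a
      contrib <- ifelse(cover, ((zz - a)^2 - (zz - upper)^2) / 2, 0)
      acc <- acc + rho * contrib
    }
    -scale * acc
  }
  raw(z) - raw(0)
}

#' Transmembrane voltages of a five-layer stack
#'
#' Closed-form voltages across the vesicle membrane (m1) and the presynaptic
#' membrane (m2) for an electro-neutral stack:
#' \deqn{\Delta V_1 = -\frac{1}{\epsilon}\left(\tfrac12\rho_{m1}H_m +
#'   \rho_{m2}H_m + \rho_2 D + \rho_3 H_L\right)H_m}
#' \deqn{\Delta V_2 = -\frac{1}{\epsilon}\left(\tfrac12\rho_{m2}H_m +
#'   \rho_{m1}H_m + \rho_2 D + \rho_1 H_L\right)H_m}
#' with \eqn{\epsilon = \epsilon_r\epsilon_0}. Sign convention:
#' \eqn{\Delta V_k = \Phi(\mathrm{outer\ face}) - \Phi(\mathrm{inner\ face})}
#' of membrane k, the inner face being the one adjoining R2. For a neutral
#' stack these closed forms equal the face potential difference of
#' [potential_profile()] exactly.
#'
#' @param stack a [layer_stack()]; a warning is issued when the neutrality
#'   residual exceeds 1e-9 e/nm^2 since the formulas assume neutrality.
#' @return named numeric vector `c(dV1 = ..., dV2 = ...)` in volts.
#' @examples
#' s <- build_stack_params(lipid_mix_pops(0.15), D = 4.7)
#' transmembrane_voltages(s)
#' @export
transmembrane_voltages <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  res <- neutrality_residual(stack)
  if (abs(res) > 1e-9)
    warning("stack is not electro-neutral (residual ",
            format(res), " e/nm^2); Eq-based voltages assume neutrality")
  scale <- .kPoissonVolt() / stack$eps_r
  dv1 <- with(stack,
              -scale * (0.5 * rho_m1 * H_m + rho_m2 * H_m +
                          rho2 * D + rho3 * H_L) * H_m)
  dv2 <- with(stack,
              -scale * (0.5 * rho_m2 * H_m + rho_m1 * H_m +
                          rho2 * D + rho1 * H_L) * H_m)
  c(dV1 = dv1, dV2 = dv2)
}

# re-close a stack at distance D under a charge-closure policy.
# fixed_rho2: keep rho2; spread the compensating charge equally over R1/R3.
# fixed_counter_charge: keep Q2 = rho2*D of the template; R1/R3 untouched.
reclose_stack <- function(template, D, policy = c("fixed_rho2",
                                                  "fixed_counter_charge")) {
  policy <- match.arg(policy)
  if (D < 0) stop("D must be >= 0")
  s <- template
  if (policy == "fixed_rho2") {
    s$D <- D
    resid <- with(s, rho1 * H_L + rho3 * H_L + rho2 * D +
                    rho_m1 * H_m + rho_m2 * H_m)
    delta <- -resid / (2 * s$H_L)
    s$rho1 <- s$rho1 + delta
    s$rho3 <- s$rho3 + delta
  } else {
    q2 <- template$rho2 * template$D
    if (D == 0 && q2 != 0)
      stop("fixed_counter_charge policy undefined at D = 0 with nonzero Q2")
    s$D <- D
    s$rho2 <- if (D > 0) q2 / D else 0
  }
  do.call(layer_stack, s[c("rho1", "rho2", "rho3", "rho_m1", "rho_m2",
                           "H_L", "H_m", "D", "eps_r")])
}

#' Transmembrane voltage as a function of inter-membrane distance
#'
#' Evaluates the closed-form voltages over a set of distances, re-closing
#' electro-neutrality at each distance under one of two policies:
#' \describe{
#'   \item{`fixed_rho2`}{the counter-ion density between the membranes is
#'     held at the template value (constant ion concentration, the protocol
#'     under which each distance is an independently built system); the
#'     compensating charge is spread equally over R1 and R3. The voltage is
#'     then exactly affine in D with slope
#'     \eqn{-\rho_2 H_m / (2\epsilon_r\epsilon_0)}.}
#'   \item{`fixed_counter_charge`}{the total charge per area between the
#'     membranes, \eqn{Q_2 = \rho_2 D}, is held fixed (ions trapped in R2 as
#'     the membranes approach); the voltage is then independent of D.}
#' }
#'
#' @param stack_template a [layer_stack()] providing all densities and
#'   geometry; its own `D` anchors the `fixed_counter_charge` policy.
#' @param d_values distances to evaluate, nm, each >= 0.
#' @param policy charge-closure policy (see Details); default `fixed_rho2`.
#' @return a `scan_result` data frame with columns `D`, `dV1`, `dV2`,
#'   `dV_max` (largest magnitude, signed). Metadata (policy, eps_r, affine
#'   slope under `fixed_rho2`) is stored in attributes.
#' @examples
#' s <- build_stack_params(lipid_mix_pops(0.15), D = 6)
#' voltage_vs_distance(s, seq(6, 2, by = -0.5))
#' @export
voltage_vs_distance <- function(stack_template, d_values,
                                policy = c("fixed_rho2",
                                           "fixed_counter_charge")) {
  policy <- match.arg(policy)
  stopifnot(inherits(stack_template, "layer_stack"))
  if (length(d_values) == 0) stop("d_values must be non-empty")
  if (any(d_values < 0)) stop("d_values must all be >= 0")
  rows <- lapply(d_values, function(D) {
    s <- reclose_stack(stack_template, D, policy)
    dv <- transmembrane_voltages(s)
    data.frame(D = D, dV1 = dv[["dV1"]], dV2 = dv[["dV2"]])
  })
  out <- do.call(rbind, rows)
  out$dV_max <- ifelse(abs(out$dV1) >= abs(out$dV2), out$dV1, out$dV2)
  structure(out,
            class = c("scan_result", "data.frame"),
            scan = "voltage_vs_distance",
            policy = policy,
            eps_r = stack_template$eps_r,
            slope_V_per_nm = if (policy == "fixed_rho2")
              -stack_template$rho2 * stack_template$H_m *
                .kPoissonVolt() / (2 * stack_template$eps_r) else 0)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Scan result (", attr(x, "scan") %||% "scan", ")\n", sep = "")
  if (!is.null(attr(x, "policy")))
    cat("  charge-closure policy:", attr(x, "policy"), "\n")
  if (!is.null(attr(x, "D_critical")))
    cat("  D_critical:", format(attr(x, "D_critical")), "nm\n")
  if (isTRUE(attr(x, "below_scan_range")))
    cat("  D_critical: below scan range\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Critical inter-membrane distance for a voltage threshold
#'
#' Finds the largest distance D in the search bracket at which the magnitude
#' of the transmembrane voltage reaches `dv_critical`, i.e. the distance
#' below which close contact drives the voltage past the electroporation
#' threshold. Under the `fixed_rho2` policy the voltage is affine in D and
#' the crossing is obtained in closed form; under `fixed_counter_charge`
#' a bisection refined to `tol` is used.
#'
#' @param stack_template a [layer_stack()] (see [voltage_vs_distance()]).
#' @param dv_critical threshold voltage magnitude, V, > 0.
#' @param policy charge-closure policy.
#' @param bracket search interval for D, nm.
#' @param tol bisection tolerance, nm.
#' @return distance in nm, with attribute `dV` giving the voltage there.
#'   Errors with "no crossing" if the voltage magnitude stays below
#'   `dv_critical` throughout the bracket.
#' @examples
#' s <- build_stack_params(lipid_mix_pops(0.15), D = 6)
#' critical_distance(s, dv_critical = 1.0)
#' @export
critical_distance <- function(stack_template, dv_critical,
                              policy = c("fixed_rho2",
                                         "fixed_counter_charge"),
                              bracket = c(0.5, 10), tol = 1e-9) {
  policy <- match.arg(policy)
  stopifnot(inherits(stack_template, "layer_stack"))
  if (!is.numeric(dv_critical) || length(dv_critical) != 1L ||
      dv_critical <= 0)
    stop("dv_critical must be a single value > 0")
  stopifnot(length(bracket) == 2L, bracket[1] >= 0, bracket[2] > bracket[1])

  vmag <- function(D) {
    dv <- transmembrane_voltages(reclose_stack(stack_template, D, policy))
    max(abs(dv))
  }

  if (policy == "fixed_rho2") {
    # both voltages are affine in D; collect candidate crossings
    dv0 <- transmembrane_voltages(reclose_stack(stack_template, bracket[1],
                                                policy))
    dv1 <- transmembrane_voltages(reclose_stack(stack_template, bracket[1] + 1,
                                                policy))
    cands <- c()
    for (k in 1:2) {
      a <- dv0[k] - (dv1[k] - dv0[k]) * bracket[1]  # intercept at D = 0
      b <- dv1[k] - dv0[k]                           # slope
      if (b != 0)
        cands <- c(cands, (dv_critical - a) / b, (-dv_critical - a) / b)
      else if (abs(a) == dv_critical)
        cands <- c(cands, bracket[2])
    }
    cands <- cands[cands >= bracket[1] & cands <= bracket[2]]
    cands <- cands[vapply(cands, function(D)
      abs(vmag(D) - dv_critical) < 1e-6, logical(1))]
    # keep the close-contact branch: |dV| must grow as D shrinks
    h <- 1e-6
    cands <- cands[vapply(cands, function(D)
      vmag(max(bracket[1], D - h)) > vmag(min(bracket[2], D + h)),
      logical(1))]
    if (length(cands) == 0) {
      if (vmag(bracket[1]) < dv_critical)
        stop("no crossing: |dV(D)| < dv_critical on the close-contact side ",
             "of the bracket")
      # threshold exceeded throughout the close-contact branch
      d_star <- bracket[2]
    } else d_star <- max(cands)
  } else {
    g <- function(D) vmag(D) - dv_critical
    # restrict to the close-contact branch (|dV| non-increasing in D):
    # scan down from the bracket top only past the |dV| minimum
    grid <- seq(bracket[2], bracket[1], length.out = 201L)
    vv <- vapply(grid, vmag, numeric(1))
    imin <- which.min(vv)
    grid <- grid[imin:length(grid)]
    gv <- vv[imin:length(vv)] - dv_critical
    if (all(gv < 0))
      stop("no crossing: |dV(D)| < dv_critical on the close-contact side ",
           "of the bracket")
    if (gv[1L] >= 0) {
      d_star <- grid[1L]  # threshold already met at the branch top
    } else {
      i <- which(gv[-1L] >= 0 & gv[-length(gv)] < 0)[1L]
      lo <- grid[i + 1L]   # g(lo) >= 0 (smaller D)
      hi <- grid[i]        # g(hi) <  0 (larger D)
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (g(mid) >= 0) lo <- mid else hi <- mid
      }
      d_star <- lo
    }
  }
  dv_at <- transmembrane_voltages(reclose_stack(stack_template, d_star,
                                                policy))
  structure(d_star, dV = dv_at[which.max(abs(dv_at))])
}
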