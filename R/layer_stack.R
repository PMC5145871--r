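#' Five-layer electrostatic stack
#'
#' Describes the layered system at the contact between a vesicle and the
#' presynaptic membrane: vesicle lumen (R1), vesicle membrane (m1), the
#' cytosol between the membranes (R2), the presynaptic membrane (m2), and
#' the interstitial fluid (R3). Charge is uniform within each layer.
#'
#' The Z axis is normal to the membranes with Z = 0 at the mid-plane of R2:
#' R2 spans \[-D/2, D/2\], membrane m1 spans \[D/2, D/2 + H_m\], R1 lies above
#' it, and m2/R3 mirror below.
#'
#' @param rho1,rho2,rho3 volume charge densities of the aqueous regions R1,
#'   R2, R3, in e/nm^3.
#' @param rho_m1,rho_m2 membrane volume charge densities (vesicle and
#'   presynaptic membrane), e/nm^3. Anionic lipids make these negative.
#' @param H_L thickness of the outer aqueous slabs R1 and R3, nm.
#' @param H_m membrane thickness, nm.
#' @param D inter-membrane distance (thickness of R2), nm.
#' @param eps_r relative dielectric constant (default 3, the measured value
#'   for the interfacial membrane environment used throughout the model).
#' @param neutral logical; if `TRUE` the constructor checks overall
#'   electro-neutrality (surface residual below `1e-9` e/nm^2) and errors
#'   otherwise. `NA` (default) records whether the stack happens to be
#'   neutral without enforcing it.
#' @return An object of class `layer_stack`.
#' @seealso [neutrality_residual()], [transmembrane_voltages()],
#'   [build_stack_params()]
#' @examples
#' s <- layer_stack(rho_m1 = -0.1, rho_m2 = -0.1, rho2 = 0.2, D = 4)
#' neutrality_residual(s)
#' @export
layer_stack <- function(rho1 = 0, rho2 = 0, rho3 = 0,
                        rho_m1 = 0, rho_m2 = 0,
                        H_L = 4, H_m = 4, D, eps_r = 3,
                        neutral = NA) {
  for (nm in c("rho1", "rho2", "rho3", "rho_m1", "rho_m2",
               "H_L", "H_m", "D", "eps_r")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a finite numeric scalar")
  }
  if (H_L <= 0) stop("H_L must be > 0")
  if (H_m <= 0) stop("H_m must be > 0")
  if (D < 0) stop("D must be >= 0")
  if (eps_r <= 0) stop("eps_r must be > 0")
  s <- structure(
    list(rho1 = rho1, rho2 = rho2, rho3 = rho3,
         rho_m1 = rho_m1, rho_m2 = rho_m2,
         H_L = H_L, H_m = H_m, D = D, eps_r = eps_r),
    class = "layer_stack")
  res <- neutrality_residual(s)
  if (isTRUE(neutral) && abs(res) >= 1e-9)
    stop("stack flagged neutral but |charge residual| = ",
         format(abs(res)), " e/nm^2 >= 1e-9")
  attr(s, "neutral") <- abs(res) < 1e-9
  s
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("Five-layer electrostatic stack (e, nm units)\n")
  cat(sprintf("  D = %g nm, H_m = %g nm, H_L = %g nm, eps_r = %g\n",
              x$D, x$H_m, x$H_L, x$eps_r))
  cat(sprintf("  rho: R1 %+.5g  R2 %+.5g  R3 %+.5g  m1 %+.5g  m2 %+.5g e/nm^3\n",
              x$rho1, x$rho2, x$rho3, x$rho_m1, x$rho_m2))
  cat(sprintf("  neutrality residual: %.3g e/nm^2%s\n",
              neutrality_residual(x),
              if (isTRUE(attr(x, "neutral"))) " (neutral)" else ""))
  invisible(x)
}

#' Electro-neutrality residual of a layer stack
#'
#' Surface-charge residual
#' \eqn{\rho_1 H_L + \rho_3 H_L + \rho_2 D + \rho_{m1} H_m + \rho_{m2} H_m}
#' in e/nm^2. Zero for an electro-neutral system.
#'
#' @param stack a [layer_stack()].
#' @return numeric scalar, e/nm^2.
#' @export
neutrality_residual <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  with(stack, rho1 * H_L + rho3 * H_L + rho2 * D +
         rho_m1 * H_m + rho_m2 * H_m)
}

#' Layer boundaries and densities, bottom to top
#'
#' @param stack a [layer_stack()].
#' @return list with `edges` (6 Z positions from the bottom of R3 to the top
#'   of R1, nm) and `rho` (5 layer densities in the same order:
#'   R3, m2, R2, m1, R1).
#' @export
layer_boundaries <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  with(stack, {
    zb <- -(D / 2 + H_m + H_L)
    list(edges = c(zb, zb + H_L, -D / 2, D / 2, D / 2 + H_m,
                   D / 2 + H_m + H_L),
         rho = c(rho3, rho_m2, rho2, rho_m1, rho1))
  })
}

#' Default lipid headgroup charges
#'
#' POPS carries -1 e, PIP2 -5 e; cholesterol, DOPC and POPE are neutral.
#'
#' @return named numeric vector of charges in e.
#' @export
default_species_charges <- function() {
  c(CHOL = 0, DOPC = 0, POPE = 0, POPS = -1, PIP2 = -5)
}

#' Chol:DOPC:POPE:POPS mixture with a given POPS fraction
#'
#' The mixture family used throughout: cholesterol and POPE fixed at 20%
#' each, POPS at `pops_frac`, DOPC absorbing the remainder
#' (e.g. 15% POPS gives 20:45:20:15).
#'
#' @param pops_frac POPS mole fraction in \[0, 0.6\].
#' @return named composition vector summing to 1.
#' @examples
#' lipid_mix_pops(0.15)
#' @export
lipid_mix_pops <- function(pops_frac) {
  stopifnot(is.numeric(pops_frac), length(pops_frac) == 1L,
            pops_frac >= 0, pops_frac <= 0.6)
  c(CHOL = 0.20, DOPC = 0.60 - pops_frac, POPE = 0.20, POPS = pops_frac)
}

#' Membrane volume charge density from lipid composition
#'
#' Converts headgroup charges per unit membrane area into a volume charge
#' density spread through the membrane slab:
#' \eqn{\rho_m = n_\mathrm{leaflets} \sum_s f_s q_s / (a_L H_m)},
#' with \eqn{a_L} the area per lipid.
#'
#' @param fractions named numeric vector of species mole fractions summing
#'   to 1 (names matched case-insensitively against `charges`).
#' @param charges named charges per species in e; defaults to
#'   [default_species_charges()].
#' @param area_per_lipid mean in-plane area per lipid, nm^2 (default 0.65,
#'   typical of fluid-phase phospholipid).
#' @param H_m membrane thickness, nm.
#' @param leaflets number of charged leaflets contributing (2 for a
#'   symmetric bilayer, 1 for e.g. PIP2 confined to the cytoplasmic leaflet).
#' @return membrane charge density, e/nm^3.
#' @examples
#' composition_to_membrane_charge(lipid_mix_pops(0.15))
#' @export
composition_to_membrane_charge <- function(fractions,
                                           charges = default_species_charges(),
                                           area_per_lipid = 0.65,
                                           H_m = 4, leaflets = 2) {
  stopifnot(is.numeric(fractions), length(fractions) >= 1L,
            !is.null(names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("composition fractions must sum to 1 (got ", sum(fractions), ")")
  if (area_per_lipid <= 0) stop("area_per_lipid must be > 0")
  if (H_m <= 0) stop("H_m must be > 0")
  if (leaflets < 1) stop("leaflets must be >= 1")
  key <- toupper(names(fractions))
  q <- charges[match(key, toupper(names(charges)))]
  if (anyNA(q))
    stop("no charge supplied for species: ",
         paste(names(fractions)[is.na(q)], collapse = ", "))
  leaflets * sum(fractions * q) / (area_per_lipid * H_m)
}
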