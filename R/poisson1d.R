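#' Binned one-dimensional charge density profile
#'
#' @param bin_edges strictly increasing Z positions (N + 1 edges), nm.
#' @param rho mean volume charge density per bin, e/nm^3 (N values).
#' @param area box cross-section (Lx x Ly), nm^2.
#' @param frame_time optional time stamp, ns.
#' @return object of class `charge_profile`.
#' @export
charge_profile <- function(bin_edges, rho, area, frame_time = NA_real_) {
  stopifnot(length(bin_edges) == length(rho) + 1L,
            !is.unsorted(bin_edges, strictly = TRUE),
            area > 0)
  structure(list(bin_edges = as.numeric(bin_edges),
                 rho = as.numeric(rho),
                 area = area, frame_time = frame_time),
            class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  q <- sum(x$rho * diff(x$bin_edges)) * x$area
  cat(sprintf(
    "Charge density profile: %d bins over Z [%.2f, %.2f] nm, area %.2f nm^2\n",
    length(x$rho), min(x$bin_edges), max(x$bin_edges), x$area))
  cat(sprintf("  integrated charge: %.4g e\n", q))
  invisible(x)
}

#' Bin particle charges into a 1-D density profile
#'
#' Averages the net particle charge over the membrane plane: charges are
#' wrapped into the primary box image and accumulated into uniform Z bins
#' spanning the full box height, then divided by the bin volume. The total
#' binned charge equals the total particle charge exactly.
#'
#' @param config a [pseudo_configuration()].
#' @param bin_width target bin width, nm (> 0); the actual width is the box
#'   height divided by the nearest integer bin count.
#' @return a [charge_profile()].
#' @examples
#' s <- build_stack_params(lipid_mix_pops(0.15), D = 4)
#' cfg <- build_configuration(s, box_xy = 10, seed = 1)
#' prof <- bin_charge_density(cfg, 0.1)
#' sum(prof$rho * diff(prof$bin_edges)) * prof$area  # net charge ~ 0
#' @export
bin_charge_density <- function(config, bin_width = 0.1) {
  stopifnot(inherits(config, "pseudo_configuration"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  n_part <- nrow(config$positions)
  if (n_part == 0L) stop("configuration has no particles")
  Lz <- config$box[3]
  n <- max(1L, round(Lz / bin_width))
  h <- Lz / n
  z <- config$positions[, 3]
  if (any(z < -Lz / 2 - 1e-9 | z > Lz / 2 + 1e-9))
    stop("particle outside box after wrapping")
  idx <- pmin(n, pmax(1L, floor((z + Lz / 2) / h) + 1L))
  qsum <- numeric(n)
  agg <- rowsum(config$charges, idx)
  qsum[as.integer(rownames(agg))] <- agg[, 1]
  edges <- seq(-Lz / 2, Lz / 2, length.out = n + 1L)
  A <- config$box[1] * config$box[2]
  charge_profile(edges, qsum / (A * h), area = A,
                 frame_time = config$frame_time)
}

#' Exact binned profile of a layer stack (noise-free path)
#'
#' Synthesizes the charge profile the binning step would produce for the
#' continuum stack: each bin receives the overlap-weighted mean of the layer
#' densities it intersects.
#'
#' @param stack a [layer_stack()].
#' @param area cross-section, nm^2 (any positive value; the profile is
#'   intensive).
#' @param bin_width nm.
#' @return a [charge_profile()].
#' @export
charge_profile_from_stack <- function(stack, area = 1, bin_width = 0.1) {
  stopifnot(inherits(stack, "layer_stack"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  lb <- layer_boundaries(stack)
  Lz <- stack$D + 2 * stack$H_m + 2 * stack$H_L
  n <- max(1L, round(Lz / bin_width))
  edges <- seq(-Lz / 2, Lz / 2, length.out = n + 1L)
  h <- Lz / n
  rho <- numeric(n)
  for (k in seq_len(5L)) {
    a <- lb$edges[k]; b <- lb$edges[k + 1L]
    if (lb$rho[k] == 0) next
    lo <- pmax(edges[-(n + 1L)], a)
    hi <- pmin(edges[-1L], b)
    rho <- rho + lb$rho[k] * pmax(0, hi - lo) / h
  }
  charge_profile(edges, rho, area = area)
}

#' Integrate the 1-D Poisson equation over a charge profile
#'
#' Double integration of \eqn{d^2\Phi/dZ^2 = -\rho(Z)/(\epsilon_r\epsilon_0)}.
#' The first integral (the field) accumulates the piecewise-constant bin
#' densities exactly from the lower box edge, where the field of an isolated
#' neutral slab vanishes; the second is a trapezoidal pass over the bin
#' edges (exact for the piecewise-linear field). The potential is then
#' shifted so that \eqn{\Phi(\mathrm{reference\_z}) = 0}; by default the
#' reference is the symmetry axis Z = 0.
#'
#' @param profile a [charge_profile()].
#' @param eps_r relative dielectric constant (> 0).
#' @param reference_z position where the potential is pinned to zero, nm;
#'   must lie inside the profile range.
#' @return a `potential_profile` sampled at the bin edges.
#' @examples
#' s <- build_stack_params(lipid_mix_pops(0.15), D = 4)
#' prof <- charge_profile_from_stack(s, bin_width = 0.05)
#' pot <- integrate_potential(prof, eps_r = 3)
#' @export
integrate_potential <- function(profile, eps_r, reference_z = 0) {
  stopifnot(inherits(profile, "charge_profile"))
  if (eps_r <= 0) stop("eps_r must be > 0")
  e <- profile$bin_edges
  if (reference_z < min(e) || reference_z > max(e))
    stop("reference_z outside the profile Z range")
  h <- diff(e)
  f <- c(0, cumsum(profile$rho * h))           # \int rho dz, e/nm^2
  scale <- .kPoissonVolt() / eps_r
  phi <- -scale * c(0, cumsum((f[-1L] + f[-length(f)]) / 2 * h))
  phi <- phi - stats::approx(e, phi, xout = reference_z)$y
  new_potential_profile(e, phi, reference_z = reference_z)
}

#' Membrane slab bounds
#'
#' Z intervals of the two membrane slabs; `m1` is the upper membrane
#' (vesicle side), `m2` the lower (presynaptic side).
#'
#' @param m1,m2 numeric `c(lower_face, upper_face)`, nm.
#' @return object of class `membrane_bounds`.
#' @export
membrane_bounds <- function(m1, m2) {
  stopifnot(length(m1) == 2L, length(m2) == 2L,
            m1[1] < m1[2], m2[1] < m2[2])
  if (max(m2) > min(m1)) {
    if (max(m1) > min(m2)) stop("membrane intervals must be disjoint")
    tmp <- m1; m1 <- m2; m2 <- tmp  # keep m1 the upper slab
  }
  structure(list(m1 = as.numeric(m1), m2 = as.numeric(m2)),
            class = "membrane_bounds")
}

#' @export
print.membrane_bounds <- function(x, ...) {
  cat(sprintf("Membrane bounds: m1 [%.3f, %.3f] nm, m2 [%.3f, %.3f] nm\n",
              x$m1[1], x$m1[2], x$m2[1], x$m2[2]))
  invisible(x)
}

#' Locate the two membrane slabs
#'
#' For a [layer_stack()] or a configuration carrying declared stack
#' geometry, returns the declared slab faces exactly. For a bare particle
#' configuration, the headgroup number density along Z is binned and each
#' membrane's faces are taken as the outermost half-maximum crossings of its
#' density cluster; both volumetric headgroup fills (one occupied run per
#' membrane) and face sheets (two narrow runs per membrane, paired) are
#' recognized.
#'
#' @param x a `layer_stack`, or a `pseudo_configuration`.
#' @param bin_width histogram bin width for the particle route, nm.
#' @param use_declared if `FALSE`, ignore declared geometry and use the
#'   particle route even when a stack attribute is present.
#' @return a [membrane_bounds()].
#' @export
locate_membranes <- function(x, bin_width = 0.1, use_declared = TRUE) {
  if (inherits(x, "layer_stack"))
    return(bounds_from_stack(x))
  stopifnot(inherits(x, "pseudo_configuration"))
  stack <- attr(x, "stack")
  if (use_declared && !is.null(stack))
    return(bounds_from_stack(stack))

  heads <- startsWith(x$species, "HEAD")
  if (!any(heads)) stop("no headgroup particles found")
  z <- x$positions[heads, 3]
  Lz <- x$box[3]
  n <- max(4L, round(Lz / bin_width))
  h <- Lz / n
  edges <- seq(-Lz / 2, Lz / 2, length.out = n + 1L)
  counts <- tabulate(pmin(n, pmax(1L, floor((z + Lz / 2) / h) + 1L)), n)
  # half-level relative to the median occupied count: robust for both
  # uniform slab fills (noisy plateaus) and face sheets (narrow spikes)
  level <- stats::median(counts[counts > 0]) / 2
  mask <- counts >= level
  # contiguous runs of above-half-maximum bins, merging gaps of <= 3 bins
  r <- rle(mask)
  if (length(r$values) > 1) {
    short_gap <- !r$values & r$lengths <= 3 &
      seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    r$values[short_gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  intervals <- cbind(edges[runs[, 1, drop = TRUE]],
                     edges[runs[, 2, drop = TRUE] + 1L])
  n_runs <- nrow(intervals)
  if (n_runs == 2L) {
    bb <- intervals
  } else if (n_runs == 4L) {
    # face sheets: pair consecutive runs into slabs
    bb <- rbind(c(intervals[1, 1], intervals[2, 2]),
                c(intervals[3, 1], intervals[4, 2]))
  } else {
    stop("expected two membrane slabs, found ", n_runs,
         " headgroup density cluster(s) at Z: ",
         paste(sprintf("[%.2f, %.2f]", intervals[, 1], intervals[, 2]),
               collapse = ", "))
  }
  membrane_bounds(m1 = bb[2, ], m2 = bb[1, ])
}

bounds_from_stack <- function(stack) {
  lb <- layer_boundaries(stack)
  membrane_bounds(m1 = c(lb$edges[4], lb$edges[5]),
                  m2 = c(lb$edges[2], lb$edges[3]))
}

#' Read transmembrane voltages off a potential profile
#'
#' \eqn{\Delta V_k = \Phi(\mathrm{outer\ face}) - \Phi(\mathrm{inner\ face})}
#' for each membrane, the inner face being the one adjoining the
#' inter-membrane region; values are linearly interpolated between grid
#' points. Identical sign convention to [transmembrane_voltages()], and
#' invariant under any constant shift of the potential.
#'
#' @param potential a `potential_profile`.
#' @param bounds a [membrane_bounds()].
#' @return named vector `c(dV1 = ..., dV2 = ...)`, volts.
#' @export
measure_voltage <- function(potential, bounds) {
  stopifnot(inherits(potential, "potential_profile"),
            inherits(bounds, "membrane_bounds"))
  faces <- c(bounds$m1, bounds$m2)
  if (any(faces < min(potential$z)) || any(faces > max(potential$z)))
    stop("membrane bounds outside the potential grid")
  p <- function(zz) stats::approx(potential$z, potential$phi, xout = zz)$y
  # m1 is the upper slab: inner face is its lower bound; m2 mirrors
  dv1 <- p(bounds$m1[2]) - p(bounds$m1[1])
  dv2 <- p(bounds$m2[1]) - p(bounds$m2[2])
  c(dV1 = dv1, dV2 = dv2)
}
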