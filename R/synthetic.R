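#' Particle configuration of the layered two-bilayer system
#'
#' A light-weight particle container: positions, per-particle charges,
#' species labels and the periodic box. Z coordinates are centred, i.e. run
#' over \[-Lz/2, Lz/2) with Z = 0 at the mid-plane between the membranes.
#'
#' @param positions numeric matrix n x 3 (x, y, z), nm.
#' @param charges numeric vector, e per particle.
#' @param species character vector of labels (`ION`, `HEAD_POPS`,
#'   `HEAD_PIP2`, `HEAD_NEUTRAL`, `HEAD_CHARGED`, `WATER_MARK`, `COMP`).
#' @param box numeric `c(Lx, Ly, Lz)`, nm.
#' @param frame_time optional time stamp, ns.
#' @return object of class `pseudo_configuration`.
#' @export
pseudo_configuration <- function(positions, charges, species, box,
                                 frame_time = NA_real_) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L,
            nrow(positions) == length(charges),
            nrow(positions) == length(species),
            length(box) == 3L, all(box > 0))
  positions <- wrap_positions(positions, box)
  structure(list(positions = positions,
                 charges = as.numeric(charges),
                 species = as.character(species),
                 box = as.numeric(box),
                 frame_time = frame_time),
            class = "pseudo_configuration")
}

# wrap x,y into [0, L), z into [-Lz/2, Lz/2)
wrap_positions <- function(pos, box) {
  pos[, 1] <- pos[, 1] %% box[1]
  pos[, 2] <- pos[, 2] %% box[2]
  pos[, 3] <- ((pos[, 3] + box[3] / 2) %% box[3]) - box[3] / 2
  pos
}

#' @export
print.pseudo_configuration <- function(x, ...) {
  cat(sprintf("Pseudo-configuration: %d particles, box %.2f x %.2f x %.2f nm\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  tab <- table(x$species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  net charge: %.3g e", sum(x$charges)))
  if (!is.na(x$frame_time)) cat(sprintf("  (t = %g ns)", x$frame_time))
  cat("\n")
  invisible(x)
}

# evaluate an expression under a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a neutral layer stack from a lipid composition
#'
#' Converts a composition into membrane charge density via
#' [composition_to_membrane_charge()] (both membranes identical) and closes
#' electro-neutrality with potassium counter-ions distributed uniformly at a
#' common density across the three aqueous regions, as in the simulated
#' system where ions fill the vesicle lumen, the inter-membrane cytosol and
#' the interstitial fluid at equal concentration.
#'
#' @param composition named species fractions summing to 1.
#' @param D inter-membrane distance, nm.
#' @param H_m,H_L slab thicknesses, nm.
#' @param eps_r relative dielectric constant.
#' @param area_per_lipid nm^2.
#' @param charges per-species headgroup charges, e.
#' @param leaflets charged leaflets per membrane (see
#'   [composition_to_membrane_charge()]).
#' @return a neutral [layer_stack()] carrying the composition and area per
#'   lipid as attributes (used by [build_configuration()]).
#' @examples
#' build_stack_params(lipid_mix_pops(0.15), D = 4)
#' @export
build_stack_params <- function(composition, D, H_m = 4, H_L = 4, eps_r = 3,
                               area_per_lipid = 0.65,
                               charges = default_species_charges(),
                               leaflets = 2) {
  if (D < 0) stop("D must be >= 0")
  rho_m <- composition_to_membrane_charge(composition, charges = charges,
                                          area_per_lipid = area_per_lipid,
                                          H_m = H_m, leaflets = leaflets)
  rho_ion <- -2 * rho_m * H_m / (2 * H_L + D)
  s <- layer_stack(rho1 = rho_ion, rho2 = rho_ion, rho3 = rho_ion,
                   rho_m1 = rho_m, rho_m2 = rho_m,
                   H_L = H_L, H_m = H_m, D = D, eps_r = eps_r,
                   neutral = TRUE)
  attr(s, "composition") <- composition
  attr(s, "area_per_lipid") <- area_per_lipid
  attr(s, "species_charges") <- charges
  attr(s, "leaflets") <- leaflets
  s
}

#' Random electro-neutral layer stack
#'
#' Draws membrane and outer-region densities uniformly and solves the
#' neutrality condition for the inter-membrane density. Intended for
#' property-style testing of the analytic/numeric agreement.
#'
#' @param seed integer seed (the draw is reproducible and leaves the global
#'   RNG untouched).
#' @return a neutral [layer_stack()].
#' @export
random_neutral_stack <- function(seed) {
  with_seed(seed, {
    H_m <- stats::runif(1, 3, 5)
    H_L <- stats::runif(1, 3, 5)
    D <- stats::runif(1, 1, 6)
    eps_r <- stats::runif(1, 2, 5)
    rho_m1 <- stats::runif(1, -0.5, -0.02)
    rho_m2 <- stats::runif(1, -0.5, -0.02)
    rho1 <- stats::runif(1, 0, 0.2)
    rho3 <- stats::runif(1, 0, 0.2)
    rho2 <- -(rho1 * H_L + rho3 * H_L + (rho_m1 + rho_m2) * H_m) / D
    layer_stack(rho1 = rho1, rho2 = rho2, rho3 = rho3,
                rho_m1 = rho_m1, rho_m2 = rho_m2,
                H_L = H_L, H_m = H_m, D = D, eps_r = eps_r, neutral = TRUE)
  })
}

#' Build a particle configuration realizing a layer stack
#'
#' Places charged headgroup particles through each membrane slab, unit-charge
#' potassium-like ions uniformly at random in the three aqueous regions
#' (integer counts, rounded from the target densities), and one compensating
#' `COMP` particle absorbing the rounding residual so the net charge is
#' exactly zero. Reproducible: the same `(stack, box_xy, seed)` give
#' bit-identical coordinates.
#'
#' @param stack a [layer_stack()]; if built by [build_stack_params()] the
#'   headgroups follow the composition (species `HEAD_POPS`, `HEAD_PIP2`,
#'   `HEAD_NEUTRAL`), otherwise a generic `HEAD_CHARGED` population carries
#'   the membrane charge.
#' @param box_xy lateral box edge, nm (the box is `box_xy` x `box_xy` x
#'   `D + 2 H_m + 2 H_L`).
#' @param seed integer seed.
#' @param head_style `"volumetric"` (default) distributes headgroup charge
#'   uniformly through each membrane slab, matching the uniform-density
#'   analytic model; `"sheet"` concentrates each leaflet's heads at its slab
#'   face.
#' @param area_per_lipid nm^2; taken from the stack attribute when present.
#' @return a [pseudo_configuration()] carrying the stack as attribute
#'   `"stack"`.
#' @examples
#' s <- build_stack_params(lipid_mix_pops(0.15), D = 4)
#' cfg <- build_configuration(s, box_xy = 10, seed = 1)
#' sum(cfg$charges)
#' @export
build_configuration <- function(stack, box_xy, seed,
                                head_style = c("volumetric", "sheet"),
                                area_per_lipid = NULL) {
  stopifnot(inherits(stack, "layer_stack"))
  head_style <- match.arg(head_style)
  if (box_xy <= 0) stop("box_xy must be > 0")
  apl <- area_per_lipid %||% attr(stack, "area_per_lipid") %||% 0.65
  A <- box_xy^2
  Lz <- stack$D + 2 * stack$H_m + 2 * stack$H_L
  lb <- layer_boundaries(stack)
  comp <- attr(stack, "composition")
  qtab <- attr(stack, "species_charges") %||% default_species_charges()

  with_seed(seed, {
    pos <- list(); chg <- list(); spc <- list()
    add <- function(p, q, s) {
      pos[[length(pos) + 1L]] <<- p
      chg[[length(chg) + 1L]] <<- q
      spc[[length(spc) + 1L]] <<- s
    }
    place_heads <- function(z_lo, z_hi, leaflet_lo, rho_slab) {
      # one leaflet: half the slab in volumetric style, the face in sheets
      if (!is.null(comp)) {
        for (sname in names(comp)) {
          n <- round(comp[[sname]] * A / apl)
          if (n <= 0) next
          q <- qtab[[toupper(sname)]]
          zz <- if (head_style == "volumetric")
            stats::runif(n, z_lo, z_hi)
          else rep(if (leaflet_lo) z_lo else z_hi, n)
          lab <- if (q == 0) "HEAD_NEUTRAL" else paste0("HEAD_", toupper(sname))
          add(cbind(stats::runif(n, 0, box_xy),
                    stats::runif(n, 0, box_xy), zz),
              rep(q, n), rep(lab, n))
        }
      } else {
        # generic heads: split the leaflet's share of the slab charge evenly
        n <- max(1L, round(A / apl))
        leaflet_q <- rho_slab * stack$H_m * A / 2
        zz <- if (head_style == "volumetric")
          stats::runif(n, z_lo, z_hi)
        else rep(if (leaflet_lo) z_lo else z_hi, n)
        add(cbind(stats::runif(n, 0, box_xy),
                  stats::runif(n, 0, box_xy), zz),
            rep(leaflet_q / n, n), rep("HEAD_CHARGED", n))
      }
    }
    # membranes: m2 is [edges2, edges3], m1 is [edges4, edges5]
    mslabs <- list(c(lb$edges[2], lb$edges[3], stack$rho_m2),
                   c(lb$edges[4], lb$edges[5], stack$rho_m1))
    for (ms in mslabs) {
      mid <- (ms[1] + ms[2]) / 2
      place_heads(ms[1], mid, leaflet_lo = TRUE, rho_slab = ms[3])
      place_heads(mid, ms[2], leaflet_lo = FALSE, rho_slab = ms[3])
    }
    # ions in the three aqueous regions
    regions <- list(R3 = c(lb$edges[1], lb$edges[2], stack$rho3),
                    R2 = c(lb$edges[3], lb$edges[4], stack$rho2),
                    R1 = c(lb$edges[5], lb$edges[6], stack$rho1))
    targets <- vapply(regions, function(rg) rg[3] * (rg[2] - rg[1]) * A,
                      numeric(1))
    q_heads <- sum(unlist(chg))
    counts <- if (all(targets >= 0) && q_heads <= 0 &&
                  abs(q_heads - round(q_heads)) < 1e-9 && sum(targets) > 0) {
      # unit counter-charges can cancel the integer headgroup charge
      # exactly: apportion the required total by largest remainder, so no
      # compensating particle (and no localized bias) is needed
      n_tot <- round(-q_heads)
      ideal <- targets * n_tot / sum(targets)
      n <- floor(ideal)
      extra <- n_tot - sum(n)
      if (extra > 0) {
        ord <- order(ideal - n, decreasing = TRUE)
        n[ord[seq_len(extra)]] <- n[ord[seq_len(extra)]] + 1L
      }
      n
    } else round(abs(targets)) * sign(targets)
    for (i in seq_along(regions)) {
      rg <- regions[[i]]
      n <- abs(counts[i])
      if (n == 0) next
      add(cbind(stats::runif(n, 0, box_xy),
                stats::runif(n, 0, box_xy),
                stats::runif(n, rg[1], rg[2])),
          rep(sign(counts[i]) * (if (counts[i] == 0) 0 else 1), n),
          rep("ION", n))
    }
    positions <- do.call(rbind, pos)
    charges <- unlist(chg)
    species <- unlist(spc)
    if (is.null(positions)) {
      positions <- matrix(numeric(0), ncol = 3)
      charges <- numeric(0); species <- character(0)
    }
    residual <- -sum(charges)
    if (abs(residual) > 0 || nrow(positions) == 0L) {
      positions <- rbind(positions, c(box_xy / 2, box_xy / 2, 0))
      charges <- c(charges, residual)
      species <- c(species, "COMP")
    }
    cfg <- pseudo_configuration(positions, charges, species,
                                box = c(box_xy, box_xy, Lz))
    attr(cfg, "stack") <- stack
    attr(cfg, "head_style") <- head_style
    cfg
  })
}

#' Potassium concentration of a configuration
#'
#' Ion number concentration per aqueous region and overall, in mol/L. The
#' physiologically matched systems fall in the 0.04-0.15 mol/L window.
#'
#' @param config a [pseudo_configuration()] built by [build_configuration()]
#'   (the declared stack geometry supplies the region volumes).
#' @return data frame with columns `region`, `n_ions`, `volume_nm3`,
#'   `mol_per_L`; the last row (`aqueous`) pools the three regions.
#' @export
ion_concentration <- function(config) {
  stopifnot(inherits(config, "pseudo_configuration"))
  stack <- attr(config, "stack")
  if (is.null(stack))
    stop("configuration carries no declared stack geometry")
  lb <- layer_boundaries(stack)
  A <- config$box[1] * config$box[2]
  z <- config$positions[, 3]
  ion <- config$species == "ION"
  reg <- list(R1 = c(lb$edges[5], lb$edges[6]),
              R2 = c(lb$edges[3], lb$edges[4]),
              R3 = c(lb$edges[1], lb$edges[2]))
  const <- memvolt_constants()$mol_per_L_per_e_per_nm3
  rows <- lapply(names(reg), function(rn) {
    v <- (reg[[rn]][2] - reg[[rn]][1]) * A
    if (v <= 0) stop("zero aqueous volume in region ", rn)
    n <- sum(ion & z >= reg[[rn]][1] & z < reg[[rn]][2])
    data.frame(region = rn, n_ions = n, volume_nm3 = v,
               mol_per_L = n / v * const)
  })
  out <- do.call(rbind, rows)
  vtot <- sum(out$volume_nm3); ntot <- sum(out$n_ions)
  rbind(out, data.frame(region = "aqueous", n_ions = ntot,
                        volume_nm3 = vtot, mol_per_L = ntot / vtot * const))
}

#' Pore radius schedule
#'
#' Prescribed time course of a planted cylindrical pore's radius, emulating
#' the fates observed under increasing lateral tension: fast reseal
#' (low tension), slow reseal (intermediate), and dilation (high tension).
#'
#' @param template one of `"none"`, `"constant"`, `"reseal_fast"`,
#'   `"reseal_slow"`, `"dilate"`.
#' @param t_open opening time, ns (radius is 0 before it).
#' @param r0 initial radius at opening, nm.
#' @param center_xy pore axis position `c(x, y)`, nm; `NULL` means box
#'   centre at build time.
#' @param t_reseal for `reseal_fast`: time from opening to closure, ns.
#' @param t_drain for `reseal_slow`: time constant of the slow linear
#'   shrinkage (closure would occur at `t_open + t_drain`), ns.
#' @param t_double for `dilate`: time for the radius to double, ns.
#' @return object of class `pore_schedule`; evaluate with
#'   [schedule_radius()].
#' @examples
#' sch <- pore_schedule("reseal_fast", t_open = 2, r0 = 0.75)
#' schedule_radius(sch, c(0, 2, 10, 17, 20))
#' @export
pore_schedule <- function(template = c("none", "constant", "reseal_fast",
                                       "reseal_slow", "dilate"),
                          t_open = 2, r0 = 0.75, center_xy = NULL,
                          t_reseal = 15, t_drain = 60, t_double = 18) {
  template <- match.arg(template)
  if (t_open < 0) stop("t_open must be >= 0")
  if (r0 < 0) stop("pore radius must be >= 0")
  structure(list(template = template, t_open = t_open, r0 = r0,
                 center_xy = center_xy, t_reseal = t_reseal,
                 t_drain = t_drain, t_double = t_double),
            class = "pore_schedule")
}

#' Evaluate a pore schedule
#'
#' @param schedule a [pore_schedule()].
#' @param t time(s), ns.
#' @return radius (nm) at each time, 0 before `t_open`.
#' @export
schedule_radius <- function(schedule, t) {
  stopifnot(inherits(schedule, "pore_schedule"))
  u <- pmax(0, t - schedule$t_open)
  open <- t >= schedule$t_open
  r <- switch(schedule$template,
              none = rep(0, length(t)),
              constant = schedule$r0 * open,
              reseal_fast = schedule$r0 * pmax(0, 1 - u / schedule$t_reseal) *
                open,
              reseal_slow = schedule$r0 * pmax(0, 1 - u / schedule$t_drain) *
                open,
              dilate = schedule$r0 * (1 + u / schedule$t_double) * open)
  as.numeric(r)
}

#' Multi-frame trajectory
#'
#' Ordered frames of [pseudo_configuration()] with strictly increasing time
#' stamps plus the pore schedule that generated them.
#'
#' @param frames list of configurations with `frame_time` set.
#' @param schedule the generating [pore_schedule()] (or `NULL`).
#' @return object of class `membrane_trajectory`.
#' @export
membrane_trajectory <- function(frames, schedule = NULL) {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "pseudo_configuration")))
  tt <- vapply(frames, function(f) f$frame_time, numeric(1))
  if (anyNA(tt) || is.unsorted(tt, strictly = TRUE))
    stop("frame times must be present and strictly increasing")
  structure(list(frames = frames, times = tt, schedule = schedule),
            class = "membrane_trajectory")
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  cat(sprintf("Membrane trajectory: %d frames, t = %g .. %g ns\n",
              length(x$frames), min(x$times), max(x$times)))
  if (!is.null(x$schedule))
    cat("  pore schedule:", x$schedule$template,
        sprintf("(t_open = %g ns, r0 = %g nm)\n",
                x$schedule$t_open, x$schedule$r0))
  invisible(x)
}

#' Build a synthetic trajectory with an optional planted pore
#'
#' Generates `frames` configurations at interval `dt`. Water-marker
#' particles (zero charge) fill the aqueous regions on a jittered lattice at
#' roughly the density of liquid water; for times past the schedule's
#' opening, a dense cylindrical column of water markers spans each membrane
#' slab at the scheduled radius, emulating the water channel of a
#' transmembrane pore. Optionally a stated number of R2 ions is relocated
#' across the membranes after opening to emulate leakage.
#'
#' @param stack a [layer_stack()].
#' @param box_xy lateral box edge, nm.
#' @param frames number of frames.
#' @param dt frame interval, ns.
#' @param schedule a [pore_schedule()].
#' @param seed integer seed.
#' @param water_density bulk water-marker density, nm^-3 (default 33,
#'   approximating 1 g/cm^3).
#' @param include_bulk_water logical; bulk water is irrelevant to pore
#'   detection (only the membrane slab interior is examined) and may be
#'   switched off for speed.
#' @param pore_fill_spacing lattice spacing of the pore column fill, nm;
#'   keep at or below the detection cell size so the channel is
#'   unambiguous.
#' @param leak_ions number of R2 ions moved to R1/R3 after opening.
#' @return a [membrane_trajectory()].
#' @export
build_trajectory <- function(stack, box_xy, frames, dt,
                             schedule = pore_schedule("none"),
                             seed = 1, water_density = 33,
                             include_bulk_water = TRUE,
                             pore_fill_spacing = 0.1,
                             leak_ions = 0) {
  stopifnot(inherits(stack, "layer_stack"), inherits(schedule, "pore_schedule"))
  if (frames < 1) stop("need at least one frame")
  if (dt <= 0) stop("dt must be > 0")
  base <- build_configuration(stack, box_xy, seed)
  lb <- layer_boundaries(stack)
  center <- schedule$center_xy %||% c(box_xy / 2, box_xy / 2)

  bulk <- NULL
  if (include_bulk_water && water_density > 0) {
    bulk <- with_seed(seed + 1L, {
      s <- water_density^(-1 / 3)
      aq <- list(c(lb$edges[1], lb$edges[2]),
                 c(lb$edges[3], lb$edges[4]),
                 c(lb$edges[5], lb$edges[6]))
      do.call(rbind, lapply(aq, function(rg) {
        if (rg[2] <= rg[1]) return(NULL)
        g <- expand.grid(x = seq(s / 2, box_xy - s / 2, by = s),
                         y = seq(s / 2, box_xy - s / 2, by = s),
                         z = seq(rg[1] + s / 2, rg[2] - s / 2, by = s))
        jit <- matrix(stats::runif(3 * nrow(g), -0.3 * s, 0.3 * s),
                      ncol = 3)
        as.matrix(g) + jit
      }))
    })
  }

  mslabs <- list(c(lb$edges[2], lb$edges[3]),   # m2
                 c(lb$edges[4], lb$edges[5]))   # m1
  column_xy <- function(r) {
    if (r <= 0) return(NULL)
    h <- pore_fill_spacing
    gx <- seq(center[1] - r, center[1] + r, by = h)
    gy <- seq(center[2] - r, center[2] + r, by = h)
    g <- expand.grid(x = gx, y = gy)
    g <- g[(g$x - center[1])^2 + (g$y - center[2])^2 <= r^2, , drop = FALSE]
    as.matrix(g)
  }

  leak_idx <- integer(0)
  if (leak_ions > 0) {
    r2_ions <- which(base$species == "ION" &
                       base$positions[, 3] >= lb$edges[3] &
                       base$positions[, 3] < lb$edges[4])
    leak_idx <- utils::head(r2_ions, leak_ions)
  }

  out <- vector("list", frames)
  for (i in seq_len(frames)) {
    t_i <- (i - 1L) * dt
    r <- schedule_radius(schedule, t_i)
    pos <- base$positions; chg <- base$charges; spc <- base$species
    if (length(leak_idx) > 0 && t_i >= schedule$t_open) {
      # alternate leaked ions into R1 and R3, mid-slab
      up <- seq_along(leak_idx) %% 2L == 1L
      pos[leak_idx[up], 3] <- (lb$edges[5] + lb$edges[6]) / 2
      pos[leak_idx[!up], 3] <- (lb$edges[1] + lb$edges[2]) / 2
    }
    extra <- list()
    if (!is.null(bulk)) extra[[length(extra) + 1L]] <- bulk
    if (r > 0) {
      xy <- column_xy(r)
      if (!is.null(xy) && nrow(xy) > 0) {
        for (ms in mslabs) {
          zz <- seq(ms[1], ms[2], by = pore_fill_spacing)
          extra[[length(extra) + 1L]] <-
            cbind(xy[rep(seq_len(nrow(xy)), each = length(zz)), ,
                     drop = FALSE],
                  rep(zz, times = nrow(xy)))
        }
      }
    }
    if (length(extra) > 0) {
      epos <- do.call(rbind, extra)
      pos <- rbind(pos, epos)
      chg <- c(chg, rep(0, nrow(epos)))
      spc <- c(spc, rep("WATER_MARK", nrow(epos)))
    }
    f <- pseudo_configuration(pos, chg, spc, base$box, frame_time = t_i)
    attr(f, "stack") <- stack
    attr(f, "planted_radius") <- r
    out[[i]] <- f
  }
  membrane_trajectory(out, schedule = schedule)
}
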