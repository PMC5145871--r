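#' Lateral membrane tension from box pressures
#'
#' \eqn{\Gamma = L_Z (P_Z - P_{Lat})}, converted from bar x nm to pN/nm
#' with a conversion factor derived from SI definitions
#' (1 bar nm = 0.1 pN/nm, see [memvolt_constants()]).
#'
#' @param L_Z box height, nm (> 0).
#' @param P_Z normal pressure, bar.
#' @param P_Lat lateral pressure, bar.
#' @return object of class `tension_record`: list with `L_Z`, `P_Z`,
#'   `P_Lat`, `gamma` (pN/nm) and the conversion constant used.
#' @examples
#' membrane_tension(L_Z = 20, P_Z = 1, P_Lat = -9.3)$gamma  # 20.6 pN/nm
#' @export
membrane_tension <- function(L_Z, P_Z, P_Lat) {
  if (!is.numeric(L_Z) || L_Z <= 0) stop("L_Z must be > 0")
  k <- memvolt_constants()$pN_per_nm_per_bar_nm
  structure(list(L_Z = L_Z, P_Z = P_Z, P_Lat = P_Lat,
                 gamma = L_Z * (P_Z - P_Lat) * k,
                 pN_per_nm_per_bar_nm = k),
            class = "tension_record")
}

#' @export
print.tension_record <- function(x, ...) {
  cat(sprintf(
    "Membrane tension: Gamma = %.4g pN/nm  (L_Z = %g nm, P_Z - P_Lat = %g bar,\n",
    x$gamma, x$L_Z, x$P_Z - x$P_Lat))
  cat(sprintf("  conversion: %g pN/nm per bar nm)\n", x$pN_per_nm_per_bar_nm))
  invisible(x)
}

#' Pressure difference producing a target tension
#'
#' Inverse of [membrane_tension()]: the `P_Z - P_Lat` (bar) that yields
#' tension `gamma` at box height `L_Z`.
#'
#' @param gamma target tension, pN/nm.
#' @param L_Z box height, nm.
#' @return pressure difference, bar.
#' @export
pressure_gap_for_tension <- function(gamma, L_Z) {
  if (L_Z <= 0) stop("L_Z must be > 0")
  gamma / (L_Z * memvolt_constants()$pN_per_nm_per_bar_nm)
}

#' Distance scan: voltage, pore formation and formation time vs D
#'
#' Mirrors the protocol of reducing the inter-membrane distance from
#' `d_start` in steps of `d_step`: at each distance the closed-form voltage
#' is evaluated (template built from the composition at `d_start`, then
#' re-closed under `policy`), a pore is predicted when the voltage magnitude
#' reaches `dv_critical`, and the critical distance is the largest scanned D
#' that forms a pore within the window.
#'
#' In `trajectory` mode a synthetic trajectory is generated per distance and
#' the formation time measured by pore detection. The coupling between
#' voltage and pore schedule is a threshold rule, not a kinetic model: above
#' threshold the planted pore opens at
#' `t_open = window * (dv_critical/|dV|)^2` (stronger overvoltage opens
#' faster), below threshold no pore is planted.
#'
#' @param composition named lipid fractions (see [lipid_mix_pops()]).
#' @param d_start,d_step,d_min scan grid, nm (defaults 6, 0.5, 2).
#' @param dv_critical threshold voltage magnitude, V.
#' @param window observation window, ns.
#' @param mode `"analytic"` or `"trajectory"`.
#' @param policy charge-closure policy, see [voltage_vs_distance()].
#' @param H_m,H_L,eps_r,area_per_lipid stack geometry parameters.
#' @param box_xy,cell_size,seed,dt trajectory-mode parameters.
#' @param include_bulk_water forwarded to [build_trajectory()].
#' @return a `scan_result` data frame with columns `D`, `dV1`, `dV2`,
#'   `dV_max`, `pore_formed`, `T` (ns, `NA` in analytic mode or when no
#'   pore forms); attributes `D_critical` (nm, or `NA` with
#'   `below_scan_range = TRUE` when no scanned distance forms a pore),
#'   `policy`, `mode`, `window`.
#' @examples
#' sc <- distance_scan(lipid_mix_pops(0.15), dv_critical = 1.0)
#' attr(sc, "D_critical")
#' @export
distance_scan <- function(composition, d_start = 6, d_step = 0.5,
                          d_min = 2, dv_critical, window = 20,
                          mode = c("analytic", "trajectory"),
                          policy = c("fixed_rho2", "fixed_counter_charge"),
                          H_m = 4, H_L = 4, eps_r = 3,
                          area_per_lipid = 0.65,
                          box_xy = 23, cell_size = 0.2, seed = 1, dt = 0.5,
                          include_bulk_water = FALSE) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  if (d_step <= 0) stop("d_step must be > 0")
  if (!is.numeric(dv_critical) || dv_critical < 0)
    stop("dv_critical must be a number >= 0")
  d_values <- seq(d_start, d_min, by = -d_step)
  template <- build_stack_params(composition, D = d_start, H_m = H_m,
                                 H_L = H_L, eps_r = eps_r,
                                 area_per_lipid = area_per_lipid)
  out <- voltage_vs_distance(template, d_values, policy)
  vmag <- abs(out$dV_max)
  out$pore_formed <- vmag >= dv_critical
  out$T <- NA_real_
  if (mode == "trajectory") {
    for (i in seq_len(nrow(out))) {
      if (!out$pore_formed[i]) next
      t_open <- window * (dv_critical / vmag[i])^2
      sch <- pore_schedule("constant", t_open = t_open, r0 = 0.75)
      s_i <- reclose_stack(template, out$D[i], policy)
      attr(s_i, "composition") <- composition
      attr(s_i, "area_per_lipid") <- area_per_lipid
      tr <- build_trajectory(s_i, box_xy = box_xy,
                             frames = floor(window / dt) + 1L, dt = dt,
                             schedule = sch, seed = seed + i,
                             include_bulk_water = include_bulk_water)
      ft <- pore_formation_time(tr, bounds_from_stack(s_i),
                                cell_size = cell_size, window = window)
      out$T[i] <- ft$time
      out$pore_formed[i] <- ft$formed
    }
  }
  formed <- which(out$pore_formed)
  attr(out, "scan") <- "distance_scan"
  attr(out, "mode") <- mode
  attr(out, "window") <- window
  attr(out, "dv_critical") <- dv_critical
  if (length(formed) > 0) {
    attr(out, "D_critical") <- max(out$D[formed])
    attr(out, "below_scan_range") <- FALSE
  } else {
    attr(out, "D_critical") <- NA_real_
    attr(out, "below_scan_range") <- TRUE
  }
  out
}

#' Composition scan: critical distance vs POPS percentage
#'
#' For each POPS fraction the Chol:DOPC:POPE:POPS mixture is built (see
#' [lipid_mix_pops()]), the voltage-distance relation is inverted and the
#' critical distance recorded. More anionic lipid means a larger critical
#' distance: pore formation starts from farther apart.
#'
#' @param pops_fractions POPS mole fractions in \[0, 1\].
#' @param dv_critical threshold voltage magnitude, V.
#' @param D_ref distance at which each template stack is built, nm.
#' @param H_m,H_L,eps_r,area_per_lipid geometry parameters.
#' @param policy charge-closure policy.
#' @param bracket search bracket for the critical distance, nm.
#' @return a `scan_result` data frame with columns `pops_pct`, `rho_m`,
#'   `D_critical`, `crossed` (fractions for which no crossing exists are
#'   flagged `crossed = FALSE` and excluded from the monotonicity
#'   assessment); attribute `monotone_nondecreasing`.
#' @examples
#' composition_scan(c(0.045, 0.06, 0.09, 0.12, 0.15), dv_critical = 1.0)
#' @export
composition_scan <- function(pops_fractions, dv_critical, D_ref = 6,
                             H_m = 4, H_L = 4, eps_r = 3,
                             area_per_lipid = 0.65,
                             policy = c("fixed_rho2",
                                        "fixed_counter_charge"),
                             bracket = c(0.5, 10)) {
  policy <- match.arg(policy)
  stopifnot(all(pops_fractions >= 0), all(pops_fractions <= 1))
  rows <- lapply(pops_fractions, function(p) {
    comp <- lipid_mix_pops(p)
    s <- build_stack_params(comp, D = D_ref, H_m = H_m, H_L = H_L,
                            eps_r = eps_r, area_per_lipid = area_per_lipid)
    dc <- tryCatch(critical_distance(s, dv_critical, policy = policy,
                                     bracket = bracket),
                   error = function(e) NA_real_)
    data.frame(pops_pct = 100 * p, rho_m = s$rho_m1,
               D_critical = as.numeric(dc), crossed = !is.na(dc))
  })
  out <- do.call(rbind, rows)
  ok <- out$crossed
  mono <- if (sum(ok) >= 2) {
    o <- order(out$pops_pct[ok])
    !is.unsorted(out$D_critical[ok][o])
  } else TRUE
  structure(out,
            class = c("scan_result", "data.frame"),
            scan = "composition_scan",
            policy = policy,
            dv_critical = dv_critical,
            monotone_nondecreasing = mono)
}
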