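#' Detect transmembrane pores in a configuration frame
#'
#' Grid-based water-channel detection. The membrane plane is tiled into
#' square cells of `cell_size`; a cell column is *open* for a membrane when
#' water occupancy is continuous across the slab, i.e. every Z sub-bin of
#' thickness `cell_size` between the membrane faces contains at least one
#' water-marker particle in that column. Open cells are grouped by
#' 4-connectivity with periodic wrap in X and Y; each connected component is
#' one pore with area `cells x cell_area` and equivalent circular diameter
#' \eqn{2\sqrt{A/\pi}}.
#'
#' @param frame a [pseudo_configuration()] containing `WATER_MARK` (or
#'   imported water) particles.
#' @param bounds a [membrane_bounds()]; must lie inside the box.
#' @param cell_size grid cell edge, nm (default 0.2).
#' @param water_species species label(s) counting as water.
#' @return object of class `pore_record`: list with `frame_time` and a data
#'   frame `pores` (columns `membrane`, `area`, `equivalent_diameter`,
#'   `centroid_x`, `centroid_y`, `member_cells`).
#' @examples
#' s <- build_stack_params(lipid_mix_pops(0.15), D = 3)
#' tr <- build_trajectory(s, box_xy = 6, frames = 1, dt = 1,
#'   schedule = pore_schedule("constant", t_open = 0, r0 = 0.75),
#'   include_bulk_water = FALSE)
#' detect_pores(tr$frames[[1]], locate_membranes(s))
#' @export
detect_pores <- function(frame, bounds, cell_size = 0.2,
                         water_species = "WATER_MARK") {
  stopifnot(inherits(frame, "pseudo_configuration"),
            inherits(bounds, "membrane_bounds"))
  if (cell_size <= 0) stop("cell_size must be > 0")
  Lz <- frame$box[3]
  faces <- c(bounds$m1, bounds$m2)
  if (any(faces < -Lz / 2 - 1e-9) || any(faces > Lz / 2 + 1e-9))
    stop("membrane bounds outside the box")
  Lx <- frame$box[1]; Ly <- frame$box[2]
  nx <- max(1L, round(Lx / cell_size))
  ny <- max(1L, round(Ly / cell_size))
  dx <- Lx / nx; dy <- Ly / ny
  wat <- frame$species %in% water_species
  pores <- list()
  for (mname in c("m1", "m2")) {
    b <- bounds[[mname]]
    nz <- max(1L, round((b[2] - b[1]) / cell_size))
    dz <- (b[2] - b[1]) / nz
    sel <- wat & frame$positions[, 3] >= b[1] & frame$positions[, 3] <= b[2]
    if (!any(sel)) next
    px <- frame$positions[sel, 1]; py <- frame$positions[sel, 2]
    pz <- frame$positions[sel, 3]
    ix <- pmin(nx - 1L, pmax(0L, floor(px / dx)))
    iy <- pmin(ny - 1L, pmax(0L, floor(py / dy)))
    iz <- pmin(nz - 1L, pmax(0L, floor((pz - b[1]) / dz)))
    col_id <- ix + nx * iy
    # number of distinct occupied sub-bins per column
    key <- paste(col_id, iz)
    occ <- unique(data.frame(col = col_id, iz = iz)[!duplicated(key), ])
    counts <- table(occ$col)
    open_cols <- as.integer(names(counts))[as.integer(counts) == nz]
    if (length(open_cols) == 0) next
    comp <- label_components_periodic(open_cols, nx, ny)
    for (cc in comp) {
      ncell <- length(cc$cells)
      area <- ncell * dx * dy
      pores[[length(pores) + 1L]] <- data.frame(
        membrane = mname,
        area = area,
        equivalent_diameter = 2 * sqrt(area / pi),
        centroid_x = ((mean(cc$ux) + 0.5) * dx) %% Lx,
        centroid_y = ((mean(cc$uy) + 0.5) * dy) %% Ly,
        member_cells = ncell)
    }
  }
  pores <- if (length(pores)) do.call(rbind, pores) else
    data.frame(membrane = character(0), area = numeric(0),
               equivalent_diameter = numeric(0), centroid_x = numeric(0),
               centroid_y = numeric(0), member_cells = integer(0))
  structure(list(frame_time = frame$frame_time, pores = pores),
            class = "pore_record")
}

#' @export
print.pore_record <- function(x, ...) {
  cat(sprintf("Pore record (t = %s ns): %d pore(s)\n",
              format(x$frame_time), nrow(x$pores)))
  if (nrow(x$pores)) print.data.frame(x$pores, row.names = FALSE)
  invisible(x)
}

# BFS connected-component labelling of open cells on an nx x ny torus,
# 4-connectivity. Returns, per component, the member cell ids and unwrapped
# integer coordinates (for centroids across the periodic seam).
label_components_periodic <- function(cells, nx, ny) {
  open <- new.env(hash = TRUE, parent = emptyenv())
  for (cid in cells) assign(as.character(cid), TRUE, envir = open)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  comps <- list()
  for (cid in cells) {
    if (!is.null(seen[[as.character(cid)]])) next
    # BFS from cid, carrying unwrapped coordinates
    x0 <- cid %% nx; y0 <- cid %/% nx
    queue <- list(c(cid, x0, y0))
    seen[[as.character(cid)]] <- TRUE
    members <- integer(0); ux <- numeric(0); uy <- numeric(0)
    while (length(queue) > 0) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, cur[1]); ux <- c(ux, cur[2]); uy <- c(uy, cur[3])
      cx <- cur[1] %% nx; cy <- cur[1] %/% nx
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nxx <- (cx + d[1]) %% nx; nyy <- (cy + d[2]) %% ny
        nid <- nxx + nx * nyy
        k <- as.character(nid)
        if (is.null(open[[k]]) || !is.null(seen[[k]])) next
        seen[[k]] <- TRUE
        queue[[length(queue) + 1L]] <- c(nid, cur[2] + d[1], cur[3] + d[2])
      }
    }
    comps[[length(comps) + 1L]] <- list(cells = members, ux = ux, uy = uy)
  }
  comps
}

#' Per-frame pore size series of a trajectory
#'
#' Runs [detect_pores()] on every frame and reports the largest equivalent
#' diameter present (0 when no pore is open).
#'
#' @param trajectory a [membrane_trajectory()].
#' @param bounds a [membrane_bounds()].
#' @param cell_size detection cell size, nm.
#' @param membrane `"both"`, `"m1"` or `"m2"`.
#' @return data frame with columns `t` (ns) and `diameter` (nm).
#' @export
pore_size_series <- function(trajectory, bounds, cell_size = 0.2,
                             membrane = "both") {
  stopifnot(inherits(trajectory, "membrane_trajectory"))
  rows <- lapply(trajectory$frames, function(f) {
    rec <- detect_pores(f, bounds, cell_size)
    p <- rec$pores
    if (membrane != "both") p <- p[p$membrane == membrane, , drop = FALSE]
    data.frame(t = f$frame_time,
               diameter = if (nrow(p)) max(p$equivalent_diameter) else 0)
  })
  do.call(rbind, rows)
}

#' Time of first pore formation
#'
#' @param trajectory a [membrane_trajectory()].
#' @param bounds a [membrane_bounds()].
#' @param cell_size detection cell size, nm.
#' @param window observation window, ns (default 20); frames after it are
#'   not examined.
#' @return list with `formed` (logical), `time` (ns of the first frame with
#'   at least one detected pore in either membrane, or `NA`), and `window`.
#' @export
pore_formation_time <- function(trajectory, bounds, cell_size = 0.2,
                                window = 20) {
  stopifnot(inherits(trajectory, "membrane_trajectory"))
  if (length(trajectory$frames) == 0) stop("empty trajectory")
  for (f in trajectory$frames) {
    if (f$frame_time > window) break
    rec <- detect_pores(f, bounds, cell_size)
    if (nrow(rec$pores) > 0)
      return(list(formed = TRUE, time = f$frame_time, window = window))
  }
  list(formed = FALSE, time = NA_real_, window = window)
}

#' Pore size distribution with Gaussian fit
#'
#' Histograms equivalent pore diameters and, given at least `min_n`
#' observations, fits a Gaussian curve \eqn{a\,e^{-(x-\mu)^2/2\sigma^2}} to
#' the histogram by least squares.
#'
#' @param x numeric vector of diameters (nm), or a list of `pore_record`s
#'   whose pooled diameters are used.
#' @param breaks passed to [graphics::hist()]; default chooses roughly
#'   `sqrt(n)` bins.
#' @param min_n minimum observations for fitting (default 10).
#' @return list with `n`, `histogram`, `fit_available`, and when fitted
#'   `mean`, `sigma`, `amplitude`, `residual` (root-mean-square of the
#'   density residuals).
#' @examples
#' d <- stats::rnorm(200, 1.5, 0.25)
#' fit <- pore_size_distribution(d)
#' c(fit$mean, fit$sigma)
#' @export
pore_size_distribution <- function(x, breaks = NULL, min_n = 10) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- unlist(lapply(x, function(r) {
      stopifnot(inherits(r, "pore_record"))
      r$pores$equivalent_diameter
    }))
  }
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) stop("no pore observations")
  if (is.null(breaks)) breaks <- max(6L, ceiling(sqrt(n)))
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  out <- list(n = n, histogram = h, fit_available = FALSE)
  if (n < min_n) return(out)
  mids <- h$mids; dens <- h$density
  mu0 <- mean(x); s0 <- max(stats::sd(x), 1e-6)
  # weights ~ 1/Var(count): counting noise grows with bin occupancy
  w <- 1 / pmax(h$counts, 1)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(dens ~ a * exp(-(mids - mu)^2 / (2 * s^2)),
                        start = list(a = max(dens), mu = mu0, s = s0),
                        weights = w, lower = c(0, -Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate histograms (e.g. all mass in one bin): moment estimates
    out$fit_available <- TRUE
    out$mean <- mu0; out$sigma <- stats::sd(x); out$amplitude <- max(dens)
    out$residual <- 0
    return(out)
  }
  cf <- stats::coef(fit)
  out$fit_available <- TRUE
  out$mean <- unname(cf["mu"])
  out$sigma <- abs(unname(cf["s"]))
  out$amplitude <- unname(cf["a"])
  out$residual <- sqrt(mean(stats::resid(fit)^2))
  out
}

#' Classify the fate of a pore from its size series
#'
#' Mirrors the tension-regulated regimes: under low tension the pore
#' reseals quickly, intermediate tension prolongs it, and high tension
#' drives dilation.
#' \describe{
#'   \item{`RESEAL_FAST`}{diameter reaches 0 within the window.}
#'   \item{`DILATE`}{final diameter exceeds the initial by at least
#'     `growth_threshold` (fractional) with a non-decreasing trend over the
#'     last third of the window (decreases up to `trend_tol` tolerated).}
#'   \item{`RESEAL_SLOW`}{still open at the window end without qualifying
#'     growth (including a constant-diameter series).}
#' }
#'
#' @param size_series data frame with columns `t` (ns) and `diameter` (nm),
#'   starting at first detection.
#' @param window classification window from the start of the series, ns.
#' @param growth_threshold fractional growth for `DILATE` (default 0.25).
#' @param trend_tol tolerated fitted net decrease over the last third of
#'   the window in the trend check, nm (default 0.2, one detection cell).
#' @param closed_tol diameter at or below which the pore counts as closed.
#' @return object of class `pore_fate`: list with `label`, `close_time`
#'   (ns, `NA` unless closure was observed), `initial_diameter`,
#'   `final_diameter`.
#' @export
classify_fate <- function(size_series, window = 20,
                          growth_threshold = 0.25, trend_tol = 0.2,
                          closed_tol = 0) {
  stopifnot(is.data.frame(size_series),
            all(c("t", "diameter") %in% names(size_series)))
  if (nrow(size_series) == 0) stop("empty size series")
  ss <- size_series[order(size_series$t), ]
  t0 <- ss$t[1L]
  ss <- ss[ss$t <= t0 + window, , drop = FALSE]
  d0 <- ss$diameter[1L]
  closed <- which(ss$diameter <= closed_tol)
  closed <- closed[closed > 1L]
  if (length(closed) > 0) {
    return(structure(list(label = "RESEAL_FAST",
                          close_time = ss$t[closed[1L]],
                          initial_diameter = d0,
                          final_diameter = 0),
                     class = "pore_fate"))
  }
  dend <- ss$diameter[nrow(ss)]
  last_third <- ss[ss$t >= t0 + 2 * window / 3, , drop = FALSE]
  # non-decreasing trend: the fitted net change over the last third must
  # not fall by more than trend_tol (robust to per-frame detection noise)
  trend_ok <- nrow(last_third) < 2 || {
    sl <- stats::coef(stats::lm(diameter ~ t, data = last_third))[[2]]
    sl * (max(last_third$t) - min(last_third$t)) >= -trend_tol
  }
  label <- if (dend >= d0 * (1 + growth_threshold) && trend_ok)
    "DILATE" else "RESEAL_SLOW"
  structure(list(label = label, close_time = NA_real_,
                 initial_diameter = d0, final_diameter = dend),
            class = "pore_fate")
}

#' @export
print.pore_fate <- function(x, ...) {
  cat("Pore fate:", x$label, "\n")
  cat(sprintf("  diameter %.3g -> %.3g nm", x$initial_diameter,
              x$final_diameter))
  if (!is.na(x$close_time)) cat(sprintf(", closed at %g ns", x$close_time))
  cat("\n")
  invisible(x)
}
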