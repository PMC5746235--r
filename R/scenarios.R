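#' Smoothed disk indicator field
#'
#' A twice-differentiable approximation of the indicator of the disk
#' `r < r0`: value `amplitude` for `r <= r0 - band/2`, zero for
#' `r >= r0 + band/2`, and a C2 quintic ramp `10 s^3 - 15 s^4 + 6 s^5`
#' across the boundary (first and second derivatives vanish at both ramp
#' ends).  The ramp is centered on `r0`, so the mass equals
#' `pi r0^2 * amplitude` up to `O(band^2)`.
#'
#' @param mesh a complete `vrl_mesh`.
#' @param center disk center `c(x, y)`; default domain center.
#' @param r0 disk radius.
#' @param band ramp width; default `2 * h` (resolution-limited smoothing).
#' @param amplitude plateau value.
#' @return numeric field vector.
#' @export
smoothed_disk <- function(mesh, center = mesh$domain / 2, r0,
                          band = 2 * mesh$h, amplitude = 1) {
  stopifnot(r0 > 0, band > 0, band <= 2 * r0)
  r <- sqrt((mesh$nodes[, 1] - center[1])^2 + (mesh$nodes[, 2] - center[2])^2)
  amplitude * ramp_c2((r0 - r) / band + 0.5)
}

# C2 smoothstep ramp: 0 for s <= 0, 1 for s >= 1, quintic in between
ramp_c2 <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s^3 * (10 - 15 * s + 6 * s^2)
}

#' Smoothed half-plane indicator field
#'
#' `amplitude` on the `side` of the vertical line `x = x0`, zero on the
#' other, with a C2 ramp of width `band` across the line.
#'
#' @inheritParams smoothed_disk
#' @param x0 position of the interface; default mid-domain.
#' @param side `"left"` or `"right"`.
#' @export
smoothed_halfplane <- function(mesh, x0 = mesh$domain[1] / 2,
                               band = 2 * mesh$h, amplitude = 1,
                               side = c("left", "right")) {
  side <- match.arg(side)
  s <- (x0 - mesh$nodes[, 1]) / band + 0.5
  if (side == "right") s <- 1 - s
  amplitude * ramp_c2(s)
}

#' Scenario catalogue
#'
#' Builds the initial conditions and settings of the simulation experiments:
#' \describe{
#'   \item{pv_only}{P. vortex disk alone (`b2 = 0`).}
#'   \item{ec_only}{E. coli disk alone (`b1 = 0`); cannot move.}
#'   \item{mixed}{both species on one disk; the ring-forming case.}
#'   \item{two_colonies}{two separated mixed disks; phases are tracked per
#'     connected component until the colonies merge and synchronize.}
#'   \item{half_plane_antibiotic}{mixed disk, antibiotic only on the left
#'     half (amplitude 1, smoothed over `2h`).}
#'   \item{three_species}{mixed disk plus algae, three-species parameters.}
#'   \item{s2_rule}{mixed colony with the `b1 + b2` switching rule
#'     (thresholds 0.029/0.066).}
#' }
#'
#' @param name scenario name (see above).
#' @param params parameter list; defaults to [default_params()] (with
#'   `three_species = TRUE` for the three-species scenario).
#' @param horizon simulation horizon in time units (default 20, the
#'   reduced-scale setting).
#' @param phase_cfg optional [phase_config()] override.
#' @return An object of class `scenario` with an `init(mesh)` method field.
#' @export
make_scenario <- function(name = c("pv_only", "ec_only", "mixed",
                                   "two_colonies", "half_plane_antibiotic",
                                   "three_species", "s2_rule"),
                          params = NULL, horizon = 20, phase_cfg = NULL) {
  name <- match.arg(name)
  stopifnot(horizon > 0)
  if (is.null(params))
    params <- default_params(three_species = name == "three_species")
  if (is.null(phase_cfg))
    phase_cfg <- if (name == "s2_rule") phase_config(rule = "b1_plus_b2")
      else phase_config(bbar_min = params$bbar_min,
                        bbar_max = params$bbar_max)

  init <- switch(name,
    pv_only = function(mesh) {
      d <- scenario_disk(mesh, params)
      list(b1 = d$field, b2 = 0 * d$field, centers = d$centers)
    },
    ec_only = function(mesh) {
      d <- scenario_disk(mesh, params)
      list(b1 = 0 * d$field, b2 = d$field, centers = d$centers)
    },
    mixed = , s2_rule = function(mesh) {
      d <- scenario_disk(mesh, params)
      list(b1 = d$field, b2 = d$field, centers = d$centers)
    },
    two_colonies = function(mesh) {
      L <- mesh$domain
      c1 <- c(0.3 * L[1], 0.5 * L[2]); c2 <- c(0.7 * L[1], 0.5 * L[2])
      r0 <- params$r0 * min(L)
      d <- smoothed_disk(mesh, c1, r0) + smoothed_disk(mesh, c2, r0)
      list(b1 = d, b2 = d, centers = rbind(c1, c2))
    },
    half_plane_antibiotic = function(mesh) {
      d <- scenario_disk(mesh, params)
      list(b1 = d$field, b2 = d$field,
           a = smoothed_halfplane(mesh, amplitude = 1, side = "left"),
           centers = d$centers)
    },
    three_species = function(mesh) {
      d <- scenario_disk(mesh, params)
      list(b1 = d$field, b2 = d$field, X = d$field, centers = d$centers)
    })

  structure(list(name = name, params = params, phase_cfg = phase_cfg,
                 horizon = horizon, init = init,
                 multi_colony = name == "two_colonies"),
            class = "scenario")
}

scenario_disk <- function(mesh, params) {
  ctr <- mesh$domain / 2
  list(field = smoothed_disk(mesh, ctr, params$r0 * min(mesh$domain)),
       centers = rbind(ctr))
}

#' Colony radius
#'
#' Robust front-position estimate: the 95th percentile of node distances
#' from the (fixed) colony center over the support
#' `{b1 + b2 > threshold}`; 0 when the support is empty.  For two disjoint
#' colonies this measures the extent covering both (documented behavior).
#'
#' @param b1,b2 density fields (`b2` may be `NULL`).
#' @param mesh the mesh.
#' @param center colony center (initial inoculation point).
#' @param threshold support threshold (default `1e-6`).
#' @param prob quantile used for robustness (default 0.95).
#' @export
colony_radius <- function(b1, b2 = NULL, mesh, center = mesh$domain / 2,
                          threshold = 1e-6, prob = 0.95) {
  b <- if (is.null(b2)) b1 else b1 + b2
  sup <- b > threshold
  if (!any(sup)) return(0)
  r <- sqrt((mesh$nodes[sup, 1] - center[1])^2 +
            (mesh$nodes[sup, 2] - center[2])^2)
  as.numeric(stats::quantile(r, prob, names = FALSE))
}

#' Cross-section profile of a field
#'
#' Values of the nodes lying within a strip of half-width `width` around a
#' line through `center` at angle `angle`, ordered by the signed coordinate
#' along the line.
#'
#' @param values field vector.
#' @param mesh the mesh.
#' @param center point on the line; default domain center.
#' @param angle line angle in radians (0 = x axis).
#' @param width strip half-width; default `mesh$h`.
#' @return data frame with columns `s` (signed along-line coordinate) and
#'   `value`.
#' @export
cross_section <- function(values, mesh, center = mesh$domain / 2, angle = 0,
                          width = mesh$h) {
  dx <- mesh$nodes[, 1] - center[1]; dy <- mesh$nodes[, 2] - center[2]
  along <- dx * cos(angle) + dy * sin(angle)
  perp <- -dx * sin(angle) + dy * cos(angle)
  keep <- abs(perp) <= width
  out <- data.frame(s = along[keep], value = values[keep])
  out[order(out$s), ]
}

#' Radial profile of a field
#'
#' Area-weighted mean of the field over concentric radial bins around
#' `center`; the read-out in which the rings of the accumulated density
#' `s_i + b_i` appear.
#'
#' @inheritParams cross_section
#' @param nbins number of radial bins; default one per lattice unit.
#' @param rmax outer radius; default the largest node distance.
#' @return data frame with columns `r` (bin midpoint) and `value`.
#' @export
radial_profile <- function(values, mesh, center = mesh$domain / 2,
                           nbins = NULL, rmax = NULL) {
  r <- sqrt((mesh$nodes[, 1] - center[1])^2 +
            (mesh$nodes[, 2] - center[2])^2)
  if (is.null(rmax)) rmax <- max(r)
  if (is.null(nbins)) nbins <- max(8L, ceiling(rmax / mesh$h))
  bin <- pmin(pmax(ceiling(r / rmax * nbins), 1L), nbins)
  wsum <- tapply(mesh$A * values, bin, sum)
  asum <- tapply(mesh$A, bin, sum)
  mids <- (as.integer(names(wsum)) - 0.5) * rmax / nbins
  data.frame(r = mids, value = as.numeric(wsum / asum))
}

#' Count rings in a radial profile
#'
#' Number of alternating high-density bands: local maxima of the (lightly
#' smoothed) profile whose height exceeds the neighboring minima on both
#' sides by at least `min_prominence` times the profile maximum.
#'
#' @param profile data frame from [radial_profile()].
#' @param min_prominence relative prominence threshold (default 0.1).
#' @param smooth running-mean half-width in bins (default 1).
#' @export
count_rings <- function(profile, min_prominence = 0.1, smooth = 1) {
  v <- profile$value
  v[!is.finite(v)] <- 0
  if (smooth > 0) {
    kern <- rep(1, 2 * smooth + 1)
    v <- as.numeric(stats::filter(v, kern / sum(kern), sides = 2))
    v <- v[!is.na(v)]
  }
  if (length(v) < 3 || max(v) <= 0) return(0L)
  scale <- max(v) * min_prominence
  # alternating extrema scan: count peaks with two-sided prominence;
  # the baseline trough is zero density, so a central plateau counts
  count <- 0L
  trough <- 0
  peak <- -Inf
  rising <- TRUE
  for (t in seq_along(v)) {
    if (rising) {
      peak <- max(peak, v[t])
      if (peak - v[t] >= scale) {       # fell off a peak
        if (peak - trough >= scale) count <- count + 1L
        rising <- FALSE
        trough <- v[t]
      }
    } else {
      trough <- min(trough, v[t])
      if (v[t] - trough >= scale) {     # climbing again
        rising <- TRUE
        peak <- v[t]
      }
    }
  }
  # trailing peak that never fell off (profile ends high)
  if (rising && peak - trough >= scale && peak > -Inf) count <- count + 1L
  count
}

#' Run a scenario
#'
#' Advances the scenario with the explicit scheme (compiled integration
#' loop) or the Crank-Nicolson stepper, recording colony radius, mean
#' density, phase and support-component count at regular intervals and
#' storing field snapshots.  Phase is re-evaluated after every step; in the
#' two-colony scenario each connected component of the colony support
#' carries its own builder/explorer phase until the colonies merge (a
#' merged component adopts the phase holding the majority of its mass).
#' Deterministic for a given mesh.
#'
#' @param scenario a [make_scenario()] object.
#' @param mesh a complete `vrl_mesh`.
#' @param cfg an [integrator_config()]; defaults to forward Euler with the
#'   scenario's `dt`.
#' @param record_every diagnostics cadence in steps (default 50).
#' @param snapshot_times times at which to store all fields; default the
#'   horizon only.
#' @param verbose print a run summary at the end.
#' @return A `colony_diagnostics` object: `series` data frame
#'   (`t`, `radius`, `bbar`, `phase`, `ncomp`, masses), `snapshots` (each
#'   with an `accumulated` live-plus-dead density), `state` (final fields),
#'   `switches`, `clipped`.
#' @export
run_scenario <- function(scenario, mesh,
                         cfg = integrator_config(dt = scenario$params$dt),
                         record_every = 50L, snapshot_times = NULL,
                         verbose = FALSE) {
  params <- scenario$params
  pcfg <- scenario$phase_cfg
  ic <- scenario$init(mesh)
  centers <- ic$centers
  center <- colMeans(centers)
  if (is.null(snapshot_times)) snapshot_times <- scenario$horizon
  n <- nrow(mesh$nodes)
  as_f <- function(v, def) {
    if (is.null(v)) v <- def
    if (length(v) == 1) rep(v, n) else as.numeric(v)
  }
  b1 <- as_f(ic$b1, 0); b2 <- as_f(ic$b2, 0)
  n0f <- as_f(ic$n, params$n0); a0f <- as_f(ic$a, params$a0)
  hasX <- !is.null(ic$X)

  nsteps <- as.integer(ceiling(scenario$horizon / cfg$dt))
  snap_steps <- as.integer(pmin(pmax(round(snapshot_times / cfg$dt), 1L),
                                nsteps))

  if (cfg$scheme == "forward_euler") {
    res <- run_core_cpp(mesh$edges$i, mesh$edges$j, mesh$wij, mesh$wji,
                        mesh$A, mesh$nodes[, 1], mesh$nodes[, 2], center,
                        b1, b2, n0f, a0f,
                        if (hasX) as_f(ic$X, 0) else NULL, hasX,
                        params[!vapply(params, is.null, TRUE)],
                        pcfg$support_threshold, pcfg$rule == "b1_plus_b2",
                        pcfg$bbar_min, pcfg$bbar_max, scenario$multi_colony,
                        cfg$dt, nsteps, as.integer(record_every),
                        snap_steps, 0.95, 0)
    keep <- seq_len(res$nrec)
    lab <- c("builder", "explorer", "mixed")
    series <- data.frame(t = res$series$t[keep],
                         radius = res$series$radius[keep],
                         bbar = res$series$bbar[keep],
                         phase = lab[res$series$phase[keep] + 1L],
                         ncomp = res$series$ncomp[keep],
                         mass_b1 = res$series$mass_b1[keep],
                         mass_b2 = res$series$mass_b2[keep],
                         mass_a = res$series$mass_a[keep])
    snapshots <- lapply(res$snapshots, function(s) {
      if (is.null(s)) return(NULL)
      s$accumulated <- s$s1 + s$b1 + s$s2 + s$b2
      s
    })
    fin <- res$final
    state <- list(mesh = mesh, b1 = fin$b1, b2 = fin$b2, n = fin$n,
                  a = fin$a, X = fin$X, s1 = fin$s1, s2 = fin$s2,
                  sX = fin$sX, phase = lab[res$phase + 1L],
                  t = nsteps * cfg$dt, params = params, phase_cfg = pcfg)
    switches <- res$switches
    clipped <- res$clipped
  } else {
    if (scenario$multi_colony)
      stop("per-component phases require the forward-Euler scheme")
    st <- model_state(mesh, b1 = b1, b2 = b2, n = n0f, a = a0f,
                      X = if (hasX) as_f(ic$X, 0) else NULL,
                      params = params, phase_cfg = pcfg)
    nrec <- nsteps %/% record_every + 1L
    series <- data.frame(t = numeric(nrec), radius = numeric(nrec),
                         bbar = numeric(nrec), phase = character(nrec),
                         ncomp = 1L, mass_b1 = numeric(nrec),
                         mass_b2 = numeric(nrec), mass_a = numeric(nrec))
    snapshots <- vector("list", length(snap_steps))
    rec <- 0L
    record <- function(st) {
      rec <<- rec + 1L
      series[rec, ] <<- list(st$t,
        colony_radius(st$b1, st$b2, mesh, center,
                      threshold = pcfg$support_threshold),
        st$bbar %||% mean_colony_density(st$b1, st$b2, pcfg, mesh),
        st$phase, 1L, total_mass(st$b1, mesh),
        if (is.null(st$b2)) 0 else total_mass(st$b2, mesh),
        total_mass(st$a, mesh))
    }
    record(st)
    for (k in seq_len(nsteps)) {
      st <- step_model(st, params, cfg)
      if (k %% record_every == 0L) record(st)
      for (s in which(snap_steps == k))
        snapshots[[s]] <- list(t = st$t, b1 = st$b1, b2 = st$b2, n = st$n,
                               a = st$a, X = st$X, s1 = st$s1, s2 = st$s2,
                               sX = st$sX,
                               accumulated = st$s1 + st$b1 +
                                 (if (is.null(st$b2)) 0 else st$s2 + st$b2))
    }
    series <- series[seq_len(rec), ]
    state <- st
    switches <- st$switches
    clipped <- st$clipped
  }
  if (verbose)
    message(sprintf("%s: %d phase switch(es), final radius %.2f",
                    scenario$name, switches, utils::tail(series$radius, 1)))
  structure(list(scenario = scenario$name, params = params,
                 series = series, snapshots = snapshots,
                 snapshot_times = snapshot_times,
                 center = center, centers = centers, state = state,
                 switches = switches, clipped = clipped,
                 horizon = scenario$horizon, dt = cfg$dt),
            class = "colony_diagnostics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.colony_diagnostics <- function(x, ...) {
  cat(sprintf("scenario '%s': horizon %g, dt %g, %d phase switch(es)\n",
              x$scenario, x$horizon, x$dt, x$switches))
  s <- x$series
  cat(sprintf("  radius %.2f -> %.2f, final bbar %.4g, final phase %s\n",
              s$radius[1], utils::tail(s$radius, 1),
              utils::tail(s$bbar, 1), utils::tail(s$phase, 1)))
  invisible(x)
}

#' Synchronization of a two-colony run
#'
#' From the recorded series: the component count over time and the first
#' time at which the colonies form a single connected component (and hence
#' share one global phase).
#'
#' @param diag a `colony_diagnostics` from the `two_colonies` scenario.
#' @return list with `ncomp` series, `t_merge` (NA if never merged) and
#'   `merged` flag.
#' @export
synchronization_metric <- function(diag) {
  s <- diag$series
  merged <- s$ncomp == 1L
  list(ncomp = s$ncomp,
       t_merge = if (any(merged)) min(s$t[merged]) else NA_real_,
       merged = any(merged))
}

#' S1 sensitivity perturbations
#'
#' The parameter sweep of the robustness study: initial antibiotic and
#' nutrient levels +-50%, the upper switching threshold +-20%, the
#' advection coefficient +-50% and the E. coli self-diffusion +-20%.
#'
#' @return named list of parameter-override lists.
#' @export
s1_perturbations <- function() {
  list(a0_minus = list(a0 = 1), a0_plus = list(a0 = 3),
       n0_minus = list(n0 = 1), n0_plus = list(n0 = 3),
       bbarmax_minus = list(bbar_max = 0.0264),
       bbarmax_plus = list(bbar_max = 0.0396),
       C2_minus = list(C2 = 4), C2_plus = list(C2 = 8),
       D2_minus = list(D2 = 8e-5), D2_plus = list(D2 = 1.2e-4))
}

#' Run the sensitivity sweep
#'
#' Runs the mixed-colony scenario under each perturbation in
#' `perturbations` (default [s1_perturbations()]) and summarizes ring
#' formation.
#'
#' @param mesh a complete `vrl_mesh`.
#' @param horizon per-run horizon (default 20).
#' @param perturbations named list of parameter overrides.
#' @param cfg integrator configuration (default forward Euler, table dt).
#' @return data frame: run name, switches, ring count, final radius.
#' @export
run_sweep <- function(mesh, horizon = 20, perturbations = s1_perturbations(),
                      cfg = NULL) {
  rows <- lapply(names(perturbations), function(nm) {
    ov <- perturbations[[nm]]
    params <- do.call(default_params, ov)
    # perturbing bbar_max moves the phase thresholds with it
    scn <- make_scenario("mixed", params = params, horizon = horizon)
    d <- run_scenario(scn, mesh,
                      cfg = cfg %||% integrator_config(dt = params$dt))
    prof <- radial_profile(d$snapshots[[1]]$accumulated, mesh, d$center)
    data.frame(run = nm, switches = d$switches,
               rings = count_rings(prof),
               radius = utils::tail(d$series$radius, 1))
  })
  do.call(rbind, rows)
}
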