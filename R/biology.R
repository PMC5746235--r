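#' Model parameters
#'
#' Default rate/diffusion/threshold constants of the two-species colony
#' model, in dimensionless simulation units (lengths in reference-lattice
#' units, one time unit ~ 0.5 h, densities as area fractions scaled so that
#' `bbar_max` ~ 50% coverage).  `three_species = TRUE` adds the algae
#' parameters and applies the three-species overrides
#' (`n0 = 0.5`, `bbar_max = 0.04`, `bbar_min = 0.02`).
#'
#' Reproduction, nutrient-consumption and antibiotic-degradation rates are
#' linear: `beta_i(n) = beta_i * n`, `lambda_i(n) = lambda_i * n`,
#' `p(a) = p * a` (see the methods vignette for the rationale).
#'
#' @param three_species logical; include the algae component.
#' @param ... named overrides of any default.
#' @return A list of class `colony_params`.
#' @export
default_params <- function(three_species = FALSE, ...) {
  p <- list(
    dt = 0.001,
    D1_explore = 0.35, D1_build = 0.0125,
    D2 = 1e-4, C2 = 6,
    Dn = 0.25, Da = 0.25,
    beta1_explore = 0.7, beta1_build = 0.9, beta2 = 0.5,
    k_explore = 0, k_build = 1,
    lambda1 = 0.9, lambda2 = 0.9,
    n0 = 2, p = 0.6, a0 = 2,
    bbar_max = 0.033, bbar_min = 0.007,
    r0 = 0.15,                      # fraction of the domain size
    three_species = three_species,
    rX = 1, DX = 0.25, CX = 10, betaX = 0.25, muX = 0.1, lambdaX = 0.9,
    algae_diffusion_literal = FALSE)
  if (three_species) {
    p$n0 <- 0.5; p$bbar_max <- 0.04; p$bbar_min <- 0.02
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  class(p) <- "colony_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- p[!vapply(p, is.logical, TRUE)]
  if (any(unlist(num) < 0)) stop("all parameters must be non-negative")
  if (p$bbar_min >= p$bbar_max) stop("bbar_min must be smaller than bbar_max")
  if (p$D2 > 0.1 * min(p$D1_explore, p$C2))
    warning("expected D2 << D1 and D2 << C2; E. coli self-motility should be ",
            "negligible against transport by P. vortex")
  invisible(p)
}

#' Mortality rate of P. vortex
#'
#' `mu1(n, a) = 0.3 * a / (1 + 4n)`: death by ampicillin, attenuated where
#' nutrients keep the cells in good condition; zero without antibiotic.
#'
#' @param n nutrient concentration(s).
#' @param a antibiotic concentration(s).
#' @export
mortality_pvortex <- function(n, a) 0.3 * a / (1 + 4 * n)

#' Mortality rate of E. coli
#'
#' `mu2(n) = 1 / (1 + 4n)`: starvation-driven, decreasing in the nutrient
#' level, independent of the antibiotic (the strain is resistant).
#'
#' @param n nutrient concentration(s).
#' @export
mortality_ecoli <- function(n) 1 / (1 + 4 * n)

#' Linear rate law
#'
#' Reproduction, nutrient-consumption and antibiotic-degradation rates are
#' proportional to their driving concentration: `rate = coefficient * x`.
#'
#' @param x nutrient (or antibiotic) concentration(s).
#' @param coefficient slope, e.g. `beta1`, `lambda2` or `p`.
#' @export
linear_rate <- function(x, coefficient) coefficient * x

#' Builder/explorer phase coefficients
#'
#' The global phase switch swaps the motility exponent `k`, the diffusion
#' coefficient `D1` and the reproduction slope `beta1` of P. vortex jointly.
#'
#' @param params a [default_params()] list.
#' @param phase `"builder"` or `"explorer"`.
#' @return list with `D1`, `beta1`, `k`.
#' @export
phase_coeffs <- function(params, phase) {
  phase <- match.arg(phase, c("builder", "explorer"))
  if (phase == "builder")
    list(D1 = params$D1_build, beta1 = params$beta1_build, k = params$k_build)
  else
    list(D1 = params$D1_explore, beta1 = params$beta1_explore,
         k = params$k_explore)
}

#' Phase-switch configuration
#'
#' The colony-wide builder/explorer transition is hysteretic: builders turn
#' explorers when the mean colony density exceeds `bbar_max`; explorers turn
#' builders when it falls below `bbar_min`.  The mean is taken over the
#' colony support `{b1 > support_threshold}` (rule `"b1_only"`) or over
#' `{b1 + b2 > support_threshold}` of the summed density (rule
#' `"b1_plus_b2"`, default thresholds 0.029/0.066).
#'
#' @param support_threshold density defining the colony support.
#' @param rule `"b1_only"` or `"b1_plus_b2"`.
#' @param bbar_min,bbar_max hysteresis thresholds; defaults depend on the
#'   rule (0.007/0.033 and 0.029/0.066 respectively).
#' @export
phase_config <- function(support_threshold = 1e-6,
                         rule = c("b1_only", "b1_plus_b2"),
                         bbar_min = NULL, bbar_max = NULL) {
  rule <- match.arg(rule)
  if (is.null(bbar_min)) bbar_min <- if (rule == "b1_only") 0.007 else 0.029
  if (is.null(bbar_max)) bbar_max <- if (rule == "b1_only") 0.033 else 0.066
  stopifnot(support_threshold > 0, bbar_min > 0)
  if (bbar_min >= bbar_max) stop("bbar_min must be smaller than bbar_max")
  structure(list(support_threshold = support_threshold, rule = rule,
                 bbar_min = bbar_min, bbar_max = bbar_max),
            class = "phase_config")
}

#' Mean colony density
#'
#' Area-weighted mean of the selected density over the colony support,
#' `bbar = integral_B b dA / integral_B dA` with
#' `B = {b > support_threshold}`, using clipped Voronoi areas as `dA`.
#' Returns 0 (with attribute `empty_support`) when the support is empty.
#'
#' @param b1 P. vortex density (numeric vector).
#' @param b2 E. coli density; needed for the `b1_plus_b2` rule.
#' @param cfg a [phase_config()].
#' @param mesh the mesh carrying cell areas.
#' @export
mean_colony_density <- function(b1, b2 = NULL, cfg, mesh) {
  b <- if (cfg$rule == "b1_plus_b2") {
    if (is.null(b2)) stop("rule 'b1_plus_b2' needs b2")
    b1 + b2
  } else b1
  sup <- b > cfg$support_threshold
  if (!any(sup)) return(structure(0, empty_support = TRUE))
  sum(mesh$A[sup] * b[sup]) / sum(mesh$A[sup])
}

#' Hysteresis phase update
#'
#' @param bbar current mean colony density.
#' @param phase current phase, `"builder"` or `"explorer"`.
#' @param cfg a [phase_config()].
#' @return The new phase.
#' @export
phase_update <- function(bbar, phase, cfg) {
  if (phase == "builder" && bbar > cfg$bbar_max) "explorer"
  else if (phase == "explorer" && bbar < cfg$bbar_min) "builder"
  else phase
}

#' Accumulate dead bacterial mass
#'
#' Integrates `ds/dt = mu * b` explicitly with `mu` evaluated at the start
#' of the step; `s + b` is the accumulated (live plus dead) density whose
#' spatial pattern shows the rings.
#'
#' @param s current dead-mass field.
#' @param b live density field.
#' @param mu_value mortality rate field (same length, or scalar).
#' @param dt time step.
#' @export
accumulate_dead <- function(s, b, mu_value, dt) s + dt * mu_value * b

#' Model state
#'
#' The tuple of fields advanced by the integrator, plus the global phase and
#' simulation time.  All bacteria start as builders.
#'
#' @param mesh a complete `vrl_mesh`.
#' @param b1 P. vortex density.
#' @param b2 E. coli density, or `NULL` for the single-species model.
#' @param n,a nutrient and antibiotic fields; default uniform `n0`, `a0`.
#' @param X algae density for the three-species model, or `NULL`.
#' @param params a [default_params()] list.
#' @param phase_cfg a [phase_config()]; defaults to the `b1_only` rule with
#'   the thresholds in `params`.
#' @param phase initial phase.
#' @param t initial time.
#' @export
model_state <- function(mesh, b1, b2 = NULL, n = NULL, a = NULL, X = NULL,
                        params = default_params(),
                        phase_cfg = NULL, phase = "builder", t = 0) {
  nn <- nrow(mesh$nodes)
  as_f <- function(v, def) {
    if (is.null(v)) v <- def
    v <- as.numeric(v)
    if (length(v) == 1) v <- rep(v, nn)
    stopifnot(length(v) == nn, all(is.finite(v)))
    v
  }
  if (is.null(phase_cfg))
    phase_cfg <- phase_config(bbar_min = params$bbar_min,
                              bbar_max = params$bbar_max)
  b1 <- as_f(b1, 0)
  if (any(b1 < 0)) stop("densities must be non-negative")
  st <- list(mesh = mesh, b1 = b1,
             b2 = if (is.null(b2)) NULL else as_f(b2, 0),
             n = as_f(n, params$n0), a = as_f(a, params$a0),
             X = if (is.null(X)) NULL else as_f(X, 0),
             s1 = rep(0, nn), s2 = if (is.null(b2)) NULL else rep(0, nn),
             sX = if (is.null(X)) NULL else rep(0, nn),
             phase = match.arg(phase, c("builder", "explorer")), t = t,
             params = params, phase_cfg = phase_cfg,
             clipped = 0, switches = 0L)
  class(st) <- "model_state"
  st
}

#' @export
print.model_state <- function(x, ...) {
  sp <- if (!is.null(x$X)) 3 else if (!is.null(x$b2)) 2 else 1
  cat(sprintf("model state: %d species, t = %.4g, phase = %s\n",
              sp, x$t, x$phase))
  cat(sprintf("  total b1 mass %.6g", total_mass(x$b1, x$mesh)))
  if (!is.null(x$b2)) cat(sprintf(", b2 mass %.6g", total_mass(x$b2, x$mesh)))
  cat("\n")
  invisible(x)
}

#' Right-hand side of the single-species model
#'
#' `db/dt = div(D1 b^k grad b) + beta1(n) b - mu1(n, a) b`,
#' `dn/dt = Dn lap n - lambda1(n) b`, with phase-dependent `(D1, beta1, k)`.
#' Without antibiotic (`a = 0`) the death term vanishes; with `a` present
#' this is exactly the two-species system restricted to `b2 = 0`.
#'
#' @param state a [model_state()].
#' @param params a [default_params()] list.
#' @return list of derivative vectors `b1`, `n` (and `a` if present).
#' @export
rhs_single <- function(state, params = state$params) {
  mesh <- state$mesh
  pc <- phase_coeffs(params, state$phase)
  psi1 <- pc$D1 * if (pc$k == 0) rep(1, length(state$b1)) else
    state$b1^pc$k
  a <- if (is.null(state$a)) 0 else state$a
  list(
    b1 = nonlinear_divergence(state$b1, psi1, mesh) +
      (linear_rate(state$n, pc$beta1) - mortality_pvortex(state$n, a)) *
      state$b1,
    n = params$Dn * laplacian(state$n, mesh) -
      linear_rate(state$n, params$lambda1) * state$b1)
}

#' Right-hand side of the two-species model
#'
#' The coupled system for P. vortex (`b1`, nonlinear diffusion), E. coli
#' (`b2`, weak self-diffusion plus advection along `grad b1` with
#' coefficient `C2`), nutrient `n` and antibiotic `a` (degraded by E. coli
#' at rate `p(a) b2`).
#'
#' @inheritParams rhs_single
#' @return list of derivative vectors `b1`, `b2`, `n`, `a`.
#' @export
rhs_two_species <- function(state, params = state$params) {
  mesh <- state$mesh
  pc <- phase_coeffs(params, state$phase)
  b1 <- state$b1; b2 <- state$b2; n <- state$n; a <- state$a
  psi1 <- pc$D1 * if (pc$k == 0) rep(1, length(b1)) else b1^pc$k
  list(
    b1 = nonlinear_divergence(b1, psi1, mesh) +
      (linear_rate(n, pc$beta1) - mortality_pvortex(n, a)) * b1,
    b2 = params$D2 * laplacian(b2, mesh) +
      nonlinear_divergence(b1, params$C2 * b2, mesh) +
      (linear_rate(n, params$beta2) - mortality_ecoli(n)) * b2,
    n = params$Dn * laplacian(n, mesh) -
      linear_rate(n, params$lambda1) * b1 -
      linear_rate(n, params$lambda2) * b2,
    a = params$Da * laplacian(a, mesh) - linear_rate(a, params$p) * b2)
}

#' Right-hand side of the three-species model
#'
#' Adds a carbon-fixing alga `X`: reproduction of both bacteria is enhanced
#' by the factor `(1 + rX * X)`; the alga is advected with P. vortex
#' (`div(CX X grad b1)`), consumes nutrients (`lambdaX(n) X`) and dies at
#' the constant rate `muX`.  Both algal transport terms act on `X` itself
#' (`div(DX grad X)` and `div(CX X grad b1)`), which is what makes the
#' model reduce exactly to the two-species system at `X = 0`; set
#' `params$algae_diffusion_literal = TRUE` for the literal variant in
#' which both terms carry `b2` (see the methods vignette).
#'
#' @inheritParams rhs_single
#' @return list of derivative vectors `b1`, `b2`, `X`, `n`, `a`.
#' @export
rhs_three_species <- function(state, params = state$params) {
  mesh <- state$mesh
  pc <- phase_coeffs(params, state$phase)
  b1 <- state$b1; b2 <- state$b2; n <- state$n; a <- state$a
  X <- if (is.null(state$X)) rep(0, length(b1)) else state$X
  psi1 <- pc$D1 * if (pc$k == 0) rep(1, length(b1)) else b1^pc$k
  G <- 1 + params$rX * X
  carried <- if (isTRUE(params$algae_diffusion_literal)) b2 else X
  phiX <- carried
  list(
    b1 = nonlinear_divergence(b1, psi1, mesh) +
      (linear_rate(n, pc$beta1) * G - mortality_pvortex(n, a)) * b1,
    b2 = params$D2 * laplacian(b2, mesh) +
      nonlinear_divergence(b1, params$C2 * b2, mesh) +
      (linear_rate(n, params$beta2) * G - mortality_ecoli(n)) * b2,
    X = params$DX * laplacian(phiX, mesh) +
      nonlinear_divergence(b1, params$CX * carried, mesh) +
      (linear_rate(n, params$betaX) - params$muX) * X,
    n = params$Dn * laplacian(n, mesh) -
      linear_rate(n, params$lambda1) * b1 -
      linear_rate(n, params$lambda2) * b2 -
      linear_rate(n, params$lambdaX) * X,
    a = params$Da * laplacian(a, mesh) - linear_rate(a, params$p) * b2)
}
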