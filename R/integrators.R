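#' Integrator configuration
#'
#' @param dt time step in simulation time units (default 0.001).
#' @param scheme `"forward_euler"` (default) or `"crank_nicolson"`.
#'   Reactions and advection are integrated explicitly in both cases; the
#'   scheme applies to the diffusion terms.
#' @param gs_tol Gauss-Seidel stop tolerance on the successive-iterate
#'   max-norm (default 1e-9).
#' @param gs_max_iter iteration cap (default 500).
#' @export
integrator_config <- function(dt = 0.001,
                              scheme = c("forward_euler", "crank_nicolson"),
                              gs_tol = 1e-9, gs_max_iter = 500L) {
  scheme <- match.arg(scheme)
  stopifnot(dt >= 0, gs_tol > 0, gs_max_iter >= 1)
  structure(list(dt = dt, scheme = scheme, gs_tol = gs_tol,
                 gs_max_iter = as.integer(gs_max_iter)),
            class = "integrator_config")
}

#' Stable explicit time step for linear diffusion
#'
#' Gershgorin bound: the diffusion operator's spectrum lies in
#' `[-2 max_i Z_ii, 0]`, so forward Euler is stable for
#' `dt <= 1/(D * max_i Z_ii)` (which reduces to the classical
#' `h^2/(4 D)` on the regular lattice).  On a random lattice small Voronoi
#' cells push row sums well above `4/h^2`, hence the explicit bound.
#'
#' @param mesh a complete `vrl_mesh`.
#' @param D diffusion coefficient.
#' @param safety multiplicative safety factor (default 0.9).
#' @export
fe_stable_dt <- function(mesh, D, safety = 0.9) {
  safety / (D * max(mesh$z))
}

#' Forward-Euler diffusion step
#'
#' `phi^{n+1} = phi^n + dt * D * div(phi^k grad phi)` with the skew-symmetric
#' edge fluxes, so total mass is conserved exactly.  `phi^0 = 1` everywhere,
#' including at `phi = 0` (the explorer limit).
#'
#' @param phi field (numeric vector or [vrl_field()]).
#' @param k diffusion exponent (0 linear, 1 porous-medium type).
#' @param D diffusion coefficient.
#' @param dt time step; must respect the explicit stability limit.
#' @param mesh the mesh (optional when `phi` is a `vrl_field`).
#' @export
fe_diffusion_step <- function(phi, k, D, dt, mesh = NULL) {
  if (is.null(mesh)) mesh <- phi$mesh
  p <- field_values(phi, mesh)
  psi <- if (k == 0) rep(1, length(p)) else p^k
  out <- p + dt * D * nonlinear_divergence(p, psi, mesh)
  if (!all(is.finite(out)))
    stop("forward-Euler diffusion produced non-finite values: ",
         "dt = ", dt, " exceeds the stability limit on this mesh")
  out
}

#' Crank-Nicolson diffusion step
#'
#' Solves the implicit relation
#' `phi^{n+1} - phi^n = (D dt / 4) * sum_j w_ij [(phi_j^k + phi_i^k)(phi_j -
#' phi_i)]` averaged over the old and new time levels.  For `k = 0` this is
#' a sparse linear solve; for `k = 1` the nonlinear system is solved by the
#' Gauss-Seidel split iteration with initial guess `V^(0) = phi^n` (the
#' nonlinear diagonal coefficient frozen at the previous iterate, neighbor
#' values taken at their latest sweep values).
#'
#' @inheritParams fe_diffusion_step
#' @param cfg an [integrator_config()] supplying `gs_tol`/`gs_max_iter`.
#' @return list with `phi` (the new field) and `report`
#'   (`iterations`, `delta`, `converged`).
#' @export
cn_diffusion_step <- function(phi, k, D, dt, cfg = integrator_config(),
                              mesh = NULL) {
  if (is.null(mesh)) mesh <- phi$mesh
  p <- field_values(phi, mesh)
  if (!k %in% c(0, 1)) stop("Crank-Nicolson step supports k = 0 or 1")
  if (dt == 0)
    return(list(phi = p, report = list(iterations = 1L, delta = 0,
                                       converged = TRUE)))
  if (k == 0) {
    c0 <- D * dt / 2
    n <- length(p)
    L <- mesh$W - Matrix::Diagonal(x = mesh$z)    # W - Z
    rhs <- p + c0 * as.numeric(L %*% p)
    M <- Matrix::Diagonal(n) - c0 * L
    out <- as.numeric(Matrix::solve(M, rhs))
    return(list(phi = out, report = list(iterations = 1L, delta = 0,
                                         converged = TRUE)))
  }
  res <- gs_cn_k1_cpp(mesh$csr$ptr, mesh$csr$adj, mesh$csr$wadj, p,
                      D * dt / 4, cfg$gs_tol, cfg$gs_max_iter)
  if (!res$converged)
    stop(sprintf(paste0("Gauss-Seidel did not converge in %d iterations ",
                        "(last max-norm update %.3g); reduce dt or check ",
                        "the mesh"), cfg$gs_max_iter, res$delta))
  list(phi = res$phi,
       report = list(iterations = res$iterations, delta = res$delta,
                     converged = res$converged))
}

#' Advance the model state by one time step
#'
#' Reference (pure R) stepper: diffusion by the configured scheme, reaction
#' and advection terms explicit, dead-mass accumulators updated with
#' start-of-step mortality, then the global builder/explorer phase
#' re-evaluated from the new mean colony density.  Negative densities from
#' the explicit terms are clipped to zero and the clipped mass is logged in
#' `state$clipped`.
#'
#' @param state a [model_state()].
#' @param params parameter list; defaults to the state's own.
#' @param cfg an [integrator_config()].
#' @return The advanced `model_state`.
#' @export
step_model <- function(state, params = state$params,
                       cfg = integrator_config(dt = params$dt)) {
  mesh <- state$mesh
  dt <- cfg$dt
  # start-of-step quantities for the explicit dead-mass bookkeeping
  mu1 <- mortality_pvortex(state$n, state$a)
  mu2 <- if (!is.null(state$b2)) mortality_ecoli(state$n) else NULL
  b1_old <- state$b1; b2_old <- state$b2; X_old <- state$X

  if (cfg$scheme == "forward_euler") {
    d <- if (!is.null(state$X)) rhs_three_species(state, params)
         else if (!is.null(state$b2)) rhs_two_species(state, params)
         else rhs_single(state, params)
    new <- lapply(names(d), function(f) state[[f]] + dt * d[[f]])
    names(new) <- names(d)
  } else {
    pc <- phase_coeffs(params, state$phase)
    new <- list()
    # diffusion implicitly, everything else explicitly
    cn <- function(v, k, D) cn_diffusion_step(v, k, D, dt, cfg, mesh)$phi
    expl <- list(
      b1 = (linear_rate(state$n, pc$beta1) *
              (if (!is.null(state$X)) 1 + params$rX * state$X else 1) -
              mu1) * state$b1)
    new$b1 <- cn(state$b1, pc$k, pc$D1) + dt * expl$b1
    if (!is.null(state$b2)) {
      adv2 <- nonlinear_divergence(state$b1, params$C2 * state$b2, mesh)
      g2 <- (linear_rate(state$n, params$beta2) *
               (if (!is.null(state$X)) 1 + params$rX * state$X else 1) -
               mortality_ecoli(state$n)) * state$b2
      new$b2 <- cn(state$b2, 0, params$D2) + dt * (adv2 + g2)
    }
    if (!is.null(state$X)) {
      phiX <- if (isTRUE(params$algae_diffusion_literal)) state$b2 else state$X
      advX <- nonlinear_divergence(state$b1, params$CX * phiX, mesh)
      # diffusion of phiX: only implicit when it acts on X itself
      diffX <- if (isTRUE(params$algae_diffusion_literal))
        state$X + dt * params$DX * laplacian(phiX, mesh)
      else cn(state$X, 0, params$DX)
      new$X <- diffX + dt * (advX + (linear_rate(state$n, params$betaX) -
                                       params$muX) * state$X)
    }
    sink_n <- linear_rate(state$n, params$lambda1) * state$b1 +
      (if (!is.null(state$b2))
        linear_rate(state$n, params$lambda2) * state$b2 else 0) +
      (if (!is.null(state$X))
        linear_rate(state$n, params$lambdaX) * state$X else 0)
    new$n <- cn(state$n, 0, params$Dn) - dt * sink_n
    if (!is.null(state$a))
      new$a <- cn(state$a, 0, params$Da) -
        dt * (if (!is.null(state$b2))
          linear_rate(state$a, params$p) * state$b2 else 0)
  }

  for (f in names(new)) {
    v <- new[[f]]
    neg <- v < 0
    if (any(neg)) {
      state$clipped <- state$clipped - sum(mesh$A[neg] * v[neg])
      v[neg] <- 0
    }
    state[[f]] <- v
  }

  # dead mass, with start-of-step mortality and density (explicit convention)
  state$s1 <- accumulate_dead(state$s1, b1_old, mu1, dt)
  if (!is.null(b2_old))
    state$s2 <- accumulate_dead(state$s2, b2_old, mu2, dt)
  if (!is.null(X_old))
    state$sX <- accumulate_dead(state$sX, X_old, params$muX, dt)

  state$t <- state$t + dt
  bbar <- mean_colony_density(state$b1, state$b2, state$phase_cfg, mesh)
  newphase <- phase_update(bbar, state$phase, state$phase_cfg)
  if (newphase != state$phase) state$switches <- state$switches + 1L
  state$phase <- newphase
  state$bbar <- as.numeric(bbar)
  state
}
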