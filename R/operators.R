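#' Scalar field on a VRL
#'
#' One real value per mesh node (bacterial density as area fraction,
#' nutrient, antibiotic...).
#'
#' @param values numeric vector, one finite value per node.
#' @param mesh a complete `vrl_mesh`.
#' @param name optional label.
#' @export
vrl_field <- function(values, mesh, name = "") {
  stopifnot(inherits(mesh, "vrl_mesh"), isTRUE(mesh$geometry))
  values <- as.numeric(values)
  if (length(values) == 1) values <- rep(values, nrow(mesh$nodes))
  if (length(values) != nrow(mesh$nodes))
    stop("field length does not match node count")
  if (!all(is.finite(values))) stop("field contains non-finite values")
  structure(list(values = values, mesh = mesh, name = name),
            class = "vrl_field")
}

field_values <- function(phi, mesh) {
  if (inherits(phi, "vrl_field")) {
    if (!identical(dim(phi$mesh$nodes), dim(mesh$nodes)) ||
        !identical(phi$mesh$edges$f, mesh$edges$f))
      stop("field defined on a different mesh")
    phi$values
  } else {
    v <- as.numeric(phi)
    if (length(v) == 1) v <- rep(v, nrow(mesh$nodes))
    if (length(v) != nrow(mesh$nodes)) stop("field length mismatch")
    v
  }
}

#' Discrete nonlinear divergence on a VRL
#'
#' Finite-volume approximation of `div(psi * grad phi)` at node `v_i`:
#' \deqn{\tfrac12 \sum_{j \in \mu_i} w_{ij} (\psi_j + \psi_i)(\phi_j - \phi_i)}
#' with `w_ij = f_ij/(l_ij A_i)` and `mu_i` the natural neighbors of `v_i`.
#' Boundary faces contribute nothing, which is the no-flux condition.
#'
#' @param phi,psi fields ([vrl_field()] or numeric vectors/scalars).
#' @param mesh the mesh (may be omitted when `phi` is a `vrl_field`).
#' @return Numeric vector of per-node divergence values.
#' @export
nonlinear_divergence <- function(phi, psi, mesh = NULL) {
  if (is.null(mesh)) mesh <- phi$mesh
  p <- field_values(phi, mesh); s <- field_values(psi, mesh)
  W <- mesh$W
  as.numeric(0.5 * (W %*% (s * p) + s * (W %*% p) - p * (W %*% s)
                    - s * p * mesh$z))
}

#' Discrete Laplacian on a VRL
#'
#' `laplacian(phi)` equals [nonlinear_divergence()] with `psi = 1`:
#' `sum_j w_ij (phi_j - phi_i)`.  Exact (to rounding) for linear fields at
#' interior nodes, by the perpendicular-bisector property of Voronoi faces.
#'
#' @inheritParams nonlinear_divergence
#' @export
laplacian <- function(phi, mesh = NULL) {
  if (is.null(mesh)) mesh <- phi$mesh
  p <- field_values(phi, mesh)
  as.numeric(W_apply(mesh, p) - p * mesh$z)
}

W_apply <- function(mesh, v) as.numeric(mesh$W %*% v)

#' Forward-Euler edge fluxes
#'
#' Per-directed-edge flux `J_ij = 0.5 * w_ij * (psi_i + psi_j) * (phi_j -
#' phi_i)`, the amount entering cell `i` from neighbor `j` per unit area of
#' cell `i`.  The area-weighted flux is skew-symmetric,
#' `A_i J_ij = -A_j J_ji`, so summing incoming fluxes per node reproduces
#' [nonlinear_divergence()] and total mass is conserved.
#'
#' @inheritParams nonlinear_divergence
#' @return A data frame with columns `i`, `j`, `J` covering both directions
#'   of every edge.
#' @export
edge_fluxes_fe <- function(phi, psi, mesh = NULL) {
  if (is.null(mesh)) mesh <- phi$mesh
  p <- field_values(phi, mesh); s <- field_values(psi, mesh)
  ed <- mesh$edges
  g <- 0.5 * (s[ed$i] + s[ed$j]) * (p[ed$j] - p[ed$i])
  data.frame(i = c(ed$i, ed$j), j = c(ed$j, ed$i),
             J = c(mesh$wij * g, -mesh$wji * g))
}

#' Total mass of a field
#'
#' `sum_i A_i phi_i`, the discrete integral over the domain using clipped
#' Voronoi cell areas.
#'
#' @inheritParams nonlinear_divergence
#' @export
total_mass <- function(phi, mesh = NULL) {
  if (is.null(mesh)) mesh <- phi$mesh
  sum(mesh$A * field_values(phi, mesh))
}

#' Sparse system matrices of the diffusion operator
#'
#' The weighted adjacency `W` (`W_ij = w_ij` for natural neighbors, zero
#' diagonal) and the diagonal row-sum matrix `Z` with
#' `Z_ii = sum_j w_ij`, as used by the Crank-Nicolson matrix form.
#'
#' @param mesh a complete `vrl_mesh`.
#' @return list with sparse matrices `W` and `Z`.
#' @export
system_matrices <- function(mesh) {
  stopifnot(inherits(mesh, "vrl_mesh"), isTRUE(mesh$geometry))
  list(W = mesh$W, Z = Matrix::Diagonal(x = mesh$z))
}
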