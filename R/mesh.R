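#' Specification of a Vectorizable Random Lattice
#'
#' A VRL places exactly one node, uniformly at random, in every cell of an
#' `nx` by `ny` rectangular reference lattice with spacing `h`, subject to a
#' per-axis minimum-distance constraint: nodes in cells that are face-adjacent
#' along axis `i` must be at Euclidean distance at least `d_i`.  `d_i = 0`
#' gives maximal randomness; `d_i = h` approaches the rectangular limit (use
#' [regular_mesh()] for the exact limit).
#'
#' @param nx,ny integer cell counts of the reference lattice (`nx*ny >= 9`).
#' @param h reference cell spacing; the domain is `[0, nx*h] x [0, ny*h]`.
#'   Default 1, i.e. lengths are measured in lattice units.
#' @param d_x,d_y minimum-distance parameters, each in `[0, h]`.  Default
#'   `0.5*h`, which retains randomness while keeping redraw counts small.
#' @param seed integer RNG seed; identical specs give bit-identical meshes.
#' @return An object of class `mesh_spec`.
#' @seealso [vrl_mesh()], [draw_nodes()]
#' @export
mesh_spec <- function(nx, ny, h = 1, d_x = 0.5 * h, d_y = 0.5 * h, seed = 1L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(is.finite(nx), is.finite(ny), nx >= 3, ny >= 3, nx * ny >= 9,
            is.finite(h), h > 0, is.finite(seed))
  if (d_x < 0 || d_x > h || d_y < 0 || d_y > h)
    stop("minimum distances d_x, d_y must lie in [0, h]")
  structure(list(nx = nx, ny = ny, h = h, d_x = d_x, d_y = d_y,
                 seed = as.integer(seed)),
            class = "mesh_spec")
}

#' @export
print.mesh_spec <- function(x, ...) {
  cat(sprintf("VRL mesh spec: %d x %d cells, h = %g, d = (%g, %g), seed %d\n",
              x$nx, x$ny, x$h, x$d_x, x$d_y, x$seed))
  invisible(x)
}

# run code with a private, seed-determined RNG stream, restoring caller state
with_mesh_rng <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw the random nodes of a VRL
#'
#' One node is drawn uniformly in each reference cell.  Sweeps over all
#' face-adjacent cell pairs then redraw *both* nodes of every pair violating
#' the axis minimum distance, until a full sweep is clean.
#'
#' @param spec a [mesh_spec()].
#' @param max_sweeps guard against non-termination (only reachable as
#'   `d_i` approaches `h`); default `1e5`.
#' @return An `n x 2` matrix of node coordinates (row-major cell order,
#'   node id `= (j-1)*nx + i` for cell `(i, j)`), with the spec, cell
#'   indices and redraw-sweep count attached as attributes.
#' @export
draw_nodes <- function(spec, max_sweeps = 1e5) {
  stopifnot(inherits(spec, "mesh_spec"))
  nx <- spec$nx; ny <- spec$ny; h <- spec$h
  n <- nx * ny
  ci <- rep(seq_len(nx), times = ny)
  cj <- rep(seq_len(ny), each = nx)
  # horizontal pairs: (i,j)-(i+1,j); vertical: (i,j)-(i,j+1)
  hp1 <- which(ci < nx); hp2 <- hp1 + 1L
  vp1 <- which(cj < ny); vp2 <- vp1 + nx

  sweeps <- 0L
  with_mesh_rng(spec$seed, {
    x <- (ci - 1) * h + stats::runif(n) * h
    y <- (cj - 1) * h + stats::runif(n) * h
    repeat {
      bad <- logical(n)
      if (spec$d_x > 0) {
        v <- (x[hp2] - x[hp1])^2 + (y[hp2] - y[hp1])^2 < spec$d_x^2
        bad[hp1[v]] <- TRUE; bad[hp2[v]] <- TRUE
      }
      if (spec$d_y > 0) {
        v <- (x[vp2] - x[vp1])^2 + (y[vp2] - y[vp1])^2 < spec$d_y^2
        bad[vp1[v]] <- TRUE; bad[vp2[v]] <- TRUE
      }
      if (!any(bad)) break
      sweeps <- sweeps + 1L
      if (sweeps > max_sweeps)
        stop("node redraw did not terminate after ", max_sweeps,
             " sweeps; d_x/d_y too close to h for this lattice")
      k <- sum(bad)
      x[bad] <- (ci[bad] - 1) * h + stats::runif(k) * h
      y[bad] <- (cj[bad] - 1) * h + stats::runif(k) * h
    }
    nodes <- cbind(x = x, y = y)
    attr(nodes, "spec") <- spec
    attr(nodes, "cell") <- cbind(i = ci, j = cj)
    attr(nodes, "sweeps") <- sweeps
    nodes
  })
}

# shared Rcpp-backed cell/face computation; rect = c(x0, y0, x1, y1)
vrl_cells <- function(nodes, rect, structured = TRUE) {
  spec <- attr(nodes, "spec"); cell <- attr(nodes, "cell")
  if (structured && !is.null(spec) && !is.null(cell)) {
    vrl_geometry_cpp(unname(nodes), as.integer(cell[, 1]),
                     as.integer(cell[, 2]), spec$nx, spec$ny,
                     as.numeric(rect), spec$h, 4L,
                     1e-12 * spec$h)
  } else {
    scale <- max(diff(range(nodes[, 1])), diff(range(nodes[, 2])), 1)
    vrl_geometry_cpp(unname(nodes), integer(0), integer(0), 0L, 0L,
                     as.numeric(rect), 0, 0L, 1e-12 * scale)
  }
}

#' Build the natural-neighbor (Delaunay) adjacency of a node set
#'
#' Natural neighbors are nodes whose Voronoi cells share a face; linking all
#' such pairs yields the Delaunay triangulation, i.e. the VRL graph.  The
#' diagram is computed in a clipping box 10 bounding-box sizes wide so that
#' the edge set equals the Delaunay edge set of the nodes (validated against
#' a brute-force empty-circumcircle oracle in the test suite).
#'
#' @param nodes an `n x 2` coordinate matrix, e.g. from [draw_nodes()].
#' @return An adjacency-only `vrl_mesh` (no areas/weights); pass it to
#'   [compute_geometry()] to obtain the finite-volume quantities.
#' @export
build_vrl <- function(nodes) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 2, nrow(nodes) >= 3)
  rx <- range(nodes[, 1]); ry <- range(nodes[, 2])
  pad <- 10 * max(diff(rx), diff(ry), 1)
  g <- vrl_cells(nodes, c(rx[1] - pad, ry[1] - pad, rx[2] + pad, ry[2] + pad),
                 structured = FALSE)
  structure(list(nodes = nodes, spec = attr(nodes, "spec"),
                 cell = attr(nodes, "cell"),
                 edges = data.frame(i = g$i, j = g$j, l = g$l),
                 geometry = FALSE),
            class = "vrl_mesh")
}

#' Finite-volume geometry of a VRL
#'
#' Clips every Voronoi cell to the domain rectangle and computes the
#' quantities of the finite-volume scheme: cell areas `A_i`, shared face
#' lengths `f_ij`, node distances `l_ij` and the directed weights
#' `w_ij = f_ij / (l_ij * A_i)`.  Edges whose shared face is clipped away
#' entirely are removed.  Boundary faces (cell edges on the rectangle) carry
#' zero flux, which implements the no-flux boundary condition.
#'
#' @param x a node matrix from [draw_nodes()], or a `vrl_mesh` from
#'   [build_vrl()].
#' @param domain domain size `c(Lx, Ly)` (rectangle `[0,Lx] x [0,Ly]`);
#'   defaults to `c(nx*h, ny*h)` when the node set carries its spec.
#' @return A complete `vrl_mesh`: nodes, cell indices, edge table
#'   `(i, j, f, l)`, areas `A`, `boundary` flags, directed weights
#'   `wij`/`wji`, the sparse weighted adjacency `W` and its row sums `z`.
#' @export
compute_geometry <- function(x, domain = NULL) {
  if (inherits(x, "vrl_mesh")) {
    nodes <- x$nodes
    attr(nodes, "spec") <- x$spec; attr(nodes, "cell") <- x$cell
  } else nodes <- x
  spec <- attr(nodes, "spec")
  if (is.null(domain)) {
    if (is.null(spec)) stop("domain must be given for unstructured node sets")
    domain <- c(spec$nx * spec$h, spec$ny * spec$h)
  }
  g <- vrl_cells(nodes, c(0, 0, domain[1], domain[2]),
                 structured = !is.null(spec))
  n <- nrow(nodes)
  A <- g$A
  if (any(A <= 0)) stop("zero-area Voronoi cell: invalid node configuration")
  edges <- data.frame(i = g$i, j = g$j, f = g$f, l = g$l)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  wij <- edges$f / (edges$l * A[edges$i])
  wji <- edges$f / (edges$l * A[edges$j])
  W <- Matrix::sparseMatrix(i = c(edges$i, edges$j), j = c(edges$j, edges$i),
                            x = c(wij, wji), dims = c(n, n))
  mesh <- structure(list(
    nodes = nodes, spec = spec, cell = attr(nodes, "cell"),
    domain = as.numeric(domain), h = if (is.null(spec)) NA_real_ else spec$h,
    edges = edges, A = A, boundary = as.logical(g$boundary),
    wij = wij, wji = wji, W = W, z = as.numeric(Matrix::rowSums(W)),
    max_face_asymmetry = g$max_face_asymmetry, geometry = TRUE),
    class = "vrl_mesh")
  mesh$csr <- build_csr(mesh)
  mesh
}

# compressed row adjacency (0-based) for the Gauss-Seidel kernel
build_csr <- function(mesh) {
  n <- nrow(mesh$nodes)
  src <- c(mesh$edges$i, mesh$edges$j)
  dst <- c(mesh$edges$j, mesh$edges$i)
  w <- c(mesh$wij, mesh$wji)
  ord <- order(src)
  list(ptr = c(0L, cumsum(tabulate(src, n))),
       adj = as.integer(dst[ord] - 1L), wadj = w[ord])
}

#' Construct a complete VRL in one call
#'
#' Convenience pipeline [draw_nodes()] then [compute_geometry()] (the
#' natural-neighbor adjacency falls out of the clipped Voronoi diagram, so
#' the intermediate [build_vrl()] pass is not needed).
#'
#' @inheritParams draw_nodes
#' @return A complete `vrl_mesh`.
#' @export
vrl_mesh <- function(spec, max_sweeps = 1e5) {
  compute_geometry(draw_nodes(spec, max_sweeps = max_sweeps))
}

#' Exact rectangular-limit mesh
#'
#' Places every node at its cell center, the `d_i = h` limit of the VRL.
#' The geometry is exact: interior nodes have 4 neighbors with `f = l = h`,
#' `A = h^2` and `w = 1/h^2`, the classical 5-point stencil.
#'
#' @inheritParams mesh_spec
#' @return A complete `vrl_mesh`.
#' @export
regular_mesh <- function(nx, ny, h = 1) {
  spec <- mesh_spec(nx, ny, h, d_x = h, d_y = h, seed = 0L)
  ci <- rep(seq_len(nx), times = ny)
  cj <- rep(seq_len(ny), each = nx)
  nodes <- cbind(x = (ci - 0.5) * h, y = (cj - 0.5) * h)
  attr(nodes, "spec") <- spec
  attr(nodes, "cell") <- cbind(i = ci, j = cj)
  compute_geometry(nodes)
}

#' @export
print.vrl_mesh <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("VRL mesh: %d nodes, %d edges%s\n", n, nrow(x$edges),
              if (isTRUE(x$geometry)) "" else " (adjacency only)"))
  if (isTRUE(x$geometry)) {
    cat(sprintf("  domain [0, %g] x [0, %g], %d boundary nodes\n",
                x$domain[1], x$domain[2], sum(x$boundary)))
    cat(sprintf("  total area %.10g (domain area %.10g)\n",
                sum(x$A), prod(x$domain)))
  }
  invisible(x)
}

#' Neighbor statistics of a VRL
#'
#' Summaries restricted to interior nodes (cells not touching the domain
#' boundary, to avoid clipping bias): mean natural-neighbor count, the
#' fraction of nodes with at least one neighbor farther than `c*h`, and the
#' bond probability by reference-cell offset shell
#' (shell 1: offsets (+-1,0),(0,+-1); shell 2: (+-1,+-1);
#' shell 3: (+-2,0),(0,+-2)).  The bond probability of a shell is the number
#' of realized bonds at its offsets divided by `4 * n_interior`, the number
#' of candidate pairs.
#'
#' @param mesh a complete `vrl_mesh` with cell indices.
#' @param c distance multiplier for the long-neighbor fraction (default 4).
#' @return A list with `n_interior`, `mean_neighbors`, `frac_beyond`,
#'   `c`, `shell_prob` (length 3) and `offset_counts` (all observed
#'   absolute offsets with bond counts, for inspecting farther shells).
#' @export
neighbor_statistics <- function(mesh, c = 4) {
  stopifnot(inherits(mesh, "vrl_mesh"), isTRUE(mesh$geometry))
  if (is.null(mesh$cell)) stop("mesh has no reference-cell indices")
  interior <- !mesh$boundary
  n_int <- sum(interior)
  if (n_int < 100)
    warning("fewer than 100 interior nodes; statistics are unreliable")
  ed <- mesh$edges
  deg <- tabulate(c(ed$i, ed$j), nrow(mesh$nodes))
  long <- ed$l > c * mesh$h
  has_long <- tabulate(c(ed$i[long], ed$j[long]), nrow(mesh$nodes)) > 0

  # directed bonds emanating from interior nodes, by absolute cell offset
  src <- c(ed$i, ed$j); dst <- c(ed$j, ed$i)
  keep <- interior[src]
  di <- abs(mesh$cell[src[keep], 1] - mesh$cell[dst[keep], 1])
  dj <- abs(mesh$cell[src[keep], 2] - mesh$cell[dst[keep], 2])
  shell <- integer(length(di))
  shell[(di + dj) == 1] <- 1L
  shell[di == 1 & dj == 1] <- 2L
  shell[(di == 2 & dj == 0) | (di == 0 & dj == 2)] <- 3L
  shell_prob <- as.numeric(tabulate(shell, 3L)) / (4 * n_int)
  oc <- as.data.frame(table(di = di, dj = dj), stringsAsFactors = FALSE)
  oc <- oc[oc$Freq > 0, ]
  oc$di <- as.integer(oc$di); oc$dj <- as.integer(oc$dj)

  list(n_interior = n_int,
       mean_neighbors = mean(deg[interior]),
       frac_beyond = mean(has_long[interior]),
       c = c,
       shell_prob = shell_prob,
       offset_counts = oc[order(oc$di, oc$dj), ])
}

#' Write a mesh as plain-text node and edge tables
#'
#' @param mesh a complete `vrl_mesh`.
#' @param node_path,edge_path output CSV paths.
#' @export
write_mesh_csv <- function(mesh, node_path, edge_path) {
  stopifnot(inherits(mesh, "vrl_mesh"), isTRUE(mesh$geometry))
  nd <- data.frame(id = seq_len(nrow(mesh$nodes)),
                   cell_i = if (is.null(mesh$cell)) NA else mesh$cell[, 1],
                   cell_j = if (is.null(mesh$cell)) NA else mesh$cell[, 2],
                   x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                   A = mesh$A, boundary = mesh$boundary)
  utils::write.csv(nd, node_path, row.names = FALSE)
  utils::write.csv(mesh$edges, edge_path, row.names = FALSE)
  invisible(c(node_path, edge_path))
}
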