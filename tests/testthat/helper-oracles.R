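# Independent oracles used to validate the implementation.  They share no
# code with the package internals: brute-force enumeration for the Delaunay
# property, a from-scratch all-pairs polygon clipper for the Voronoi
# geometry, classical RK4 for reaction ODEs, and closed forms.

# circumcircle of three points: list(cx, cy, r2) or NULL if collinear
oracle_circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14 * max(abs(c(ax, ay, bx, by, cx, cy)), 1)^2) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(cx = ux, cy = uy, r2 = (ax - ux)^2 + (ay - uy)^2)
}

# brute-force Delaunay edge set: every triple whose circumcircle is empty of
# all other nodes contributes its three edges
oracle_delaunay_edges <- function(nodes) {
  n <- nrow(nodes)
  edges <- list()
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    cc <- oracle_circumcircle(nodes[i, ], nodes[j, ], nodes[k, ])
    if (is.null(cc)) next
    d2 <- (nodes[, 1] - cc$cx)^2 + (nodes[, 2] - cc$cy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all(d2[others] > cc$r2 * (1 - 1e-10)))
      edges[[length(edges) + 1]] <- rbind(c(i, j), c(i, k), c(j, k))
  }
  e <- unique(do.call(rbind, edges))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# from-scratch Voronoi cell of node i clipped to rect = c(x0,y0,x1,y1),
# using ALL other nodes (no windowing).  Returns area, per-neighbor shared
# face lengths and whether the cell touches the rectangle.
oracle_voronoi_cell <- function(nodes, i, rect) {
  px <- c(rect[1], rect[3], rect[3], rect[1])
  py <- c(rect[2], rect[2], rect[4], rect[4])
  own <- rep(0L, 4)                      # 0 = rectangle edge
  xi <- nodes[i, 1]; yi <- nodes[i, 2]
  for (j in seq_len(nrow(nodes))) {
    if (j == i) next
    dx <- nodes[j, 1] - xi; dy <- nodes[j, 2] - yi
    mx <- (nodes[j, 1] + xi) / 2; my <- (nodes[j, 2] + yi) / 2
    g <- (px - mx) * dx + (py - my) * dy
    m <- length(px)
    nx2 <- c(); ny2 <- c(); no2 <- c()
    for (t in seq_len(m)) {
      u <- if (t == m) 1L else t + 1L
      if (g[t] <= 0) {
        nx2 <- c(nx2, px[t]); ny2 <- c(ny2, py[t]); no2 <- c(no2, own[t])
        if (g[u] > 0) {
          s <- g[t] / (g[t] - g[u])
          nx2 <- c(nx2, px[t] + s * (px[u] - px[t]))
          ny2 <- c(ny2, py[t] + s * (py[u] - py[t]))
          no2 <- c(no2, j)
        }
      } else if (g[u] <= 0) {
        s <- g[t] / (g[t] - g[u])
        nx2 <- c(nx2, px[t] + s * (px[u] - px[t]))
        ny2 <- c(ny2, py[t] + s * (py[u] - py[t]))
        no2 <- c(no2, own[t])
      }
    }
    px <- nx2; py <- ny2; own <- no2
    if (length(px) < 3) return(list(area = 0, faces = numeric(0),
                                    boundary = FALSE))
  }
  m <- length(px)
  u <- c(seq(2, m), 1)
  area <- abs(sum(px * py[u] - px[u] * py)) / 2
  seglen <- sqrt((px[u] - px)^2 + (py[u] - py)^2)
  faces <- tapply(seglen, own, sum)
  list(area = area,
       faces = faces[names(faces) != "0"],
       boundary = any(own == 0 & seglen > 1e-12))
}

# face-integral finite-volume operator evaluated directly from the oracle
# geometry: (1/A_i) sum_j (f_ij / l_ij) * 0.5*(psi_i+psi_j) * (phi_j - phi_i)
oracle_face_integral <- function(nodes, rect, phi, psi = rep(1, nrow(nodes))) {
  n <- nrow(nodes)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cell <- oracle_voronoi_cell(nodes, i, rect)
    js <- as.integer(names(cell$faces))
    if (!length(js)) next
    l <- sqrt((nodes[js, 1] - nodes[i, 1])^2 + (nodes[js, 2] - nodes[i, 2])^2)
    out[i] <- sum(cell$faces / l * 0.5 * (psi[js] + psi[i]) *
                    (phi[js] - phi[i])) / cell$area
  }
  out
}

# classical RK4 on a first-order system dy/dt = f(t, y)
oracle_rk4 <- function(f, y0, t_end, nstep) {
  y <- y0; t <- 0; dt <- t_end / nstep
  for (s in seq_len(nstep)) {
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  y
}

# dense Newton solve of the k = 1 Crank-Nicolson relation
oracle_cn_newton <- function(mesh, phi0, D, dt, tol = 1e-14) {
  cc <- D * dt / 4
  W <- as.matrix(mesh$W); z <- mesh$z
  rhs <- phi0 + cc * (as.numeric(W %*% (phi0^2)) - z * phi0^2)
  p <- phi0
  for (it in 1:100) {
    Fv <- p + cc * z * p^2 - cc * as.numeric(W %*% (p^2)) - rhs
    J <- diag(1 + 2 * cc * z * p) - 2 * cc * W %*% diag(p)
    dp <- solve(J, Fv)
    p <- p - dp
    if (max(abs(dp)) < tol) break
  }
  p
}

# free-space heat kernel evolution of a centered Gaussian exp(-r^2/(2 s0^2))
oracle_heat_gaussian <- function(r2, s0, D, t) {
  s2 <- s0^2 + 2 * D * t
  (s0^2 / s2) * exp(-r2 / (2 * s2))
}
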