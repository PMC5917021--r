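# Independent dense finite-element oracle for small meshes.
# Deliberately coded from scratch (own shape-function derivatives, 3x3 Gauss
# rule, dense assembly, base::solve) so it shares no code path with the
# package's sparse solver.

fe_oracle_solve <- function(mesh, E, eps_app = 0.05, nu = 0.3) {
  nodes <- mesh$nodes
  elems <- mesh$elements
  nn <- nrow(nodes)
  K <- matrix(0, 2 * nn, 2 * nn)

  # 3x3 Gauss rule
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)

  shape_deriv <- function(xi, eta) {
    # corners in the element's node order: (-1,-1), (1,-1), (1,1), (-1,1)
    xs <- c(-1, 1, 1, -1); es <- c(-1, -1, 1, 1)
    cbind(d_xi = xs * (1 + es * eta) / 4, d_eta = es * (1 + xs * xi) / 4)
  }

  Dm <- function(E) E / (1 - nu^2) *
    matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)

  strain_B <- function(xy, xi, eta) {
    dN <- shape_deriv(xi, eta)
    J <- t(dN) %*% xy
    dNxy <- dN %*% solve(J)
    B <- matrix(0, 3, 8)
    for (a in 1:4) {
      B[1, 2 * a - 1] <- dNxy[a, 1]
      B[2, 2 * a]     <- dNxy[a, 2]
      B[3, 2 * a - 1] <- dNxy[a, 2]
      B[3, 2 * a]     <- dNxy[a, 1]
    }
    list(B = B, detJ = det(J))
  }

  for (e in seq_len(nrow(elems))) {
    en <- elems[e, ]
    xy <- nodes[en, , drop = FALSE]
    ke <- matrix(0, 8, 8)
    for (i in 1:3) for (j in 1:3) {
      sb <- strain_B(xy, gp[i], gp[j])
      ke <- ke + gw[i] * gw[j] * t(sb$B) %*% Dm(E[e]) %*% sb$B * sb$detJ
    }
    dofs <- as.vector(rbind(2 * en - 1, 2 * en))
    K[dofs, dofs] <- K[dofs, dofs] + ke
  }

  ctr <- colMeans(nodes)
  bnd <- nodes[, 1] %in% range(nodes[, 1]) | nodes[, 2] %in% range(nodes[, 2])
  u <- numeric(2 * nn)
  u[2 * which(bnd) - 1] <- eps_app * (nodes[bnd, 1] - ctr[1])
  u[2 * which(bnd)]     <- eps_app * (nodes[bnd, 2] - ctr[2])
  fixed <- sort(c(2 * which(bnd) - 1, 2 * which(bnd)))
  free <- setdiff(seq_len(2 * nn), fixed)
  if (length(free)) {
    u[free] <- solve(K[free, free], -K[free, fixed] %*% u[fixed])
  }

  strains <- t(vapply(seq_len(nrow(elems)), function(e) {
    en <- elems[e, ]
    sb <- strain_B(nodes[en, , drop = FALSE], 0, 0)
    dofs <- as.vector(rbind(2 * en - 1, 2 * en))
    as.numeric(sb$B %*% u[dofs])
  }, numeric(3)))

  list(u = u, strains = strains, K = K, free = free)
}
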