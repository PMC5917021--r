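#' Composition-dependent Young's modulus of alveolar tissue
#'
#' Linear mixture of the elastin and collagen phase moduli weighted by the
#' normalized local content: `E = 0.7 * cel * E_el + 0.3 * ccl * E_cl` with
#' `E_el = 0.1 kPa` and `E_cl = 20 kPa`. Dead cells no longer contribute to the
#' elastic response and are assigned 1 Pa without changing the mesh topology.
#'
#' @param cel normalized elastin content in \[0, 1\] (vectorized).
#' @param ccl normalized collagen content in \[0, 1\].
#' @param alive logical; dead cells get 1 Pa.
#' @param E_el,E_cl phase moduli, Pa.
#' @param delta_el,delta_cl mixture weights.
#' @param E_dead modulus of destroyed tissue, Pa.
#' @return Young's modulus in Pa.
#' @examples
#' mixture_modulus(1, 1) # healthy tissue, 6070 Pa
#' @export
mixture_modulus <- function(cel, ccl, alive = TRUE,
                            E_el = 100, E_cl = 20000,
                            delta_el = 0.7, delta_cl = 0.3, E_dead = 1) {
  if (any(cel < 0 | cel > 1) || any(ccl < 0 | ccl > 1)) {
    stop("cel and ccl must lie in [0, 1]", call. = FALSE)
  }
  E <- delta_el * cel * E_el + delta_cl * ccl * E_cl
  ifelse(alive, E, E_dead)
}

#' Structured quadrilateral mesh over the agent grid
#'
#' One bilinear quad element per grid cell, `(rows+1)*(cols+1)` nodes. Element
#' `i` maps to grid cell `i` in column-major order, so per-cell fields index
#' elements directly.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param cell_size element edge length, mm.
#' @return An object of class `quad_mesh` with `nodes` (n x 2 coordinates, mm)
#'   and `elements` (n_el x 4 counter-clockwise node indices).
#' @examples
#' m <- build_mesh(2, 2)
#' nrow(m$nodes); nrow(m$elements) # 9 nodes, 4 elements
#' @export
build_mesh <- function(rows, cols, cell_size = 1) {
  stopifnot(rows >= 1, cols >= 1, cell_size > 0)
  nr <- rows + 1L
  # node id for 0-based (row, col) corner: row-fastest (column-major like cells)
  nid <- function(r0, c0) c0 * nr + r0 + 1L
  coords <- cbind(
    x = rep(0:cols, each = nr) * cell_size,
    y = rep(0:rows, times = cols + 1L) * cell_size
  )
  cells <- expand.grid(r = seq_len(rows), c = seq_len(cols))  # column-major
  elements <- cbind(
    nid(cells$r - 1L, cells$c - 1L),
    nid(cells$r - 1L, cells$c),
    nid(cells$r, cells$c),
    nid(cells$r, cells$c - 1L)
  )
  structure(list(nodes = coords, elements = elements,
                 rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size),
            class = "quad_mesh")
}

#' Breathing load
#'
#' Displacement-controlled boundary condition emulating tidal breathing: the
#' boundary nodes are displaced according to a uniform strain field of
#' magnitude `eps_app`.
#'
#' @param eps_app applied boundary strain (dimensionless, >= 0).
#' @param mode `"biaxial"` (equal strain in x and y), `"uniaxial-x"` or
#'   `"uniaxial-y"`.
#' @return An object of class `breathing_load`.
#' @export
breathing_load <- function(eps_app = 0.05,
                           mode = c("biaxial", "uniaxial-x", "uniaxial-y")) {
  stopifnot(eps_app >= 0)
  structure(list(eps_app = eps_app, mode = match.arg(mode)),
            class = "breathing_load")
}

# plane-stress constitutive matrix
plane_stress_D <- function(E, nu) {
  E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
}

# strain-displacement matrix of a bilinear quad at natural coords (xi, eta)
quad_B <- function(xy, xi, eta) {
  dN <- matrix(c(
    -(1 - eta), -(1 - xi),
     (1 - eta), -(1 + xi),
     (1 + eta),  (1 + xi),
    -(1 + eta),  (1 - xi)
  ) / 4, nrow = 4, ncol = 2, byrow = TRUE)
  J <- t(dN) %*% xy
  dNxy <- dN %*% solve(J)
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNxy[, 1]
  B[2, seq(2, 8, 2)] <- dNxy[, 2]
  B[3, seq(1, 8, 2)] <- dNxy[, 2]
  B[3, seq(2, 8, 2)] <- dNxy[, 1]
  list(B = B, detJ = det(J))
}

# 8x8 element stiffness, 2x2 Gauss quadrature
quad_ke <- function(xy, D) {
  g <- 1 / sqrt(3)
  ke <- matrix(0, 8, 8)
  for (xi in c(-g, g)) for (eta in c(-g, g)) {
    bq <- quad_B(xy, xi, eta)
    ke <- ke + t(bq$B) %*% D %*% bq$B * bq$detJ
  }
  ke
}

#' Solve the plane-stress elasticity problem
#'
#' Static small-strain linear elasticity on the structured quad mesh with
#' per-element Young's modulus, under displacement-controlled boundary
#' conditions realizing the breathing load on every boundary node. Assembly is
#' sparse; the reduced system is solved directly.
#'
#' @param mesh a [build_mesh] result.
#' @param E per-element Young's modulus, Pa (length = number of elements).
#' @param load a [breathing_load].
#' @param nu Poisson ratio (global; plane stress, thin-tissue assumption).
#' @return An object of class `strain_field`: a tibble with one row per
#'   element (`element`, `exx`, `eyy`, `exy` tensor shear, `max_principal`)
#'   carrying the node displacement matrix in attribute `displacements`.
#' @examples
#' m <- build_mesh(3, 3)
#' sf <- solve_elasticity(m, rep(6070, 9), breathing_load(0.05))
#' range(sf$max_principal) # homogeneous: uniform 0.05
#' @export
solve_elasticity <- function(mesh, E, load = breathing_load(), nu = 0.3) {
  n_el <- nrow(mesh$elements)
  stopifnot(length(E) == n_el, all(is.finite(E)), all(E > 0), nu >= 0, nu < 0.5)
  n_nodes <- nrow(mesh$nodes)
  ndof <- 2L * n_nodes

  # assemble sparse stiffness from triplets
  ii <- integer(64 * n_el); jj <- integer(64 * n_el); vv <- numeric(64 * n_el)
  pos <- 0L
  for (e in seq_len(n_el)) {
    en <- mesh$elements[e, ]
    xy <- mesh$nodes[en, , drop = FALSE]
    ke <- quad_ke(xy, plane_stress_D(E[e], nu))
    edof <- as.vector(rbind(2L * en - 1L, 2L * en))
    idx <- pos + 1:64
    ii[idx] <- rep(edof, times = 8)
    jj[idx] <- rep(edof, each = 8)
    vv[idx] <- as.vector(ke)
    pos <- pos + 64L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ndof, ndof))

  # prescribed displacements on the boundary
  xy <- mesh$nodes
  ctr <- colMeans(xy)
  on_bnd <- xy[, 1] %in% range(xy[, 1]) | xy[, 2] %in% range(xy[, 2])
  ux <- switch(load$mode,
               "biaxial" = , "uniaxial-x" = load$eps_app * (xy[, 1] - ctr[1]),
               "uniaxial-y" = rep(0, n_nodes))
  uy <- switch(load$mode,
               "biaxial" = , "uniaxial-y" = load$eps_app * (xy[, 2] - ctr[2]),
               "uniaxial-x" = rep(0, n_nodes))
  u <- numeric(ndof)
  bdof <- c(2L * which(on_bnd) - 1L, 2L * which(on_bnd))
  u[bdof] <- c(ux[on_bnd], uy[on_bnd])
  free <- setdiff(seq_len(ndof), bdof)

  if (length(free)) {
    rhs <- -K[free, bdof, drop = FALSE] %*% u[bdof]
    u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
    res <- K[free, , drop = FALSE] %*% u
    rel <- sqrt(sum(res^2)) / max(sqrt(sum(u^2)) * max(abs(vv)), .Machine$double.eps)
    if (!is.finite(rel) || rel > 1e-8) {
      stop("elastic solve did not converge (singular or ill-conditioned system)",
           call. = FALSE)
    }
  }

  # centroid strains
  strains <- matrix(0, n_el, 3)
  for (e in seq_len(n_el)) {
    en <- mesh$elements[e, ]
    bq <- quad_B(mesh$nodes[en, , drop = FALSE], 0, 0)
    edof <- as.vector(rbind(2L * en - 1L, 2L * en))
    strains[e, ] <- as.numeric(bq$B %*% u[edof])
  }
  exx <- strains[, 1]; eyy <- strains[, 2]; exy <- strains[, 3] / 2
  maxp <- (exx + eyy) / 2 + sqrt(((exx - eyy) / 2)^2 + exy^2)
  out <- tibble::tibble(element = seq_len(n_el), exx = exx, eyy = eyy,
                        exy = exy, max_principal = maxp)
  attr(out, "displacements") <- matrix(u, ncol = 2, byrow = TRUE,
                                       dimnames = list(NULL, c("ux", "uy")))
  class(out) <- c("strain_field", class(out))
  out
}

#' Composition-weighted rupture strain limit
#'
#' Elastin sustains tensile strains up to 100 percent; pure collagen fibrils
#' fail at about 10 percent. Each cell's limit is the content-weighted blend
#' `(cel * 1.0 + ccl * 0.1) / (cel + ccl)`.
#'
#' @param cel,ccl normalized elastin/collagen content (vectorized).
#' @return Maximum tensile strain (dimensionless). Cells with no matrix left
#'   (`cel = ccl = 0`) get the conservative collagen limit 0.1, with a warning.
#' @examples
#' max_tensile_strain_limit(1, 0) # 1.0
#' max_tensile_strain_limit(0.5, 0.5) # 0.55
#' @export
max_tensile_strain_limit <- function(cel, ccl) {
  tot <- cel + ccl
  if (any(tot == 0)) {
    warning("cell(s) with no matrix content: using collagen limit 0.1")
  }
  ifelse(tot > 0, (cel * 1.0 + ccl * 0.1) / pmax(tot, .Machine$double.eps), 0.1)
}

#' Identify ruptured cells
#'
#' Compares each alive cell's maximum principal strain against its
#' composition-weighted strain limit.
#'
#' @param strains a [solve_elasticity] `strain_field` on the grid-equivalent
#'   mesh.
#' @param cel,ccl,alive per-cell composition and viability (column-major,
#'   matching element order).
#' @return Integer vector of newly ruptured cell indices (column-major).
#' @export
rupture <- function(strains, cel, ccl, alive) {
  cel <- as.vector(cel); ccl <- as.vector(ccl); alive <- as.vector(alive)
  stopifnot(nrow(strains) == length(cel), length(cel) == length(ccl),
            length(cel) == length(alive))
  lim <- suppressWarnings(max_tensile_strain_limit(cel, ccl))
  which(alive & strains$max_principal > lim)
}

#' Export mesh, displacements and strains as VTU
#'
#' Writes an ASCII VTK unstructured-grid file with the node displacements and
#' per-element strain fields, viewable in ParaView.
#'
#' @param mesh a [build_mesh] result.
#' @param strains a `strain_field` from [solve_elasticity].
#' @param path output file path (conventionally `.vtu`).
#' @param cell_data optional named list of extra per-element vectors (e.g.
#'   modulus).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, strains, path, cell_data = list()) {
  n_nodes <- nrow(mesh$nodes); n_el <- nrow(mesh$elements)
  u <- attr(strains, "displacements")
  num <- function(x) paste(format(x, digits = 9, trim = TRUE), collapse = " ")
  cd <- c(list(exx = strains$exx, eyy = strains$eyy, exy = strains$exy,
               max_principal = strains$max_principal), cell_data)
  cd_xml <- paste(vapply(names(cd), function(nm) {
    paste0('<DataArray type="Float64" Name="', nm,
           '" format="ascii">\n', num(cd[[nm]]), "\n</DataArray>")
  }, character(1)), collapse = "\n")
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    '<UnstructuredGrid>\n',
    '<Piece NumberOfPoints="', n_nodes, '" NumberOfCells="', n_el, '">\n',
    '<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    num(as.vector(t(cbind(mesh$nodes, 0)))),
    "\n</DataArray></Points>\n",
    "<Cells>\n",
    '<DataArray type="Int32" Name="connectivity" format="ascii">\n',
    num(as.vector(t(mesh$elements - 1L))),
    "\n</DataArray>\n",
    '<DataArray type="Int32" Name="offsets" format="ascii">\n',
    num(seq_len(n_el) * 4L),
    "\n</DataArray>\n",
    '<DataArray type="UInt8" Name="types" format="ascii">\n',
    num(rep(9L, n_el)),
    "\n</DataArray>\n</Cells>\n",
    '<PointData Vectors="displacement">\n',
    '<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">\n',
    num(as.vector(t(cbind(u, 0)))),
    "\n</DataArray>\n</PointData>\n",
    "<CellData>\n", cd_xml, "\n</CellData>\n",
    "</Piece>\n</UnstructuredGrid>\n</VTKFile>\n"
  )
  writeLines(xml, path)
  invisible(path)
}
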