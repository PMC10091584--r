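#' Labeled volumetric mesh
#'
#' Container for a homogeneous tetrahedral or hexahedral volumetric mesh whose
#' boundary facets carry integer labels identifying the anatomical surfaces
#' (endocardium, epicardium, base, valve and vein rings) that Dirichlet
#' boundary conditions are attached to.
#'
#' Connectivity is 1-based. Hexahedra use the Gmsh/VTK node ordering: nodes
#' 1-4 are the bottom quadrilateral (counter-clockwise), nodes 5-8 the top.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (meters).
#' @param cells integer matrix of vertex indices, one row per cell; 4 columns
#'   for tetrahedra, 8 for hexahedra.
#' @param facets integer matrix of boundary facet connectivity (3 columns for
#'   triangles, 4 for quadrilaterals).
#' @param facet_labels integer vector, one label per facet row.
#' @param element_type `"tet"` or `"hex"`.
#' @param validate check invariants (positive cell volumes, index ranges).
#' @return An object of class `labeled_mesh` with fields `vertices`, `cells`,
#'   `facets`, `facet_labels`, `element_type` and `label_set`.
#' @export
labeled_mesh <- function(vertices, cells, facets, facet_labels,
                         element_type = c("tet", "hex"), validate = TRUE) {
  element_type <- match.arg(element_type)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  facet_labels <- as.integer(facet_labels)

  nv_cell <- if (element_type == "tet") 4L else 8L
  nv_facet <- if (element_type == "tet") 3L else 4L
  if (ncol(vertices) != 3L)
    stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(cells) != nv_cell)
    stop(sprintf("%s cells must have %d vertices", element_type, nv_cell),
         call. = FALSE)
  if (ncol(facets) != nv_facet)
    stop(sprintf("%s boundary facets must have %d vertices", element_type,
                 nv_facet), call. = FALSE)
  if (length(facet_labels) != nrow(facets))
    stop("one label per boundary facet required", call. = FALSE)

  mesh <- structure(
    list(vertices = vertices,
         cells = cells,
         facets = facets,
         facet_labels = facet_labels,
         element_type = element_type,
         label_set = sort(unique(facet_labels))),
    class = "labeled_mesh")

  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  idx <- c(mesh$cells, mesh$facets)
  if (length(idx) && (min(idx) < 1L || max(idx) > nv))
    stop("connectivity index out of range", call. = FALSE)
  vol <- cell_volumes(mesh)
  if (any(vol <= 0))
    stop(sprintf("mesh has %d cells with non-positive volume",
                 sum(vol <= 0)), call. = FALSE)
  invisible(mesh)
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("Labeled %s mesh: %d vertices, %d cells, %d boundary facets\n",
              ifelse(x$element_type == "tet", "tetrahedral", "hexahedral"),
              nrow(x$vertices), nrow(x$cells), nrow(x$facets)))
  cat("  boundary labels:", paste(x$label_set, collapse = ", "), "\n")
  cat(sprintf("  average edge length: %.4g mm\n",
              1000 * average_edge_length(x)))
  invisible(x)
}

#' Cell volumes
#'
#' Tetrahedron volumes from the signed determinant formula; hexahedron volumes
#' by 2x2x2 Gauss quadrature of the trilinear map Jacobian.
#'
#' @param mesh a [labeled_mesh()].
#' @return numeric vector of cell volumes (m^3).
#' @export
cell_volumes <- function(mesh) {
  v <- mesh$vertices
  c_ <- mesh$cells
  if (mesh$element_type == "tet") {
    a <- v[c_[, 2], , drop = FALSE] - v[c_[, 1], , drop = FALSE]
    b <- v[c_[, 3], , drop = FALSE] - v[c_[, 1], , drop = FALSE]
    d <- v[c_[, 4], , drop = FALSE] - v[c_[, 1], , drop = FALSE]
    det <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
      a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
      a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
    det / 6
  } else {
    gp <- hex_quadrature()
    vol <- numeric(nrow(c_))
    coords <- hex_coord_arrays(mesh)
    for (q in seq_len(8)) {
      J <- hex_jacobian(coords, gp$dN[[q]])
      vol <- vol + gp$w[q] * J$det
    }
    vol
  }
}

# coords[[a]] = n_cells x 3 matrix of node-a coordinates
hex_coord_arrays <- function(mesh) {
  lapply(seq_len(8), function(a) mesh$vertices[mesh$cells[, a], , drop = FALSE])
}

# 2x2x2 Gauss points and trilinear shape derivatives on [-1,1]^3
hex_quadrature <- function() {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  # node order: bottom (-1,-1,-1),(1,-1,-1),(1,1,-1),(-1,1,-1), then top
  sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  dN <- lapply(seq_len(nrow(pts)), function(q) {
    p <- pts[q, ]
    d <- matrix(0, 8, 3)
    for (a in seq_len(8)) {
      s <- sgn[a, ]
      d[a, 1] <- s[1] * (1 + s[2] * p[2]) * (1 + s[3] * p[3]) / 8
      d[a, 2] <- s[2] * (1 + s[1] * p[1]) * (1 + s[3] * p[3]) / 8
      d[a, 3] <- s[3] * (1 + s[1] * p[1]) * (1 + s[2] * p[2]) / 8
    }
    d
  })
  list(pts = pts, w = rep(1, 8), dN = dN, sgn = sgn)
}

hex_shape <- function(p, sgn) {
  vapply(seq_len(8), function(a) {
    s <- sgn[a, ]
    (1 + s[1] * p[, 1]) * (1 + s[2] * p[, 2]) * (1 + s[3] * p[, 3]) / 8
  }, numeric(nrow(p)))
}

# Jacobian of the trilinear map at one quadrature point for all cells.
# Returns entries J[i][j] (vectors), determinant and inverse entries.
hex_jacobian <- function(coords, dNq) {
  J <- vector("list", 3)
  for (i in 1:3) {
    J[[i]] <- vector("list", 3)
    for (j in 1:3) {
      acc <- 0
      for (a in seq_len(8)) acc <- acc + coords[[a]][, i] * dNq[a, j]
      J[[i]][[j]] <- acc
    }
  }
  det <- J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
  inv <- vector("list", 3)
  for (i in 1:3) inv[[i]] <- vector("list", 3)
  # inverse via cofactors: inv[i][j] = cof(J)[j][i] / det
  cof <- function(r1, r2, c1, c2) J[[r1]][[c1]] * J[[r2]][[c2]] - J[[r1]][[c2]] * J[[r2]][[c1]]
  inv[[1]][[1]] <- cof(2, 3, 2, 3) / det
  inv[[1]][[2]] <- -cof(1, 3, 2, 3) / det
  inv[[1]][[3]] <- cof(1, 2, 2, 3) / det
  inv[[2]][[1]] <- -cof(2, 3, 1, 3) / det
  inv[[2]][[2]] <- cof(1, 3, 1, 3) / det
  inv[[2]][[3]] <- -cof(1, 2, 1, 3) / det
  inv[[3]][[1]] <- cof(2, 3, 1, 2) / det
  inv[[3]][[2]] <- -cof(1, 3, 1, 2) / det
  inv[[3]][[3]] <- cof(1, 2, 1, 2) / det
  list(J = J, det = det, inv = inv)
}

# unique undirected edges of the mesh (2-column matrix of vertex indices)
mesh_edges <- function(mesh) {
  c_ <- mesh$cells
  pairs <- if (mesh$element_type == "tet") {
    rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  } else {
    rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
          c(5, 6), c(6, 7), c(7, 8), c(8, 5),
          c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  }
  e <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    cbind(c_[, pairs[k, 1]], c_[, pairs[k, 2]])
  }))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Average mesh edge length
#'
#' Mean length over the unique element edges, the `h` convention used by the
#' mesh-sensitivity report.
#'
#' @param mesh a [labeled_mesh()].
#' @return average edge length in meters.
#' @export
average_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# vertex -> neighboring vertices adjacency (list), from unique edges
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  spl1 <- split(e[, 2], e[, 1])
  spl2 <- split(e[, 1], e[, 2])
  for (k in names(spl1)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], spl1[[k]])
  for (k in names(spl2)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], spl2[[k]])
  adj
}

# vertices lying on facets with any of the given labels
label_vertices <- function(mesh, labels) {
  sel <- mesh$facet_labels %in% labels
  sort(unique(as.vector(mesh$facets[sel, , drop = FALSE])))
}

#' Scale mesh coordinates
#'
#' Multiplies all vertex coordinates by a scalar (unit conversion; e.g.
#' a millimeter mesh becomes meters with `s = 1e-3`).
#'
#' @param mesh a [labeled_mesh()].
#' @param s positive scaling factor.
#' @return the scaled mesh.
#' @export
scale_mesh <- function(mesh, s) {
  stopifnot(is.numeric(s), length(s) == 1, s > 0)
  mesh$vertices <- mesh$vertices * s
  mesh
}
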