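#' Dirichlet boundary data for a Laplace problem
#'
#' Collects the Dirichlet constraints of a Laplace-Dirichlet problem:
#' prescribed values on labeled boundary surfaces, and prescribed values at
#' isolated points (apex, sphere poles), which are snapped to the nearest
#' mesh vertex. All remaining boundary is homogeneous Neumann.
#'
#' @param surface_values named-by-label numeric vector or a list
#'   `list(labels = <int vector>, value = <real>)` entries; the canonical form
#'   is a list of such entries so several labels can share one value.
#' @param point_values optional list of `list(point = <3-vector>,
#'   value = <real>)` entries.
#' @return An object of class `dirichlet_spec`.
#' @export
dirichlet_spec <- function(surface_values = list(), point_values = list()) {
  if (is.numeric(surface_values) && !is.null(names(surface_values))) {
    surface_values <- lapply(seq_along(surface_values), function(i)
      list(labels = as.integer(names(surface_values)[i]),
           value = unname(surface_values[i])))
  }
  if (length(surface_values) == 0 && length(point_values) == 0)
    stop("ill-posed problem: at least one Dirichlet constraint is required",
         call. = FALSE)
  structure(list(surface_values = surface_values, point_values = point_values),
            class = "dirichlet_spec")
}

# resolve a dirichlet_spec to (vertex indices, values) on a given mesh
resolve_dirichlet <- function(mesh, bc) {
  stopifnot(inherits(bc, "dirichlet_spec"))
  idx <- integer(0)
  val <- numeric(0)
  for (sv in bc$surface_values) {
    labs <- as.integer(sv$labels)
    missing <- setdiff(labs, mesh$label_set)
    if (length(missing))
      stop(sprintf("boundary label(s) %s not present in mesh (available: %s)",
                   paste(missing, collapse = ", "),
                   paste(mesh$label_set, collapse = ", ")), call. = FALSE)
    vi <- label_vertices(mesh, labs)
    idx <- c(idx, vi)
    val <- c(val, rep(sv$value, length(vi)))
  }
  for (pv in bc$point_values) {
    p <- as.numeric(pv$point)
    d2 <- (mesh$vertices[, 1] - p[1])^2 + (mesh$vertices[, 2] - p[2])^2 +
      (mesh$vertices[, 3] - p[3])^2
    vi <- which.min(d2)
    idx <- c(idx, vi)
    val <- c(val, pv$value)
  }
  # later entries win on duplicates, but conflicting values on the same vertex
  # from different surfaces keep the first surface value (deterministic)
  keep <- !duplicated(idx)
  list(index = idx[keep], value = val[keep])
}

#' Assemble the P1/Q1 stiffness matrix of the Laplace operator
#'
#' Linear (P1) elements on tetrahedra with exact closed-form element
#' matrices; trilinear (Q1) elements on hexahedra with 2x2x2 Gauss
#' quadrature. The assembled operator is symmetric positive semi-definite.
#'
#' @param mesh a [labeled_mesh()].
#' @return a sparse symmetric `dgCMatrix` of dimension n_vertices^2.
#' @export
assemble_stiffness <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (mesh$element_type == "tet") {
    g <- tet_gradients(mesh)  # list: vol, grad[[a]] = nel x 3
    nel <- nrow(mesh$cells)
    ii <- jj <- integer(16L * nel)
    xx <- numeric(16L * nel)
    pos <- 0L
    for (a in 1:4) for (b in 1:4) {
      k <- g$vol * (g$grad[[a]][, 1] * g$grad[[b]][, 1] +
                    g$grad[[a]][, 2] * g$grad[[b]][, 2] +
                    g$grad[[a]][, 3] * g$grad[[b]][, 3])
      ii[pos + seq_len(nel)] <- mesh$cells[, a]
      jj[pos + seq_len(nel)] <- mesh$cells[, b]
      xx[pos + seq_len(nel)] <- k
      pos <- pos + nel
    }
  } else {
    gp <- hex_quadrature()
    coords <- hex_coord_arrays(mesh)
    nel <- nrow(mesh$cells)
    acc <- vector("list", 36)  # upper-triangular accumulation a <= b
    names(acc) <- paste(rep(1:8, times = 8), rep(1:8, each = 8))[
      rep(1:8, times = 8) <= rep(1:8, each = 8)]
    for (nm in names(acc)) acc[[nm]] <- numeric(nel)
    for (q in seq_len(8)) {
      J <- hex_jacobian(coords, gp$dN[[q]])
      if (any(J$det <= 0)) stop("degenerate hexahedron (non-positive Jacobian)",
                                call. = FALSE)
      gn <- vector("list", 8)
      for (a in 1:8) {
        gn[[a]] <- lapply(1:3, function(i)
          J$inv[[1]][[i]] * gp$dN[[q]][a, 1] +
          J$inv[[2]][[i]] * gp$dN[[q]][a, 2] +
          J$inv[[3]][[i]] * gp$dN[[q]][a, 3])
      }
      for (a in 1:8) for (b in a:8) {
        nm <- paste(a, b)
        acc[[nm]] <- acc[[nm]] + gp$w[q] * J$det *
          (gn[[a]][[1]] * gn[[b]][[1]] + gn[[a]][[2]] * gn[[b]][[2]] +
           gn[[a]][[3]] * gn[[b]][[3]])
      }
    }
    nterms <- 64L
    ii <- jj <- integer(nterms * nel)
    xx <- numeric(nterms * nel)
    pos <- 0L
    for (a in 1:8) for (b in 1:8) {
      nm <- if (a <= b) paste(a, b) else paste(b, a)
      ii[pos + seq_len(nel)] <- mesh$cells[, a]
      jj[pos + seq_len(nel)] <- mesh$cells[, b]
      xx[pos + seq_len(nel)] <- acc[[nm]]
      pos <- pos + nel
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
}

# P1 shape-function gradients and volumes for all tets.
# grad of barycentric lambda_a is constant per cell; computed via the
# cofactor form of the inverse edge matrix.
tet_gradients <- function(mesh) {
  v <- mesh$vertices
  c_ <- mesh$cells
  p1 <- v[c_[, 1], , drop = FALSE]
  e1 <- v[c_[, 2], , drop = FALSE] - p1
  e2 <- v[c_[, 3], , drop = FALSE] - p1
  e3 <- v[c_[, 4], , drop = FALSE] - p1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(e2, e3)
  c31 <- cr(e3, e1)
  c12 <- cr(e1, e2)
  det <- rowSums(e1 * c23)  # 6 * volume
  if (any(det <= 0)) stop("degenerate tetrahedron (non-positive volume)",
                          call. = FALSE)
  g2 <- c23 / det
  g3 <- c31 / det
  g4 <- c12 / det
  g1 <- -(g2 + g3 + g4)
  list(vol = det / 6, grad = list(g1, g2, g3, g4))
}

#' Solve a Laplace-Dirichlet problem
#'
#' Solves `-Laplacian(u) = 0` with the Dirichlet data of `bc` and
#' homogeneous Neumann conditions on the rest of the boundary, using degree-1
#' continuous finite elements and a Jacobi-preconditioned conjugate-gradient
#' solver on the symmetrically reduced system.
#'
#' @param mesh a [labeled_mesh()].
#' @param bc a [dirichlet_spec()].
#' @param degree FE degree; only 1 is supported.
#' @param rtol relative residual tolerance of the CG iteration.
#' @param maxit maximum CG iterations.
#' @param A optional pre-assembled stiffness matrix (reused across the
#'   several potentials of one fiber-generation run).
#' @return numeric vector of nodal values (one per mesh vertex) with
#'   attribute `"iterations"`.
#' @export
solve_laplace <- function(mesh, bc, degree = 1L, rtol = 1e-10, maxit = 10000L,
                          A = NULL) {
  if (!identical(as.integer(degree), 1L))
    stop("only FE space degree 1 is supported", call. = FALSE)
  if (is.null(A)) A <- assemble_stiffness(mesh)
  nv <- nrow(mesh$vertices)
  dd <- resolve_dirichlet(mesh, bc)
  if (length(dd$index) == 0)
    stop("ill-posed problem: no Dirichlet constraint resolved", call. = FALSE)

  u <- numeric(nv)
  u[dd$index] <- dd$value
  free <- setdiff(seq_len(nv), dd$index)
  if (length(free)) {
    b <- -as.numeric(A[free, dd$index, drop = FALSE] %*% dd$value)
    Aff <- A[free, free, drop = FALSE]
    sol <- cg_solve(Aff, b, rtol = rtol, maxit = maxit)
    u[free] <- sol$x
    attr(u, "iterations") <- sol$iterations
  } else {
    attr(u, "iterations") <- 0L
  }
  u
}

# Jacobi-preconditioned conjugate gradients; deterministic, zero start.
cg_solve <- function(A, b, rtol = 1e-10, maxit = 10000L) {
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("non-SPD reduced system", call. = FALSE)
  x <- numeric(length(b))
  r <- b
  nb <- sqrt(sum(b * b))
  if (nb == 0) return(list(x = x, iterations = 0L))
  z <- r / d
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= rtol * nb)
      return(list(x = x, iterations = it))
    z <- r / d
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  stop(sprintf("CG did not converge within %d iterations (relative residual %.3e)",
               maxit, sqrt(sum(r * r)) / nb), call. = FALSE)
}

#' Recover the nodal gradient of a scalar field
#'
#' Cell gradients (constant on tetrahedra; the quadrature average on
#' hexahedra) averaged to vertices with cell-volume weights. Exact for
#' globally linear fields.
#'
#' @param mesh a [labeled_mesh()].
#' @param field numeric vector of nodal values.
#' @return an n_vertices x 3 matrix of nodal gradients.
#' @export
fem_gradient <- function(mesh, field) {
  field <- as.numeric(field)
  if (length(field) != nrow(mesh$vertices))
    stop("field length must equal the vertex count", call. = FALSE)
  nel <- nrow(mesh$cells)
  if (mesh$element_type == "tet") {
    g <- tet_gradients(mesh)
    gc <- matrix(0, nel, 3)
    for (a in 1:4) gc <- gc + field[mesh$cells[, a]] * g$grad[[a]]
    vol <- g$vol
  } else {
    gp <- hex_quadrature()
    coords <- hex_coord_arrays(mesh)
    gc <- matrix(0, nel, 3)
    vol <- numeric(nel)
    for (q in seq_len(8)) {
      J <- hex_jacobian(coords, gp$dN[[q]])
      w <- gp$w[q] * J$det
      for (i in 1:3) {
        gi <- 0
        for (a in 1:8) {
          gna <- J$inv[[1]][[i]] * gp$dN[[q]][a, 1] +
            J$inv[[2]][[i]] * gp$dN[[q]][a, 2] +
            J$inv[[3]][[i]] * gp$dN[[q]][a, 3]
          gi <- gi + field[mesh$cells[, a]] * gna
        }
        gc[, i] <- gc[, i] + w * gi
      }
      vol <- vol + w
    }
    gc <- gc / vol
  }
  # volume-weighted average of adjacent cell gradients at each vertex
  nv <- nrow(mesh$vertices)
  nodes <- as.vector(mesh$cells)
  wts <- rep(vol, ncol(mesh$cells))
  num <- matrix(0, nv, 3)
  for (i in 1:3) {
    num[, i] <- rowsum_full(wts * rep(gc[, i], ncol(mesh$cells)), nodes, nv)
  }
  den <- rowsum_full(wts, nodes, nv)
  if (any(den == 0)) stop("isolated vertex: no adjacent cell", call. = FALSE)
  num / den
}

# rowsum over groups 1..n including empty groups
rowsum_full <- function(x, g, n) {
  out <- numeric(n)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}
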