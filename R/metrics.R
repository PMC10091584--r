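#' Angular error between unit direction fields
#'
#' `delta_theta = |arccos(f_a . f_b)|` in degrees, the mesh-sensitivity error
#' estimate for orthonormalized fiber fields: any difference between two
#' solutions is an orientation difference. The dot product is clamped to
#' `[-1, 1]` so touching vectors never produce a domain error. Accepts single
#' 3-vectors or aligned n x 3 matrices.
#'
#' @param f_a,f_b unit 3-vectors or n x 3 matrices of unit rows.
#' @return angle(s) in degrees, in `[0, 180]`.
#' @export
angular_error <- function(f_a, f_b) {
  if (is.null(dim(f_a))) f_a <- matrix(f_a, 1)
  if (is.null(dim(f_b))) f_b <- matrix(f_b, 1)
  if (any(abs(sqrt(rowSums(f_a^2)) - 1) > 1e-6) ||
      any(abs(sqrt(rowSums(f_b^2)) - 1) > 1e-6))
    stop("angular_error expects unit vectors", call. = FALSE)
  d <- pmin(1, pmax(-1, rowSums(f_a * f_b)))
  abs(acos(d)) * 180 / pi
}

#' Interpolate a nodal vector field at arbitrary points of another mesh
#'
#' Locates each target point in the source mesh (uniform-grid accelerated;
#' barycentric coordinates on tetrahedra, Newton inversion of the trilinear
#' map on hexahedra), interpolates the nodal field with the element shape
#' functions, and renormalizes the result to unit length (the fields being
#' transferred are orientation fields). Points outside every cell are
#' accepted up to a small containment tolerance in reference coordinates
#' (snapping boundary round-off); farther points raise an out-of-domain
#' error.
#'
#' @param source_mesh a [labeled_mesh()].
#' @param field n_source x 3 numeric matrix of nodal vectors.
#' @param target_points m x 3 matrix of coordinates.
#' @param normalize renormalize interpolated vectors to unit length.
#' @param tol containment tolerance in reference/barycentric units.
#' @return an m x 3 matrix of interpolated vectors.
#' @export
transfer_field <- function(source_mesh, field, target_points,
                           normalize = TRUE, tol = 1e-6) {
  loc <- locate_points(source_mesh, target_points, tol = tol)
  out <- matrix(0, nrow(target_points), 3)
  for (i in 1:3) {
    vals <- matrix(field[t(source_mesh$cells[loc$cell, , drop = FALSE]), i],
                   nrow = ncol(source_mesh$cells))
    out[, i] <- colSums(vals * t(loc$weights))
  }
  if (normalize) {
    nrm <- sqrt(rowSums(out^2))
    if (any(nrm < 1e-14))
      stop("interpolated vector vanished; cannot renormalize", call. = FALSE)
    out <- out / nrm
  }
  out
}

# Locate points in a mesh. Returns cell index and shape-function weights
# (4 barycentric weights for tets, 8 trilinear weights for hexes) per point.
locate_points <- function(mesh, points, tol = 1e-6) {
  points <- as.matrix(points)
  np <- nrow(points)
  nel <- nrow(mesh$cells)
  v <- mesh$vertices

  # uniform binning of cell bounding boxes
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  nb <- pmax(1L, pmin(64L, as.integer(round(nel^(1 / 3)))))
  nb <- rep(nb, 3)
  span <- pmax(hi - lo, .Machine$double.eps)
  binof <- function(x, d) pmax(1L, pmin(nb[d], 1L + as.integer(floor(
    (x - lo[d]) / span[d] * nb[d]))))
  nvc <- ncol(mesh$cells)
  cx <- matrix(v[mesh$cells, 1], nel, nvc)
  cy <- matrix(v[mesh$cells, 2], nel, nvc)
  cz <- matrix(v[mesh$cells, 3], nel, nvc)
  pad <- tol * max(span)
  c_lo <- cbind(apply(cx, 1, min), apply(cy, 1, min), apply(cz, 1, min)) - pad
  c_hi <- cbind(apply(cx, 1, max), apply(cy, 1, max), apply(cz, 1, max)) + pad
  bin_id <- function(b) (b[, 3] - 1L) * nb[1] * nb[2] + (b[, 2] - 1L) * nb[1] + b[, 1]

  # cell -> bins (cells may span several bins)
  blo <- cbind(binof(c_lo[, 1], 1), binof(c_lo[, 2], 2), binof(c_lo[, 3], 3))
  bhi <- cbind(binof(c_hi[, 1], 1), binof(c_hi[, 2], 2), binof(c_hi[, 3], 3))
  # expand cell -> bin pairs by iterating over bin offsets (vectorized over
  # cells; the offset ranges are small, typically <= 1 per axis)
  parts_cell <- list(); parts_bin <- list(); np_i <- 0L
  for (dx in 0:max(bhi[, 1] - blo[, 1]))
    for (dy in 0:max(bhi[, 2] - blo[, 2]))
      for (dz in 0:max(bhi[, 3] - blo[, 3])) {
        sel <- which(blo[, 1] + dx <= bhi[, 1] & blo[, 2] + dy <= bhi[, 2] &
                     blo[, 3] + dz <= bhi[, 3])
        if (!length(sel)) next
        np_i <- np_i + 1L
        parts_cell[[np_i]] <- sel
        parts_bin[[np_i]] <- bin_id(cbind(blo[sel, 1] + dx, blo[sel, 2] + dy,
                                          blo[sel, 3] + dz))
      }
  cell_rep <- unlist(parts_cell, use.names = FALSE)
  cell_bins <- unlist(parts_bin, use.names = FALSE)
  ord <- order(cell_bins)
  cell_bins <- cell_bins[ord]; cell_rep <- cell_rep[ord]
  bin_split <- split(cell_rep, cell_bins)

  pb <- bin_id(cbind(binof(points[, 1], 1), binof(points[, 2], 2),
                     binof(points[, 3], 3)))
  cand_list <- bin_split[as.character(pb)]
  n_cand <- lengths(cand_list)
  if (any(n_cand == 0))
    stop(sprintf("point %d is outside the source mesh",
                 which(n_cand == 0)[1]), call. = FALSE)
  pair_pt <- rep(seq_len(np), n_cand)
  pair_cell <- unlist(cand_list, use.names = FALSE)

  P <- points[pair_pt, , drop = FALSE]
  if (mesh$element_type == "tet") {
    cpair <- mesh$cells[pair_cell, , drop = FALSE]
    p1 <- v[cpair[, 1], , drop = FALSE]
    e1 <- v[cpair[, 2], , drop = FALSE] - p1
    e2 <- v[cpair[, 3], , drop = FALSE] - p1
    e3 <- v[cpair[, 4], , drop = FALSE] - p1
    r <- P - p1
    cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                               a[, 3] * b[, 1] - a[, 1] * b[, 3],
                               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    c23 <- cr(e2, e3); c31 <- cr(e3, e1); c12 <- cr(e1, e2)
    det <- rowSums(e1 * c23)
    l1 <- rowSums(r * c23) / det
    l2 <- rowSums(r * c31) / det
    l3 <- rowSums(r * c12) / det
    l0 <- 1 - l1 - l2 - l3
    W <- cbind(l0, l1, l2, l3)
    viol <- pmax(-apply(W, 1, min), 0)
  } else {
    coords <- lapply(seq_len(8), function(a)
      v[mesh$cells[pair_cell, a], , drop = FALSE])
    sgn <- hex_quadrature()$sgn
    xi <- matrix(0, length(pair_pt), 3)
    for (it in seq_len(8)) {
      N <- hex_shape(xi, sgn)
      X <- matrix(0, length(pair_pt), 3)
      for (a in seq_len(8)) X <- X + N[, a] * coords[[a]]
      res <- P - X
      dN <- local_hex_dN(xi, sgn)
      J <- vector("list", 3)
      for (i in 1:3) J[[i]] <- vector("list", 3)
      for (i in 1:3) for (j in 1:3) {
        acc <- 0
        for (a in seq_len(8)) acc <- acc + coords[[a]][, i] * dN[[a]][, j]
        J[[i]][[j]] <- acc
      }
      upd <- solve3(J, res)
      xi <- xi + upd
      if (max(abs(upd)) < 1e-13) break
    }
    N <- hex_shape(xi, sgn)
    W <- N
    viol <- pmax(apply(abs(xi), 1, max) - 1, 0)
  }
  ord2 <- order(pair_pt, viol)
  first <- !duplicated(pair_pt[ord2])
  sel <- ord2[first]
  got_pt <- pair_pt[sel]
  res_cell <- integer(np); res_viol <- numeric(np)
  res_cell[got_pt] <- pair_cell[sel]
  res_viol[got_pt] <- viol[sel]
  Wres <- matrix(0, np, ncol(W))
  Wres[got_pt, ] <- W[sel, , drop = FALSE]
  if (any(res_viol > tol))
    stop(sprintf("point %d lies outside the source mesh (violation %.3e)",
                 which(res_viol > tol)[1], max(res_viol)), call. = FALSE)
  list(cell = res_cell, weights = Wres)
}

# trilinear shape derivatives at arbitrary reference points (list over nodes)
local_hex_dN <- function(xi, sgn) {
  lapply(seq_len(8), function(a) {
    s <- sgn[a, ]
    cbind(s[1] * (1 + s[2] * xi[, 2]) * (1 + s[3] * xi[, 3]) / 8,
          s[2] * (1 + s[1] * xi[, 1]) * (1 + s[3] * xi[, 3]) / 8,
          s[3] * (1 + s[1] * xi[, 1]) * (1 + s[2] * xi[, 2]) / 8)
  })
}

# solve 3x3 systems J x = b rowwise (entries of J given as vectors)
solve3 <- function(J, b) {
  a11 <- J[[1]][[1]]; a12 <- J[[1]][[2]]; a13 <- J[[1]][[3]]
  a21 <- J[[2]][[1]]; a22 <- J[[2]][[2]]; a23 <- J[[2]][[3]]
  a31 <- J[[3]][[1]]; a32 <- J[[3]][[2]]; a33 <- J[[3]][[3]]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  b1 <- b[, 1]; b2 <- b[, 2]; b3 <- b[, 3]
  x1 <- (b1 * (a22 * a33 - a23 * a32) - a12 * (b2 * a33 - a23 * b3) +
           a13 * (b2 * a32 - a22 * b3)) / det
  x2 <- (a11 * (b2 * a33 - a23 * b3) - b1 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * b3 - b2 * a31)) / det
  x3 <- (a11 * (a22 * b3 - b2 * a32) - a12 * (a21 * b3 - b2 * a31) +
           b1 * (a21 * a32 - a22 * a31)) / det
  cbind(x1, x2, x3)
}

#' Mesh-sensitivity study of the fiber field
#'
#' Runs [generate_fibers()] on an ordered refinement family of meshes of the
#' same labeled geometry (decreasing mesh size), takes the finest level as
#' the reference, evaluates every coarser fiber field at the finest mesh's
#' vertices via [transfer_field()], and reports the average and maximum
#' angular error [angular_error()] per coarse level.
#'
#' @param meshes list of [labeled_mesh()], ordered coarse to fine.
#' @param config an [ldrbm_config()] valid for every mesh in the family.
#' @return A `sensitivity_report`: data frame with columns `i`, `h_mm`
#'   (average edge length, millimeters), `dofs`, `avg_deg`, `max_deg`; the
#'   reference (finest) row carries `NA` errors.
#' @export
sensitivity_study <- function(meshes, config) {
  stopifnot(length(meshes) >= 2)
  labsets <- lapply(meshes, function(m) m$label_set)
  if (!all(vapply(labsets, identical, logical(1), y = labsets[[1]])))
    stop("inconsistent boundary label sets across the refinement family",
         call. = FALSE)
  h <- vapply(meshes, average_edge_length, numeric(1))
  if (any(diff(h) > 0))
    stop("meshes must be ordered by decreasing mesh size", call. = FALSE)
  results <- lapply(meshes, function(m) generate_fibers(m, config))
  nlev <- length(meshes)
  ref <- results[[nlev]]$fields$vectors$f
  pts <- meshes[[nlev]]$vertices
  avg <- max_ <- rep(NA_real_, nlev)
  for (i in seq_len(nlev - 1L)) {
    fi <- transfer_field(meshes[[i]], results[[i]]$fields$vectors$f, pts)
    dth <- angular_error(fi, ref)
    avg[i] <- mean(dth)
    max_[i] <- max(dth)
  }
  rep_df <- data.frame(i = seq_len(nlev),
                       h_mm = 1000 * h,
                       dofs = vapply(meshes, function(m) nrow(m$vertices), numeric(1)),
                       avg_deg = avg, max_deg = max_)
  structure(rep_df, class = c("sensitivity_report", "data.frame"))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Mesh sensitivity of the fiber field (reference: finest level)\n")
  cat(sprintf("%3s %10s %10s %12s %12s\n", "i", "h [mm]", "#dofs",
              "avg dth [deg]", "max dth [deg]"))
  for (r in seq_len(nrow(x))) {
    cat(sprintf("%3d %10.3f %10d %12s %12s\n", x$i[r], x$h_mm[r],
                as.integer(x$dofs[r]),
                ifelse(is.na(x$avg_deg[r]), "--", sprintf("%.4f", x$avg_deg[r])),
                ifelse(is.na(x$max_deg[r]), "--", sprintf("%.4f", x$max_deg[r]))))
  }
  invisible(x)
}

#' Write a sensitivity report as a delimited text table
#'
#' Tab-separated columns `i`, `h_mm`, `dofs`, `avg_deg`, `max_deg`, matching
#' the layout of the printed report; the reference row has empty error cells.
#'
#' @param report a `sensitivity_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sensitivity_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
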