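# LDRBM building blocks: transmural direction, normal-direction variants,
# orthonormal local frame and the helical/sheetlet axis rotations.

normalize_rows <- function(v, min_norm = 1e-14, what = "vector") {
  n <- sqrt(rowSums(v^2))
  bad <- which(n < min_norm)
  if (length(bad))
    stop(sprintf("degenerate %s (norm < %g) at vertex %d", what, min_norm, bad[1]),
         call. = FALSE)
  v / n
}

#' Transmural potential and unit transmural direction
#'
#' Solves the transmural Laplace-Dirichlet problem (potential 1 on the
#' epicardium, 0 on the endocardium, homogeneous Neumann elsewhere) and
#' returns the normalized nodal gradient, the unit transmural direction
#' pointing from endocardium to epicardium.
#'
#' @param mesh a [labeled_mesh()].
#' @param endo_tags,epi_tags integer boundary labels.
#' @param A optional pre-assembled stiffness matrix.
#' @param rtol,maxit CG solver controls.
#' @return list with `phi` (nodal values) and `e_t` (unit n x 3 matrix).
#' @export
transmural_direction <- function(mesh, endo_tags, epi_tags, A = NULL,
                                 rtol = 1e-10, maxit = 10000L) {
  bc <- dirichlet_spec(list(list(labels = endo_tags, value = 0),
                            list(labels = epi_tags, value = 1)))
  phi <- solve_laplace(mesh, bc, A = A, rtol = rtol, maxit = maxit)
  g <- fem_gradient(mesh, phi)
  list(phi = phi, e_t = normalize_rows(g, what = "transmural gradient"))
}

#' Normal direction, Rossi-Lassila variant
#'
#' The apico-basal vector field is the constant outward normal to the basal
#' plane; no auxiliary Laplace problem is solved.
#'
#' @param mesh a [labeled_mesh()].
#' @param n_base nonzero 3-vector (normalization happens during frame
#'   construction).
#' @return list with `k` (n x 3 matrix, constant rows).
#' @export
normal_rl <- function(mesh, n_base) {
  n_base <- as.numeric(n_base)
  if (length(n_base) != 3 || sqrt(sum(n_base^2)) == 0)
    stop("Normal to base must be a nonzero 3-vector", call. = FALSE)
  k <- matrix(n_base, nrow(mesh$vertices), 3, byrow = TRUE)
  list(k = k)
}

#' Normal direction, Bayer-Trayanova variant
#'
#' Solves the apico-basal Laplace-Dirichlet problem (1 on the base, 0 at the
#' apex) and takes its nodal gradient as the apico-basal vector field. The
#' base and apex may each be either labeled surfaces or points (snapped to
#' the nearest vertex), covering the ventricular slab (two surfaces), the
#' spherical slab (two pole points) and the based left ventricle (surface
#' base, point apex).
#'
#' @param mesh a [labeled_mesh()].
#' @param base_tags,apex_tags integer labels, or `NULL`.
#' @param base_point,apex_point 3-vectors, or `NULL`.
#' @param A,rtol,maxit solver controls.
#' @return list with `k` and the potential `psi`.
#' @export
normal_bt <- function(mesh, base_tags = NULL, apex_tags = NULL,
                      base_point = NULL, apex_point = NULL, A = NULL,
                      rtol = 1e-10, maxit = 10000L) {
  sv <- list(); pv <- list()
  if (!is.null(base_tags)) sv <- c(sv, list(list(labels = base_tags, value = 1)))
  if (!is.null(apex_tags)) sv <- c(sv, list(list(labels = apex_tags, value = 0)))
  if (!is.null(base_point)) pv <- c(pv, list(list(point = base_point, value = 1)))
  if (!is.null(apex_point)) pv <- c(pv, list(list(point = apex_point, value = 0)))
  if (!is.null(apex_point) && !is.null(base_tags)) {
    dd <- resolve_dirichlet(mesh, dirichlet_spec(point_values =
      list(list(point = apex_point, value = 0))))
    if (dd$index %in% label_vertices(mesh, base_tags))
      stop("apex point snaps to a vertex on the basal surface", call. = FALSE)
  }
  bc <- dirichlet_spec(sv, pv)
  psi <- solve_laplace(mesh, bc, A = A, rtol = rtol, maxit = maxit)
  list(k = fem_gradient(mesh, psi), psi = psi)
}

#' Normal direction, Doste variant (complete left ventricle)
#'
#' Blends the apico-basal direction (gradient of the potential driven by the
#' mitral ring) and the apico-outflow-tract direction (driven by the aortic
#' ring) with a harmonic interpolation weight `w` (1 on the mitral ring and
#' at the apex, 0 on the aortic ring):
#' `k = w grad(psi_ab) + (1 - w) grad(psi_ot)`.
#'
#' @param mesh a [labeled_mesh()].
#' @param mv_tags,av_tags disjoint mitral/aortic ring labels.
#' @param apex_point epicardial apex coordinate.
#' @param A,rtol,maxit solver controls.
#' @return list with `k`, `psi_ab`, `psi_ot`, `w`.
#' @export
normal_doste <- function(mesh, mv_tags, av_tags, apex_point, A = NULL,
                         rtol = 1e-10, maxit = 10000L) {
  if (length(intersect(mv_tags, av_tags)))
    stop("Tags MV and Tags AV must be disjoint", call. = FALSE)
  if (is.null(A)) A <- assemble_stiffness(mesh)
  ab <- normal_bt(mesh, base_tags = mv_tags, apex_point = apex_point, A = A,
                  rtol = rtol, maxit = maxit)
  ot <- normal_bt(mesh, base_tags = av_tags, apex_point = apex_point, A = A,
                  rtol = rtol, maxit = maxit)
  bc_w <- dirichlet_spec(list(list(labels = mv_tags, value = 1),
                              list(labels = av_tags, value = 0)),
                         list(list(point = apex_point, value = 1)))
  w <- solve_laplace(mesh, bc_w, A = A, rtol = rtol, maxit = maxit)
  k <- ab$k * w + ot$k * (1 - w)
  list(k = k, psi_ab = ab$psi, psi_ot = ot$psi, w = as.numeric(w))
}

#' Normal direction, atrial bundle variant
#'
#' Solves three auxiliary Laplace-Dirichlet problems and assigns each vertex
#' to exactly one atrial bundle by threshold tests, taking the corresponding
#' gradient as the local apico-basal vector:
#' \itemize{
#' \item `psi_ab`: 1 on the mitral ring, 0 at the (appendage) apex point;
#' \item `psi_v`: 1 on the left pulmonary-vein ring, 0 on the right;
#' \item `psi_r`: 1 on the mitral ring, 0 on both pulmonary-vein rings.
#' }
#' Bundle rule, evaluated in fixed order per vertex with thresholds
#' `taus = c(mv, lpv, rpv)` in `[0, 1]`: mitral bundle if `psi_r > 1 - tau_mv`
#' (k from `psi_r`); else left-vein bundle if `psi_v > 1 - tau_lpv` (k from
#' `psi_v`); else right-vein bundle if `psi_v < tau_rpv` (k from `psi_v`);
#' else the default apico-basal bundle (k from `psi_ab`). The comparisons are
#' strict, so a threshold of 0 disables its bundle.
#'
#' @param mesh a [labeled_mesh()].
#' @param mv_tags,lpv_tags,rpv_tags ring labels.
#' @param apex_point appendage apex coordinate.
#' @param taus named numeric vector `c(mv=, lpv=, rpv=)` in `[0, 1]`.
#' @param A,rtol,maxit solver controls.
#' @return list with `k`, `psi_ab`, `psi_v`, `psi_r` and `bundle_id`
#'   (factor with levels mv/lpv/rpv/ab).
#' @export
normal_atrial <- function(mesh, mv_tags, lpv_tags, rpv_tags, apex_point,
                          taus = c(mv = 0.15, lpv = 0.15, rpv = 0.15),
                          A = NULL, rtol = 1e-10, maxit = 10000L) {
  taus <- taus[c("mv", "lpv", "rpv")]
  if (anyNA(taus) || any(taus < 0) || any(taus > 1))
    stop("Tau bundle MV/LPV/RPV must lie in [0, 1]", call. = FALSE)
  if (is.null(A)) A <- assemble_stiffness(mesh)
  s <- function(bc) solve_laplace(mesh, bc, A = A, rtol = rtol, maxit = maxit)
  psi_ab <- s(dirichlet_spec(list(list(labels = mv_tags, value = 1)),
                             list(list(point = apex_point, value = 0))))
  psi_v <- s(dirichlet_spec(list(list(labels = lpv_tags, value = 1),
                                 list(labels = rpv_tags, value = 0))))
  psi_r <- s(dirichlet_spec(list(list(labels = mv_tags, value = 1),
                                 list(labels = c(lpv_tags, rpv_tags), value = 0))))
  g_ab <- fem_gradient(mesh, psi_ab)
  g_v <- fem_gradient(mesh, psi_v)
  g_r <- fem_gradient(mesh, psi_r)

  bundle <- rep("ab", nrow(mesh$vertices))
  bundle[psi_v < taus["rpv"]] <- "rpv"
  bundle[psi_v > 1 - taus["lpv"]] <- "lpv"
  bundle[psi_r > 1 - taus["mv"]] <- "mv"
  bundle <- factor(bundle, levels = c("mv", "lpv", "rpv", "ab"))

  k <- g_ab
  k[bundle == "mv", ] <- g_r[bundle == "mv", ]
  k[bundle %in% c("lpv", "rpv"), ] <- g_v[bundle %in% c("lpv", "rpv"), ]
  list(k = k, psi_ab = as.numeric(psi_ab), psi_v = as.numeric(psi_v),
       psi_r = as.numeric(psi_r), bundle_id = bundle)
}

#' Orthonormal local frame from transmural direction and apico-basal vector
#'
#' Per vertex: `e_n` is the apico-basal vector with its transmural component
#' removed and normalized; `e_l = e_n x e_t` completes the right-handed
#' orthonormal triad `Q = [e_l, e_n, e_t]`.
#'
#' Vertices where the apico-basal vector is (numerically) parallel to the
#' transmural direction are degenerate; their apico-basal vector is replaced
#' by the average over adjacent non-degenerate vertices (deterministic; such
#' isolated degeneracies occur at apex/pole singularities) and they are
#' flagged in the returned `mask`. If every vertex is degenerate the
#' apico-basal field is globally parallel to the transmural field and an
#' error is raised.
#'
#' @param e_t unit transmural directions (n x 3).
#' @param k apico-basal vectors (n x 3), not necessarily unit.
#' @param mesh the mesh (for vertex adjacency in degenerate repair); may be
#'   `NULL` if no degeneracy repair is possible/needed.
#' @return list of class `frame_field`: `e_l`, `e_n`, `e_t`, `mask`.
#' @export
build_frame <- function(e_t, k, mesh = NULL) {
  nrm_t <- sqrt(rowSums(e_t^2))
  if (any(abs(nrm_t - 1) > 1e-8))
    stop("e_t must be unit norm", call. = FALSE)
  proj <- rowSums(k * e_t)
  kp <- k - proj * e_t
  kn <- sqrt(rowSums(kp^2))
  tol <- 1e-10 * pmax(sqrt(rowSums(k^2)), .Machine$double.xmin)
  mask <- kn < tol
  if (all(mask))
    stop("apico-basal direction is globally parallel to the transmural direction",
         call. = FALSE)
  if (any(mask)) {
    if (is.null(mesh))
      stop(sprintf("degenerate frame at vertex %d and no mesh for repair",
                   which(mask)[1]), call. = FALSE)
    adj <- vertex_adjacency(mesh)
    k_fix <- k
    for (v in which(mask)) {
      nb <- adj[[v]]
      nb <- nb[!mask[nb]]
      if (!length(nb))
        stop(sprintf("degenerate frame at vertex %d could not be repaired", v),
             call. = FALSE)
      k_fix[v, ] <- colMeans(k[nb, , drop = FALSE])
    }
    proj <- rowSums(k_fix * e_t)
    kp <- k_fix - proj * e_t
    kn <- sqrt(rowSums(kp^2))
    still <- which(kn < tol)
    # truly singular vertices (e.g. the apex of an axisymmetric ventricle,
    # where every apico-basal candidate is transmural and the neighbor
    # average cancels): choose the normal direction deterministically by
    # projecting the first coordinate axis not parallel to e_t
    for (vtx in still) {
      ax <- diag(3)[, which(abs(e_t[vtx, ]) < 0.9)[1]]
      kp[vtx, ] <- ax - sum(ax * e_t[vtx, ]) * e_t[vtx, ]
      kn[vtx] <- sqrt(sum(kp[vtx, ]^2))
    }
  }
  e_n <- kp / kn
  e_l <- cross_rows(e_n, e_t)
  structure(list(e_l = e_l, e_n = e_n, e_t = e_t, mask = mask),
            class = "frame_field")
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Rodrigues rotation of row vectors v about unit row-vector axes by angles
# (radians), right-hand rule.
rodrigues_rotate <- function(v, axis, angle) {
  ca <- cos(angle)
  sa <- sin(angle)
  axv <- cross_rows(axis, v)
  ad <- rowSums(axis * v)
  v * ca + axv * sa + axis * (ad * (1 - ca))
}

#' Rotate the local frame into the myofiber directions
#'
#' Applies the two LDRBM axis rotations per vertex: the longitudinal
#' direction `e_l` rotates counter-clockwise (right-hand rule) about the
#' transmural direction `e_t` by the helical angle `alpha`, giving the fiber
#' direction `f`; then the transmural direction rotates counter-clockwise
#' about the (rotated) longitudinal axis `f` by the sheetlet angle `beta`,
#' giving the sheet direction `s`, with the sheet-normal `n` completing the
#' rotated triad. Both angles follow the linear transmural laws
#' `alpha(phi) = alpha_endo (1 - phi) + alpha_epi phi` (same for `beta`).
#'
#' @param frame a `frame_field` from [build_frame()].
#' @param phi transmural potential (nodal values in `[0, 1]`).
#' @param law list/vector with `alpha_endo`, `alpha_epi`, `beta_endo`,
#'   `beta_epi` in degrees; each entry may also be a per-vertex vector (used
#'   by the outflow-tract blending of the complete-ventricle algorithm).
#' @return list of class `fiber_field`: unit matrices `f`, `n`, `s`, plus
#'   the per-vertex `alpha` and `beta` (degrees).
#' @export
rotate_frame <- function(frame, phi, law) {
  stopifnot(inherits(frame, "frame_field"))
  alpha <- (law$alpha_endo * (1 - phi) + law$alpha_epi * phi) * pi / 180
  beta <- (law$beta_endo * (1 - phi) + law$beta_epi * phi) * pi / 180
  f <- rodrigues_rotate(frame$e_l, frame$e_t, alpha)
  n1 <- rodrigues_rotate(frame$e_n, frame$e_t, alpha)
  s <- rodrigues_rotate(frame$e_t, f, beta)
  n <- rodrigues_rotate(n1, f, beta)
  structure(list(f = f, n = n, s = s,
                 alpha = alpha * 180 / pi, beta = beta * 180 / pi),
            class = "fiber_field")
}

#' Helical angle of a fiber field relative to the unrotated frame
#'
#' Signed angle (degrees, in the local tangent plane) between the fiber
#' direction and the longitudinal direction, measured counter-clockwise
#' about the transmural axis: `atan2(f . e_n, f . e_l)`.
#'
#' @param f fiber directions (n x 3).
#' @param frame a `frame_field`.
#' @return numeric vector of angles in degrees.
#' @export
helical_angle <- function(f, frame) {
  atan2(rowSums(f * frame$e_n), rowSums(f * frame$e_l)) * 180 / pi
}
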