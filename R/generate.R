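#' LDRBM run configuration
#'
#' Typed configuration for [generate_fibers()]. The parameter-file interface
#' ([read_params()], [cli_main()]) builds this object from the `prm`/`json`
#' dialects; it can also be constructed directly.
#'
#' @param geometry_type one of `"Slab"`, `"Left ventricle"`,
#'   `"Left ventricle complete"`, `"Left atrium"`.
#' @param tags named list of integer label vectors; which names are required
#'   depends on the geometry: `endo`/`epi` always; `base_up`/`base_down`
#'   (ventricular slab); `base` (based left ventricle); `mv`/`av` (complete
#'   left ventricle); `mv`/`lpv`/`rpv` (left atrium).
#' @param alpha_endo,alpha_epi helical angle at endocardium/epicardium
#'   (degrees; defaults are the physiological -60/+60 range).
#' @param beta_endo,beta_epi sheetlet angles (degrees).
#' @param alpha_endo_ot,alpha_epi_ot,beta_endo_ot,beta_epi_ot outflow-tract
#'   angle variants (complete left ventricle only; default to the standard
#'   angles).
#' @param algorithm_type `"BT"` or `"RL"` (based left ventricle only).
#' @param normal_to_base 3-vector, outward normal to the basal plane (RL).
#' @param apex epicardial apex coordinate (BT/complete/atrial-appendage).
#' @param sphere_slab logical: spherical rather than ventricular slab.
#' @param sphere_radial_fibers logical: exchange fiber and sheet directions
#'   on the spherical slab (radial fibers).
#' @param north_pole,south_pole epicardial pole coordinates (spherical slab).
#' @param appendage logical: realistic left atrium with appendage apex.
#' @param taus named vector `c(mv=, lpv=, rpv=)` of atrial bundle thresholds
#'   in `[0, 1]`.
#' @param fe_degree FE space degree (only 1 supported).
#' @param scaling_factor coordinate scaling applied when the mesh is read
#'   from file.
#' @param mesh_filename input mesh path (used by the CLI runner).
#' @param enable_output,output_filename output switch and basename.
#' @param rtol,maxit linear solver controls.
#' @return an object of class `ldrbm_config`.
#' @export
ldrbm_config <- function(geometry_type,
                         tags = list(),
                         alpha_endo = -60, alpha_epi = 60,
                         beta_endo = 0, beta_epi = 0,
                         alpha_endo_ot = alpha_endo, alpha_epi_ot = alpha_epi,
                         beta_endo_ot = beta_endo, beta_epi_ot = beta_epi,
                         algorithm_type = "BT",
                         normal_to_base = c(0, 0, 1),
                         apex = NULL,
                         sphere_slab = FALSE,
                         sphere_radial_fibers = FALSE,
                         north_pole = NULL, south_pole = NULL,
                         appendage = FALSE,
                         taus = c(mv = 0.15, lpv = 0.15, rpv = 0.15),
                         fe_degree = 1L,
                         scaling_factor = 1,
                         mesh_filename = NULL,
                         enable_output = FALSE,
                         output_filename = "fibers",
                         rtol = 1e-10, maxit = 10000L) {
  geometry_type <- match.arg(geometry_type,
    c("Slab", "Left ventricle", "Left ventricle complete", "Left atrium"))
  algorithm_type <- match.arg(algorithm_type, c("BT", "RL"))
  if (scaling_factor <= 0) stop("Scaling factor must be positive", call. = FALSE)
  if (!identical(as.integer(fe_degree), 1L))
    stop("only FE space degree 1 is supported", call. = FALSE)
  stopifnot(is.list(tags))
  tags <- lapply(tags, as.integer)
  cfg <- structure(list(
    geometry_type = geometry_type, tags = tags,
    angles = list(alpha_endo = alpha_endo, alpha_epi = alpha_epi,
                  beta_endo = beta_endo, beta_epi = beta_epi,
                  alpha_endo_ot = alpha_endo_ot, alpha_epi_ot = alpha_epi_ot,
                  beta_endo_ot = beta_endo_ot, beta_epi_ot = beta_epi_ot),
    algorithm_type = algorithm_type,
    normal_to_base = as.numeric(normal_to_base),
    apex = if (!is.null(apex)) as.numeric(apex),
    sphere_slab = isTRUE(sphere_slab),
    sphere_radial_fibers = isTRUE(sphere_radial_fibers),
    north_pole = if (!is.null(north_pole)) as.numeric(north_pole),
    south_pole = if (!is.null(south_pole)) as.numeric(south_pole),
    appendage = isTRUE(appendage),
    taus = taus,
    fe_degree = 1L, scaling_factor = scaling_factor,
    mesh_filename = mesh_filename,
    enable_output = isTRUE(enable_output), output_filename = output_filename,
    rtol = rtol, maxit = as.integer(maxit)),
    class = "ldrbm_config")
  validate_config(cfg)
  cfg
}

need_tags <- function(cfg, names_needed, param_names) {
  for (i in seq_along(names_needed)) {
    nm <- names_needed[i]
    if (is.null(cfg$tags[[nm]]) || !length(cfg$tags[[nm]]))
      stop(sprintf("missing required parameter '%s' for Geometry type = %s",
                   param_names[i], cfg$geometry_type), call. = FALSE)
  }
}

validate_config <- function(cfg) {
  gt <- cfg$geometry_type
  if (gt != "Left ventricle" && !is.null(cfg$.algo_set) && cfg$.algo_set)
    stop(sprintf("Algorithm type is only valid for Geometry type = Left ventricle, not %s", gt),
         call. = FALSE)
  if (any(cfg$taus < 0 | cfg$taus > 1))
    stop("Tau bundle MV/LPV/RPV must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Generate myocardial fiber, sheet and sheet-normal fields
#'
#' Runs the full Laplace-Dirichlet rule-based pipeline on a labeled mesh:
#' transmural potential and direction, the geometry-appropriate apico-basal
#' (normal) direction, the orthonormal local frame, and the helical/sheetlet
#' axis rotations, dispatching on `Geometry type`:
#' \itemize{
#' \item `Slab`: Bayer-Trayanova normal from the base-up/base-down surfaces
#'   (ventricular slab) or from the north/south pole points (spherical slab);
#'   the spherical slab can optionally exchange fiber and sheet directions
#'   ("radial fibers").
#' \item `Left ventricle` (based): Bayer-Trayanova (surface base, apex point)
#'   or Rossi-Lassila (constant basal normal), per `Algorithm type`.
#' \item `Left ventricle complete`: Doste blended normal from the mitral and
#'   aortic rings, with outflow-tract angle variants blended by the same
#'   harmonic weight.
#' \item `Left atrium`: bundle-selected atrial normal; no transmural rotation
#'   is applied, the local frame itself is the fiber triad.
#' }
#'
#' @param mesh a [labeled_mesh()] whose labels match `config$tags`.
#' @param config an [ldrbm_config()].
#' @return An object of class `ldrbm_result`: list with `fields` (a
#'   [field_bundle()] holding the potentials and the unit `f`, `s`, `n`
#'   vector fields), `frame` (the unrotated `frame_field`), `fiber` (the
#'   rotated `fiber_field`, `NULL` for atrial runs), `bundle_id` (atrial
#'   only) and `config`.
#' @export
generate_fibers <- function(mesh, config) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(config, "ldrbm_config"))
  gt <- config$geometry_type
  tags <- config$tags
  A <- assemble_stiffness(mesh)
  rtol <- config$rtol; maxit <- config$maxit

  need_tags(config, c("endo", "epi"), c("Tags endo", "Tags epi"))
  tm <- transmural_direction(mesh, tags$endo, tags$epi, A = A,
                             rtol = rtol, maxit = maxit)
  aux <- list()
  bundle_id <- NULL

  if (gt == "Slab") {
    if (config$sphere_slab) {
      if (is.null(config$north_pole) || is.null(config$south_pole))
        stop("missing required parameter 'North pole'/'South pole' for the spherical slab",
             call. = FALSE)
      nd <- normal_bt(mesh, base_point = config$north_pole,
                      apex_point = config$south_pole, A = A,
                      rtol = rtol, maxit = maxit)
    } else {
      need_tags(config, c("base_up", "base_down"),
                c("Tags base up", "Tags base down"))
      nd <- normal_bt(mesh, base_tags = tags$base_up, apex_tags = tags$base_down,
                      A = A, rtol = rtol, maxit = maxit)
    }
    aux$psi <- nd$psi
  } else if (gt == "Left ventricle") {
    need_tags(config, "base", "Tags base")
    if (config$algorithm_type == "RL") {
      nd <- normal_rl(mesh, config$normal_to_base)
    } else {
      if (is.null(config$apex))
        stop("missing required parameter 'Apex' for Algorithm type = BT",
             call. = FALSE)
      nd <- normal_bt(mesh, base_tags = tags$base, apex_point = config$apex,
                      A = A, rtol = rtol, maxit = maxit)
      aux$psi <- nd$psi
    }
  } else if (gt == "Left ventricle complete") {
    need_tags(config, c("mv", "av"), c("Tags MV", "Tags AV"))
    if (is.null(config$apex))
      stop("missing required parameter 'Apex' for Geometry type = Left ventricle complete",
           call. = FALSE)
    nd <- normal_doste(mesh, tags$mv, tags$av, config$apex, A = A,
                       rtol = rtol, maxit = maxit)
    aux$psi_ab <- nd$psi_ab; aux$psi_ot <- nd$psi_ot; aux$w <- nd$w
  } else { # Left atrium
    need_tags(config, c("mv", "lpv", "rpv"),
              c("Tags MV", "Tags LPV", "Tags RPV"))
    apex <- config$apex
    if (is.null(apex)) {
      if (config$appendage)
        stop("missing required parameter 'Apex' for Appendage = true", call. = FALSE)
      # idealized atrium: apex defaults to the vertex farthest from the
      # mitral-ring centroid
      mv_v <- label_vertices(mesh, tags$mv)
      ctr <- colMeans(mesh$vertices[mv_v, , drop = FALSE])
      d2 <- rowSums(sweep(mesh$vertices, 2, ctr)^2)
      apex <- mesh$vertices[which.max(d2), ]
    }
    nd <- normal_atrial(mesh, tags$mv, tags$lpv, tags$rpv, apex,
                        taus = config$taus, A = A, rtol = rtol, maxit = maxit)
    aux$psi_ab <- nd$psi_ab; aux$psi_v <- nd$psi_v; aux$psi_r <- nd$psi_r
    bundle_id <- nd$bundle_id
  }

  frame <- build_frame(tm$e_t, nd$k, mesh)

  if (gt == "Left atrium") {
    # no transmural rotation: the local frame is the fiber triad
    fiber <- NULL
    f <- frame$e_l; n <- frame$e_n; s <- frame$e_t
  } else {
    ang <- config$angles
    if (gt == "Left ventricle complete") {
      w <- nd$w
      law <- list(alpha_endo = w * ang$alpha_endo + (1 - w) * ang$alpha_endo_ot,
                  alpha_epi = w * ang$alpha_epi + (1 - w) * ang$alpha_epi_ot,
                  beta_endo = w * ang$beta_endo + (1 - w) * ang$beta_endo_ot,
                  beta_epi = w * ang$beta_epi + (1 - w) * ang$beta_epi_ot)
    } else {
      law <- ang[c("alpha_endo", "alpha_epi", "beta_endo", "beta_epi")]
    }
    fiber <- rotate_frame(frame, tm$phi, law)
    f <- fiber$f; n <- fiber$n; s <- fiber$s
    if (gt == "Slab" && config$sphere_slab && config$sphere_radial_fibers) {
      tmpv <- f; f <- s; s <- tmpv
    }
  }

  scalars <- c(list(phi = as.numeric(tm$phi)), lapply(aux, as.numeric))
  fields <- field_bundle(scalars = scalars,
                         vectors = list(f = f, s = s, n = n),
                         unit_norm = c("f", "s", "n"))
  check_bundle(mesh, fields)
  structure(list(mesh = mesh, fields = fields, frame = frame, fiber = fiber,
                 phi = as.numeric(tm$phi), bundle_id = bundle_id,
                 config = config),
            class = "ldrbm_result")
}

#' @export
print.ldrbm_result <- function(x, ...) {
  cat(sprintf("LDRBM fiber field (%s) on %d vertices\n",
              x$config$geometry_type, nrow(x$mesh$vertices)))
  cat("  fields:", paste(c(names(x$fields$scalars), names(x$fields$vectors)),
                         collapse = ", "), "\n")
  if (!is.null(x$bundle_id)) {
    tb <- table(x$bundle_id)
    cat("  atrial bundles:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  if (any(x$frame$mask))
    cat(sprintf("  %d degenerate vertices repaired by neighbor averaging\n",
                sum(x$frame$mask)))
  invisible(x)
}
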