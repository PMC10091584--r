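#' Structured ventricular-slab fixture mesh
#'
#' Generates a structured axis-aligned slab with the boundary-label layout of
#' a ventricular slab: the endocardium and epicardium are the lateral walls
#' at `x = 0` and `x = Lx`, the base-up/base-down surfaces are the top
#' (`z = Lz`) and bottom (`z = 0`) faces, and the two remaining walls share a
#' side label (homogeneous Neumann in all Laplace-Dirichlet problems).
#'
#' The tetrahedral variant splits every hexahedron into six tetrahedra with
#' the Kuhn (path-simplex) decomposition, whose face diagonals are
#' translation-invariant, so neighboring cells conform without node insertion.
#'
#' @param Lx,Ly,Lz slab extents in meters (`Lx` is the transmural wall
#'   thickness).
#' @param nx,ny,nz positive subdivision counts per axis.
#' @param element_type `"hex"` or `"tet"`.
#' @return A [labeled_mesh()] with labels `endo = 1`, `epi = 2`,
#'   `base_up = 3`, `base_down = 4`, `side = 5` (stored in the `"labels"`
#'   attribute).
#' @examples
#' m <- make_slab(1, 1, 1, 2, 2, 2, "hex")
#' m$label_set
#' @export
make_slab <- function(Lx = 0.024, Ly = 0.04, Lz = 0.04,
                      nx = 4L, ny = 7L, nz = 7L,
                      element_type = c("hex", "tet")) {
  element_type <- match.arg(element_type)
  if (any(c(Lx, Ly, Lz) <= 0)) stop("slab extents must be positive", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 1L)) stop("subdivisions must be >= 1", call. = FALSE)

  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  zs <- seq(0, Lz, length.out = nz + 1L)
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  vertices <- cbind(xs[g$i + 1L], ys[g$j + 1L], zs[g$k + 1L])

  ce <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  hexes <- cbind(vid(ce$i,      ce$j,      ce$k),
                 vid(ce$i + 1L, ce$j,      ce$k),
                 vid(ce$i + 1L, ce$j + 1L, ce$k),
                 vid(ce$i,      ce$j + 1L, ce$k),
                 vid(ce$i,      ce$j,      ce$k + 1L),
                 vid(ce$i + 1L, ce$j,      ce$k + 1L),
                 vid(ce$i + 1L, ce$j + 1L, ce$k + 1L),
                 vid(ce$i,      ce$j + 1L, ce$k + 1L))

  # boundary quads per face; corners ordered so the (min, max) corner diagonal
  # used by the Kuhn split is quad[ ,1]-quad[ ,3]
  face_quads <- function(axis, at_max) {
    if (axis == 1L) {
      q <- expand.grid(a = 0:(ny - 1L), b = 0:(nz - 1L))
      i <- if (at_max) nx else 0L
      cbind(vid(i, q$a, q$b), vid(i, q$a + 1L, q$b),
            vid(i, q$a + 1L, q$b + 1L), vid(i, q$a, q$b + 1L))
    } else if (axis == 2L) {
      q <- expand.grid(a = 0:(nx - 1L), b = 0:(nz - 1L))
      j <- if (at_max) ny else 0L
      cbind(vid(q$a, j, q$b), vid(q$a + 1L, j, q$b),
            vid(q$a + 1L, j, q$b + 1L), vid(q$a, j, q$b + 1L))
    } else {
      q <- expand.grid(a = 0:(nx - 1L), b = 0:(ny - 1L))
      k <- if (at_max) nz else 0L
      cbind(vid(q$a, q$b, k), vid(q$a + 1L, q$b, k),
            vid(q$a + 1L, q$b + 1L, k), vid(q$a, q$b + 1L, k))
    }
  }
  labels <- c(endo = 1L, epi = 2L, base_up = 3L, base_down = 4L, side = 5L)
  quads <- rbind(face_quads(1L, FALSE), face_quads(1L, TRUE),
                 face_quads(3L, TRUE), face_quads(3L, FALSE),
                 face_quads(2L, FALSE), face_quads(2L, TRUE))
  nq <- c(ny * nz, ny * nz, nx * ny, nx * ny, nx * nz, nx * nz)
  qlab <- rep(c(1L, 2L, 3L, 4L, 5L, 5L), nq)

  if (element_type == "hex") {
    mesh <- labeled_mesh(vertices, hexes, quads, qlab, "hex")
  } else {
    tets <- kuhn_split(hexes)
    tris <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
    tlab <- c(qlab, qlab)
    mesh <- labeled_mesh(vertices, tets, tris, tlab, "tet")
  }
  attr(mesh, "labels") <- labels
  mesh
}

# Kuhn decomposition of hexahedra (nodes ordered bottom CCW then top CCW)
# into 6 tets per cell; diagonals are translation-invariant so structured
# grids conform. Local corner c(x,y,z bits) -> node index in Gmsh ordering.
kuhn_split <- function(hexes) {
  corner <- function(b) {
    # bits b = c(bx, by, bz) in {0,1}
    idx <- matrix(c(0, 0, 0, 1, 1, 0, 0, 1, 1, 1, 0, 1), ncol = 3, byrow = FALSE)
    local_of_bits <- c("000" = 1L, "100" = 2L, "110" = 3L, "010" = 4L,
                       "001" = 5L, "101" = 6L, "111" = 7L, "011" = 8L)
    local_of_bits[paste0(b[1], b[2], b[3])]
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sgn <- c(1, -1, -1, 1, 1, -1)
  tets <- vector("list", 6)
  for (p in seq_along(perms)) {
    bits <- matrix(0L, 4, 3)
    for (step in 1:3) {
      bits[step + 1L, ] <- bits[step, ]
      bits[step + 1L, perms[[p]][step]] <- 1L
    }
    loc <- vapply(1:4, function(r) corner(bits[r, ]), integer(1))
    if (sgn[p] < 0) loc <- loc[c(1, 2, 4, 3)]  # fix orientation
    tets[[p]] <- hexes[, loc, drop = FALSE]
  }
  do.call(rbind, tets)
}

# icosahedron oriented with vertices at the +z / -z poles
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  lat <- atan(1 / 2)
  up <- t(vapply(0:4, function(k) {
    a <- 2 * pi * k / 5
    c(cos(lat) * cos(a), cos(lat) * sin(a), sin(lat))
  }, numeric(3)))
  dn <- t(vapply(0:4, function(k) {
    a <- 2 * pi * k / 5 + pi / 5
    c(cos(lat) * cos(a), cos(lat) * sin(a), -sin(lat))
  }, numeric(3)))
  v <- rbind(c(0, 0, 1), up, dn, c(0, 0, -1))
  f <- rbind(
    cbind(1, 1 + (0:4) + 1, 1 + ((0:4 + 1) %% 5) + 1),
    cbind(1 + (0:4) + 1, 1 + 5 + (0:4) + 1, 1 + ((0:4 + 1) %% 5) + 1),
    cbind(1 + ((0:4 + 1) %% 5) + 1, 1 + 5 + (0:4) + 1, 1 + 5 + ((0:4 + 1) %% 5) + 1),
    cbind(12, 1 + 5 + ((0:4 + 1) %% 5) + 1, 1 + 5 + (0:4) + 1))
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

# subdivide each triangle into 4, projecting new vertices onto the unit sphere
subdivide_sphere <- function(surf) {
  v <- surf$vertices
  f <- surf$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  key <- pmin(e[, 1], e[, 2]) + nrow(v) * pmax(e[, 1], e[, 2])
  uk <- unique(key)
  mid_id <- match(key, uk) + nrow(v)
  ue <- e[!duplicated(key), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m13 <- mid_id[2 * nf + seq_len(nf)]
  faces <- rbind(cbind(f[, 1], m12, m13),
                 cbind(f[, 2], m23, m12),
                 cbind(f[, 3], m13, m23),
                 cbind(m12, m23, m13))
  storage.mode(faces) <- "integer"
  list(vertices = rbind(v, mids), faces = faces)
}

icosphere <- function(subdiv = 2L) {
  s <- icosahedron()
  for (k in seq_len(subdiv)) s <- subdivide_sphere(s)
  s
}

#' Spherical-shell fixture mesh, optionally with labeled ring holes
#'
#' Tetrahedral mesh of the shell `r_endo <= |x| <= r_epi`, built by radially
#' extruding a subdivided icosahedral sphere triangulation into prism layers
#' and splitting each prism into three tetrahedra with an index-consistent
#' (Dompierre-style) rule. The inner surface is labeled `endo = 1`, the outer
#' `epi = 2`. Optional holes (spherical caps removed from the surface
#' triangulation before extrusion) model the mitral-valve and pulmonary-vein
#' rings of an idealized left atrium: the lateral rim facets of each hole
#' carry that hole's label (3, 4, ... in the order given).
#'
#' The icosahedron is oriented with vertices at the north and south poles, so
#' pole point constraints of the spherical-slab geometry snap exactly.
#'
#' @param r_endo,r_epi inner/outer radii in meters, `0 < r_endo < r_epi`.
#' @param subdiv icosphere subdivision level (0 = icosahedron, each level
#'   quadruples the surface triangle count).
#' @param nr number of radial element layers.
#' @param holes optional named list; each element is `list(dir = <3-vector>,
#'   angle = <cap half-angle, radians>)`. Hole labels are assigned in order
#'   starting at 3 and named in the `"labels"` attribute.
#' @return A [labeled_mesh()] (tetrahedral).
#' @export
make_shell <- function(r_endo = 0.02, r_epi = 0.03, subdiv = 2L, nr = 2L,
                       holes = NULL) {
  if (!(r_endo > 0 && r_epi > r_endo)) stop("need 0 < r_endo < r_epi", call. = FALSE)
  nr <- as.integer(nr)
  if (nr < 1L) stop("nr must be >= 1", call. = FALSE)
  surf <- icosphere(as.integer(subdiv))
  v <- surf$vertices
  f <- surf$faces
  labels <- c(endo = 1L, epi = 2L)

  hole_of_face <- NULL
  if (!is.null(holes) && length(holes)) {
    if (is.null(names(holes)) || any(names(holes) == ""))
      stop("holes must be a named list", call. = FALSE)
    dirs <- t(vapply(holes, function(h) {
      d <- h$dir / sqrt(sum(h$dir^2)); d
    }, numeric(3)))
    angs <- vapply(holes, function(h) h$angle, numeric(1))
    # overlapping caps are a spec error
    if (length(holes) > 1L) {
      for (a in seq_len(length(holes) - 1L)) for (b in (a + 1L):length(holes)) {
        sep <- acos(max(-1, min(1, sum(dirs[a, ] * dirs[b, ]))))
        if (sep < angs[a] + angs[b])
          stop("hole specifications overlap", call. = FALSE)
      }
    }
    inside <- sapply(seq_along(holes), function(h) {
      cosang <- v %*% dirs[h, ]
      drop(cosang) > cos(angs[h])
    })  # n_vertices x n_holes
    inside <- matrix(inside, nrow = nrow(v))
    face_in <- sapply(seq_along(holes), function(h) {
      inside[f[, 1], h] & inside[f[, 2], h] & inside[f[, 3], h]
    })
    face_in <- matrix(face_in, nrow = nrow(f))
    keep <- rowSums(face_in) == 0
    removed_hole <- apply(face_in, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
    # rim edges: edges shared between a kept and a removed face
    all_e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- pmin(all_e[, 1], all_e[, 2]) + nrow(v) * pmax(all_e[, 1], all_e[, 2])
    stat <- rep(keep, 3)
    hol <- rep(removed_hole, 3)
    kept_keys <- unique(ekey[stat])
    rim_sel <- !stat & ekey %in% kept_keys
    rim_edges <- all_e[rim_sel, , drop = FALSE]
    rim_hole <- hol[rim_sel]
    dup <- duplicated(ekey[rim_sel])
    rim_edges <- rim_edges[!dup, , drop = FALSE]
    rim_hole <- rim_hole[!dup]
    f <- f[keep, , drop = FALSE]
    labels <- c(labels, stats::setNames(2L + seq_along(holes), names(holes)))
  } else {
    rim_edges <- matrix(integer(0), 0, 2)
    rim_hole <- integer(0)
  }

  # drop surface vertices no longer referenced
  used <- sort(unique(c(as.vector(f), as.vector(rim_edges))))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3)
  if (nrow(rim_edges)) rim_edges <- matrix(remap[rim_edges], ncol = 2)

  ns <- nrow(v)
  radii <- seq(r_endo, r_epi, length.out = nr + 1L)
  vertices <- do.call(rbind, lapply(radii, function(r) v * r))

  # prisms -> 3 tets, diagonal through the smallest global index of each quad
  bot <- f
  tets_list <- vector("list", nr)
  for (l in seq_len(nr)) {
    off_b <- (l - 1L) * ns
    off_t <- l * ns
    b <- bot + off_b
    tp <- bot + off_t
    # rotate so the smallest bottom index is first
    rot <- max.col(-cbind(b[, 1], b[, 2], b[, 3]), ties.method = "first")
    idx <- function(m, r) m[cbind(seq_len(nrow(m)), r)]
    r2 <- function(r) (r %% 3L) + 1L
    a1 <- idx(b, rot); a2 <- idx(b, r2(rot)); a3 <- idx(b, r2(r2(rot)))
    t1 <- idx(tp, rot); t2 <- idx(tp, r2(rot)); t3 <- idx(tp, r2(r2(rot)))
    # quad face (a2, a3, t3, t2): diagonal via smaller of a2, a3
    c1 <- a2 < a3
    T <- matrix(0L, length(a1) * 3L, 4L)
    n <- length(a1)
    # template 1 (a2 < a3): (a1,a2,a3,t3), (a1,a2,t3,t2), (a1,t2,t3,t1)
    # template 2:           (a1,a2,a3,t2), (a1,t2,a3,t3), (a1,t2,t3,t1)
    T[seq_len(n), ] <- cbind(a1, a2, a3, ifelse(c1, t3, t2))
    T[n + seq_len(n), ] <- cbind(a1, ifelse(c1, a2, t2), ifelse(c1, t3, a3), ifelse(c1, t2, t3))
    T[2L * n + seq_len(n), ] <- cbind(a1, t2, t3, t1)
    tets_list[[l]] <- T
  }
  tets <- do.call(rbind, tets_list)

  # orientation fix
  a <- vertices[tets[, 2], ] - vertices[tets[, 1], ]
  bb <- vertices[tets[, 3], ] - vertices[tets[, 1], ]
  d <- vertices[tets[, 4], ] - vertices[tets[, 1], ]
  det <- a[, 1] * (bb[, 2] * d[, 3] - bb[, 3] * d[, 2]) -
    a[, 2] * (bb[, 1] * d[, 3] - bb[, 3] * d[, 1]) +
    a[, 3] * (bb[, 1] * d[, 2] - bb[, 2] * d[, 1])
  flip <- det < 0
  tmp <- tets[flip, 3L]
  tets[flip, 3L] <- tets[flip, 4L]
  tets[flip, 4L] <- tmp

  # boundary facets: endo surface, epi surface, hole rims
  tris <- rbind(f, f + nr * ns)
  tlab <- rep(c(1L, 2L), each = nrow(f))
  if (nrow(rim_edges)) {
    rims <- vector("list", nr)
    for (l in seq_len(nr)) {
      off_b <- (l - 1L) * ns
      off_t <- l * ns
      aa <- rim_edges[, 1]; bbv <- rim_edges[, 2]
      al <- aa + off_b; bl <- bbv + off_b; au <- aa + off_t; bu <- bbv + off_t
      c1 <- al < bl
      t1 <- cbind(al, bl, ifelse(c1, bu, au))
      t2 <- cbind(ifelse(c1, al, bl), ifelse(c1, bu, au), ifelse(c1, au, bu))
      rims[[l]] <- list(tri = rbind(t1, t2), lab = rep(2L + rim_hole, 2L))
    }
    tris <- rbind(tris, do.call(rbind, lapply(rims, `[[`, "tri")))
    tlab <- c(tlab, unlist(lapply(rims, `[[`, "lab")))
  }

  mesh <- labeled_mesh(vertices, tets, tris, tlab, "tet")
  attr(mesh, "labels") <- labels
  mesh
}

#' Idealized truncated-ellipsoid left-ventricle fixture mesh
#'
#' Tetrahedral mesh of the wall between two concentric coaxial ellipsoids,
#' truncated by a basal plane `z = z_base`. Built on a structured
#' (transmural, colatitude, longitude) grid with the apex row collapsed to a
#' single pole vertex per transmural layer, then Kuhn-split to tetrahedra
#' (degenerate slivers at the pole are dropped).
#'
#' Labels: `endo = 1` (inner ellipsoid), `epi = 2` (outer), `base = 3`
#' (truncation plane). The epicardial apex coordinate (the point furthest
#' below the base) is attached as the `"apex"` attribute.
#'
#' @param a_endo,c_endo equatorial/polar semi-axes of the endocardial
#'   ellipsoid (meters).
#' @param a_epi,c_epi semi-axes of the epicardial ellipsoid; must strictly
#'   exceed the endocardial ones.
#' @param z_base height of the truncation plane; must satisfy
#'   `-c_endo < z_base < c_endo`.
#' @param n_s,n_u,n_v subdivisions in the transmural, colatitude and
#'   longitude directions.
#' @return A [labeled_mesh()] (tetrahedral) with an `"apex"` attribute.
#' @export
make_lv <- function(a_endo = 0.02, c_endo = 0.06, a_epi = 0.03, c_epi = 0.07,
                    z_base = 0.02, n_s = 2L, n_u = 8L, n_v = 12L) {
  if (!(a_epi > a_endo && c_epi > c_endo))
    stop("epicardial semi-axes must strictly exceed endocardial ones", call. = FALSE)
  if (!(z_base > -c_endo && z_base < c_endo))
    stop("truncation plane must cut both ellipsoids between apex and top", call. = FALSE)
  n_s <- as.integer(n_s); n_u <- as.integer(n_u); n_v <- as.integer(n_v)
  if (any(c(n_s, n_u, n_v) < 2L)) stop("subdivisions must be >= 2", call. = FALSE)

  a_of <- function(s) a_endo + (a_epi - a_endo) * s
  c_of <- function(s) c_endo + (c_epi - c_endo) * s

  # vertex table: rows i_u in 0..n_u-1 have n_v vertices; row n_u is the pole
  per_layer <- n_u * n_v + 1L
  vid <- function(i_s, i_u, i_v) {
    # i_v wraps; pole row i_u == n_u
    base <- i_s * per_layer
    ifelse(i_u == n_u, base + per_layer,
           base + i_u * n_v + (i_v %% n_v) + 1L)
  }
  verts <- matrix(0, (n_s + 1L) * per_layer, 3)
  meta_s <- integer(nrow(verts)); meta_u <- integer(nrow(verts))
  for (i_s in 0:n_s) {
    s <- i_s / n_s
    a <- a_of(s); cc <- c_of(s)
    u0 <- acos(z_base / cc)
    for (i_u in 0:(n_u - 1L)) {
      u <- u0 + (pi - u0) * i_u / n_u
      for (i_v in 0:(n_v - 1L)) {
        ang <- 2 * pi * i_v / n_v
        id <- vid(i_s, i_u, i_v)
        verts[id, ] <- c(a * sin(u) * cos(ang), a * sin(u) * sin(ang), cc * cos(u))
        meta_s[id] <- i_s; meta_u[id] <- i_u
      }
    }
    id <- vid(i_s, n_u, 0L)
    verts[id, ] <- c(0, 0, -cc)
    meta_s[id] <- i_s; meta_u[id] <- n_u
  }

  ce <- expand.grid(i_s = 0:(n_s - 1L), i_u = 0:(n_u - 1L), i_v = 0:(n_v - 1L))
  # hex in (s, v, u) index space; node order bottom CCW then top (u increasing
  # towards the apex plays the role of the local z axis)
  hexes <- cbind(vid(ce$i_s,      ce$i_u,      ce$i_v),
                 vid(ce$i_s + 1L, ce$i_u,      ce$i_v),
                 vid(ce$i_s + 1L, ce$i_u,      ce$i_v + 1L),
                 vid(ce$i_s,      ce$i_u,      ce$i_v + 1L),
                 vid(ce$i_s,      ce$i_u + 1L, ce$i_v),
                 vid(ce$i_s + 1L, ce$i_u + 1L, ce$i_v),
                 vid(ce$i_s + 1L, ce$i_u + 1L, ce$i_v + 1L),
                 vid(ce$i_s,      ce$i_u + 1L, ce$i_v + 1L))
  tets <- kuhn_split(hexes)
  # drop degenerate tets at the collapsed pole
  distinct <- (tets[, 1] != tets[, 2]) & (tets[, 1] != tets[, 3]) &
    (tets[, 1] != tets[, 4]) & (tets[, 2] != tets[, 3]) &
    (tets[, 2] != tets[, 4]) & (tets[, 3] != tets[, 4])
  tets <- tets[distinct, , drop = FALSE]
  a <- verts[tets[, 2], ] - verts[tets[, 1], ]
  b <- verts[tets[, 3], ] - verts[tets[, 1], ]
  d <- verts[tets[, 4], ] - verts[tets[, 1], ]
  det <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
    a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
    a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  keep <- abs(det) > max(abs(det)) * 1e-12
  tets <- tets[keep, , drop = FALSE]
  det <- det[keep]
  flip <- det < 0
  tmp <- tets[flip, 3L]; tets[flip, 3L] <- tets[flip, 4L]; tets[flip, 4L] <- tmp

  bf <- boundary_faces_tet(tets)
  on_endo <- meta_s[bf[, 1]] == 0L & meta_s[bf[, 2]] == 0L & meta_s[bf[, 3]] == 0L
  on_epi <- meta_s[bf[, 1]] == n_s & meta_s[bf[, 2]] == n_s & meta_s[bf[, 3]] == n_s
  on_base <- meta_u[bf[, 1]] == 0L & meta_u[bf[, 2]] == 0L & meta_u[bf[, 3]] == 0L
  lab <- ifelse(on_endo, 1L, ifelse(on_epi, 2L, ifelse(on_base, 3L, NA_integer_)))
  if (anyNA(lab)) stop("internal error: unclassified boundary facet", call. = FALSE)

  mesh <- labeled_mesh(verts, tets, bf, lab, "tet")
  attr(mesh, "labels") <- c(endo = 1L, epi = 2L, base = 3L)
  attr(mesh, "apex") <- c(0, 0, -c_epi)
  mesh
}

# faces of a tet connectivity that belong to exactly one tet
boundary_faces_tet <- function(tets) {
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  s <- t(apply(faces, 1, sort))
  n <- max(faces) + 1
  key <- (s[, 1] * n + s[, 2]) * n + s[, 3]
  cnt <- table(key)
  once <- names(cnt)[cnt == 1]
  faces[match(as.numeric(once), key), , drop = FALSE]
}
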