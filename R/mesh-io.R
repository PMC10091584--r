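#' Read a labeled Gmsh mesh
#'
#' Parses Gmsh ASCII `.msh` files (format versions 2.2 and 4.1) containing a
#' single volumetric element type (4-node tetrahedra or 8-node hexahedra) and
#' labeled boundary facets (triangles/quadrilaterals). Physical-group tags
#' are preferred as facet labels; elementary-entity tags are used when no
#' physical tag is attached (both conventions occur in gmsh output).
#'
#' All coordinates are multiplied by `scaling_factor` on read, converting the
#' mesh to SI meters (e.g. `1e-3` for a millimeter mesh). `.msh` node
#' numbering is converted to contiguous 1-based internal indexing.
#'
#' @param path path to an ASCII `.msh` file.
#' @param scaling_factor positive real coordinate scaling.
#' @return A [labeled_mesh()].
#' @export
read_msh <- function(path, scaling_factor = 1) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path), call. = FALSE)
  stopifnot(is.numeric(scaling_factor), length(scaling_factor) == 1,
            scaling_factor > 0)
  lines <- readLines(path, warn = FALSE)
  fmt_i <- which(lines == "$MeshFormat")
  if (!length(fmt_i)) stop("not a Gmsh .msh file (no $MeshFormat section)", call. = FALSE)
  fmt <- strsplit(trimws(lines[fmt_i[1] + 1L]), "\\s+")[[1]]
  version <- fmt[1]
  if (length(fmt) >= 2 && fmt[2] != "0")
    stop("binary .msh files are not supported; re-export as ASCII", call. = FALSE)
  if (!version %in% c("2.2", "4.1"))
    stop(sprintf("unsupported .msh format version %s (supported: 2.2, 4.1)", version),
         call. = FALSE)
  parsed <- if (version == "2.2") parse_msh22(lines) else parse_msh41(lines)

  present <- names(parsed$cells)[!vapply(parsed$cells, is.null, logical(1))]
  vol_types <- intersect(c("tet", "hex"), present)
  if (length(vol_types) == 0)
    stop("no volumetric elements (tet4/hex8) found in mesh", call. = FALSE)
  if (length(vol_types) > 1)
    stop("mixed tetrahedral/hexahedral meshes are not supported", call. = FALSE)
  etype <- vol_types
  facet_name <- if (etype == "tet") "tri" else "quad"
  facets <- parsed$cells[[facet_name]]
  if (is.null(facets) || nrow(facets$conn) == 0)
    stop("mesh has no labeled boundary facets of the expected kind", call. = FALSE)

  # compact vertex numbering to vertices actually referenced
  mesh <- labeled_mesh(parsed$vertices * scaling_factor,
                       parsed$cells[[etype]]$conn,
                       facets$conn, facets$labels, etype)
  mesh
}

# token stream helpers ------------------------------------------------------

msh_section <- function(lines, name) {
  i0 <- which(lines == paste0("$", name))
  if (!length(i0)) return(NULL)
  i1 <- which(lines == paste0("$End", name))
  i1 <- i1[i1 > i0[1]][1]
  lines[(i0[1] + 1L):(i1 - 1L)]
}

parse_msh22 <- function(lines) {
  nl <- msh_section(lines, "Nodes")
  n_nodes <- as.integer(nl[1])
  toks <- scan(text = nl[-1], quiet = TRUE)
  nodes <- matrix(toks, ncol = 4, byrow = TRUE)
  tag_map <- integer(max(nodes[, 1]))
  tag_map[as.integer(nodes[, 1])] <- seq_len(n_nodes)
  vertices <- nodes[, 2:4, drop = FALSE]

  el <- msh_section(lines, "Elements")
  n_el <- as.integer(el[1])
  out <- list(tri = NULL, quad = NULL, tet = NULL, hex = NULL)
  acc <- list(tri = list(), quad = list(), tet = list(), hex = list())
  nodes_of <- c(`2` = 3L, `3` = 4L, `4` = 4L, `5` = 8L)
  kind_of <- c(`2` = "tri", `3` = "quad", `4` = "tet", `5` = "hex")
  for (ln in el[-1]) {
    t <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    type <- as.character(as.integer(t[2]))
    if (!type %in% names(nodes_of)) next
    ntags <- as.integer(t[3])
    tags <- t[3 + seq_len(ntags)]
    phys <- if (ntags >= 1 && tags[1] > 0) tags[1] else if (ntags >= 2) tags[2] else 0
    conn <- t[(4 + ntags):(3 + ntags + nodes_of[[type]])]
    k <- kind_of[[type]]
    acc[[k]][[length(acc[[k]]) + 1L]] <- c(phys, conn)
  }
  for (k in names(acc)) {
    if (length(acc[[k]])) {
      m <- do.call(rbind, acc[[k]])
      conn <- matrix(tag_map[as.integer(m[, -1])], nrow = nrow(m))
      out[[k]] <- list(conn = conn, labels = as.integer(m[, 1]))
    }
  }
  list(vertices = vertices, cells = out)
}

parse_msh41 <- function(lines) {
  # physical tags of surface/volume entities, from $Entities (when present)
  ent <- msh_section(lines, "Entities")
  phys_of_entity <- list(`2` = integer(0), `3` = integer(0))
  if (!is.null(ent)) {
    toks <- scan(text = ent, quiet = TRUE)
    pos <- 1L
    counts <- toks[pos:(pos + 3L)]; pos <- pos + 4L
    nxt <- function(n) { v <- toks[pos:(pos + n - 1L)]; pos <<- pos + n; v }
    # points: tag x y z numPhys phys...
    for (i in seq_len(counts[1])) {
      nxt(4L); np <- nxt(1L); if (np > 0) nxt(np)
    }
    # curves: tag 6 bbox numPhys phys... numBnd bnd...
    for (i in seq_len(counts[2])) {
      nxt(7L); np <- nxt(1L); if (np > 0) nxt(np)
      nb <- nxt(1L); if (nb > 0) nxt(nb)
    }
    surf_tags <- integer(0); surf_phys <- integer(0)
    for (i in seq_len(counts[3])) {
      tg <- nxt(1L); nxt(6L); np <- nxt(1L)
      ph <- if (np > 0) nxt(np)[1] else 0L
      nb <- nxt(1L); if (nb > 0) nxt(nb)
      surf_tags <- c(surf_tags, as.integer(tg)); surf_phys <- c(surf_phys, as.integer(ph))
    }
    vol_tags <- integer(0); vol_phys <- integer(0)
    for (i in seq_len(counts[4])) {
      tg <- nxt(1L); nxt(6L); np <- nxt(1L)
      ph <- if (np > 0) nxt(np)[1] else 0L
      nb <- nxt(1L); if (nb > 0) nxt(nb)
      vol_tags <- c(vol_tags, as.integer(tg)); vol_phys <- c(vol_phys, as.integer(ph))
    }
    phys_of_entity[["2"]] <- stats::setNames(surf_phys, surf_tags)
    phys_of_entity[["3"]] <- stats::setNames(vol_phys, vol_tags)
  }

  nl <- msh_section(lines, "Nodes")
  toks <- scan(text = nl, quiet = TRUE)
  pos <- 1L
  nxt <- function(n) { v <- toks[pos:(pos + n - 1L)]; pos <<- pos + n; v }
  hdr <- nxt(4L)
  n_blocks <- as.integer(hdr[1]); n_nodes <- as.integer(hdr[2])
  max_tag <- as.integer(hdr[4])
  tag_map <- integer(max_tag)
  vertices <- matrix(0, n_nodes, 3)
  filled <- 0L
  for (b in seq_len(n_blocks)) {
    bh <- nxt(4L)
    nn <- as.integer(bh[4])
    if (nn == 0) next
    tags <- as.integer(nxt(nn))
    xyz <- matrix(nxt(3L * nn), ncol = 3, byrow = TRUE)
    tag_map[tags] <- filled + seq_len(nn)
    vertices[filled + seq_len(nn), ] <- xyz
    filled <- filled + nn
  }

  el <- msh_section(lines, "Elements")
  toks <- scan(text = el, quiet = TRUE)
  pos <- 1L
  hdr <- nxt(4L)
  n_blocks <- as.integer(hdr[1])
  nodes_of <- c(`2` = 3L, `3` = 4L, `4` = 4L, `5` = 8L)
  kind_of <- c(`2` = "tri", `3` = "quad", `4` = "tet", `5` = "hex")
  acc <- list(tri = list(), quad = list(), tet = list(), hex = list())
  for (b in seq_len(n_blocks)) {
    bh <- nxt(4L)
    dim <- as.integer(bh[1]); etag <- as.integer(bh[2])
    type <- as.character(as.integer(bh[3])); ne <- as.integer(bh[4])
    if (!type %in% names(nodes_of)) {
      # skip unsupported block (points/lines/etc.): 1 tag + k nodes per elem
      k <- switch(type, `15` = 1L, `1` = 2L, `8` = 3L, `9` = 6L, `10` = 9L,
                  `11` = 10L, `16` = 8L, `17` = 20L, NA_integer_)
      if (is.na(k)) stop(sprintf("unsupported element type %s in .msh file", type),
                         call. = FALSE)
      nxt((1L + k) * ne)
      next
    }
    nv <- nodes_of[[type]]
    block <- matrix(nxt((1L + nv) * ne), ncol = 1L + nv, byrow = TRUE)
    lab <- etag
    pmap <- phys_of_entity[[as.character(dim)]]
    if (length(pmap) && as.character(etag) %in% names(pmap) &&
        pmap[[as.character(etag)]] > 0)
      lab <- pmap[[as.character(etag)]]
    k <- kind_of[[type]]
    acc[[k]][[length(acc[[k]]) + 1L]] <-
      cbind(rep(lab, ne), block[, -1, drop = FALSE])
  }
  out <- list(tri = NULL, quad = NULL, tet = NULL, hex = NULL)
  for (k in names(acc)) {
    if (length(acc[[k]])) {
      m <- do.call(rbind, acc[[k]])
      conn <- matrix(tag_map[as.integer(m[, -1])], nrow = nrow(m))
      out[[k]] <- list(conn = conn, labels = as.integer(m[, 1]))
    }
  }
  list(vertices = vertices, cells = out)
}

#' Write a labeled mesh as Gmsh ASCII `.msh` version 2.2
#'
#' Boundary facets are written before volume cells; each element carries its
#' label as both the physical and the elementary tag (volume cells get tag 0).
#'
#' @param mesh a [labeled_mesh()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_msh <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nv)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nv),
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
             con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(nrow(mesh$facets) + nrow(mesh$cells))), con)
  ftype <- if (mesh$element_type == "tet") 2L else 3L
  ctype <- if (mesh$element_type == "tet") 4L else 5L
  fconn <- apply(mesh$facets, 1, paste, collapse = " ")
  writeLines(sprintf("%d %d 2 %d %d %s", seq_along(fconn), ftype,
                     mesh$facet_labels, mesh$facet_labels, fconn), con)
  cconn <- apply(mesh$cells, 1, paste, collapse = " ")
  writeLines(sprintf("%d %d 2 0 0 %s", nrow(mesh$facets) + seq_along(cconn),
                     ctype, cconn), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Bundle of per-vertex output fields
#'
#' Named scalar and vector nodal fields aligned with one mesh; the container
#' written to disk by [write_fields()].
#'
#' @param scalars named list of numeric vectors (one value per vertex).
#' @param vectors named list of n x 3 numeric matrices.
#' @param unit_norm character vector naming the vector fields that must be
#'   unit length (checked to 1e-8).
#' @return an object of class `field_bundle`.
#' @export
field_bundle <- function(scalars = list(), vectors = list(),
                         unit_norm = character(0)) {
  structure(list(scalars = scalars, vectors = vectors, unit_norm = unit_norm),
            class = "field_bundle")
}

check_bundle <- function(mesh, fields) {
  stopifnot(inherits(fields, "field_bundle"))
  nv <- nrow(mesh$vertices)
  for (nm in names(fields$scalars))
    if (length(fields$scalars[[nm]]) != nv)
      stop(sprintf("scalar field '%s' is not aligned with the mesh", nm),
           call. = FALSE)
  for (nm in names(fields$vectors)) {
    v <- fields$vectors[[nm]]
    if (!is.matrix(v) || nrow(v) != nv || ncol(v) != 3)
      stop(sprintf("vector field '%s' is not aligned with the mesh", nm),
           call. = FALSE)
    if (nm %in% fields$unit_norm) {
      nrm <- sqrt(rowSums(v^2))
      if (any(abs(nrm - 1) > 1e-8))
        stop(sprintf("vector field '%s' is flagged unit-norm but is not", nm),
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write nodal fields in a ParaView-consumable format
#'
#' Writes the mesh and all fields of a [field_bundle()] as an ASCII VTU
#' (VTK XML unstructured grid) file, directly loadable in ParaView for
#' streamline/glyph visualization of the fiber fields. Numbers are printed
#' with 17 significant digits, so a round-trip through the file is bitwise
#' exact for doubles.
#'
#' @param mesh a [labeled_mesh()].
#' @param fields a [field_bundle()] aligned with `mesh`.
#' @param path output path (conventionally `.vtu`).
#' @param enabled when `FALSE`, writes nothing and returns invisibly (the
#'   `Enable output` switch of the parameter file).
#' @return the path invisibly, or `NULL` when disabled.
#' @export
write_fields <- function(mesh, fields, path, enabled = TRUE) {
  if (!isTRUE(enabled)) return(invisible(NULL))
  check_bundle(mesh, fields)
  nv <- nrow(mesh$vertices)
  nc <- nrow(mesh$cells)
  num <- function(x) sprintf("%.17g", x)
  out <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, nc),
    '      <PointData>')
  for (nm in names(fields$scalars)) {
    out <- c(out,
             sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm),
             paste(num(fields$scalars[[nm]]), collapse = " "),
             '        </DataArray>')
  }
  for (nm in names(fields$vectors)) {
    v <- t(fields$vectors[[nm]])
    out <- c(out,
             sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm),
             paste(num(as.vector(v)), collapse = " "),
             '        </DataArray>')
  }
  vtk_type <- if (mesh$element_type == "tet") 10L else 12L
  out <- c(out,
           '      </PointData>',
           '      <Points>',
           '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
           paste(num(as.vector(t(mesh$vertices))), collapse = " "),
           '        </DataArray>',
           '      </Points>',
           '      <Cells>',
           '        <DataArray type="Int64" Name="connectivity" format="ascii">',
           paste(as.vector(t(mesh$cells)) - 1L, collapse = " "),
           '        </DataArray>',
           '        <DataArray type="Int64" Name="offsets" format="ascii">',
           paste(seq_len(nc) * ncol(mesh$cells), collapse = " "),
           '        </DataArray>',
           '        <DataArray type="UInt8" Name="types" format="ascii">',
           paste(rep(vtk_type, nc), collapse = " "),
           '        </DataArray>',
           '      </Cells>',
           '    </Piece>',
           '  </UnstructuredGrid>',
           '</VTKFile>')
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write output file: %s", path), call. = FALSE)
  invisible(path)
}
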