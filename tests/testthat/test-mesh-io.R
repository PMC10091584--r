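# Gmsh reader/writer and VTU field output.

test_that("minimal MSH 2.2 file parses with labels, counts and scaling", {
  f <- msh22_minimal(tempfile(fileext = ".msh"))
  m <- read_msh(f, 1.0)
  expect_s3_class(m, "labeled_mesh")
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$cells), 1)
  expect_equal(nrow(m$facets), 4)
  expect_equal(m$element_type, "tet")
  expect_setequal(m$label_set, c(10L, 20L, 30L, 40L))

  ms <- read_msh(f, 1e-3)
  expect_identical(ms$vertices, m$vertices * 1e-3)
})

test_that("MSH 4.1 file parses, resolving physical tags through entities", {
  f <- msh41_minimal(tempfile(fileext = ".msh"))
  m <- read_msh(f)
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$cells), 1)
  expect_setequal(m$label_set, c(10L, 20L, 30L, 40L))
  # identical content to the 2.2 encoding of the same mesh
  m22 <- read_msh(msh22_minimal(tempfile(fileext = ".msh")))
  expect_identical(m$cells, m22$cells)
  expect_identical(m$facet_labels, m22$facet_labels)
  expect_equal(m$vertices, m22$vertices)
})

test_that("malformed mesh files are rejected with specific messages", {
  bad_version <- tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "3.0 0 8", "$EndMeshFormat"), bad_version)
  expect_error(read_msh(bad_version), "3\\.0")

  binary <- tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 1 8", "$EndMeshFormat"), binary)
  expect_error(read_msh(binary), "binary")

  nolabels <- tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "4", "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
               "$EndNodes", "$Elements", "1", "1 4 2 0 1 1 2 3 4",
               "$EndElements"), nolabels)
  expect_error(read_msh(nolabels), "boundary facets")

  expect_error(read_msh(tempfile()), "not found")
})

test_that("write -> read round-trip preserves geometry, topology and labels", {
  for (et in c("tet", "hex")) {
    m <- make_slab(0.024, 0.04, 0.04, 2, 3, 3, et)
    f <- tempfile(fileext = ".msh")
    write_msh(m, f)
    m2 <- read_msh(f)
    expect_lt(max(abs(m2$vertices - m$vertices)) / max(abs(m$vertices)), 1e-12)
    expect_identical(m2$cells, m$cells)
    expect_identical(m2$facets, m$facets)
    expect_identical(m2$facet_labels, m$facet_labels)
  }
})

test_that("read scaling is exactly linear in the scale factor", {
  m <- make_slab(0.02, 0.03, 0.04, 2, 2, 2, "tet")
  f <- tempfile(fileext = ".msh")
  write_msh(m, f)
  s <- 2.5e-3
  expect_identical(read_msh(f, s)$vertices, s * read_msh(f, 1)$vertices)
})

test_that("VTU output round-trips bitwise through an independent XML reader", {
  m <- read_msh(msh22_minimal(tempfile(fileext = ".msh")))
  phi <- c(0, 0, 0, 1)
  f3 <- matrix(rep(c(1, 0, 0), each = 4), ncol = 3)
  fb <- field_bundle(scalars = list(phi = phi),
                     vectors = list(f = f3, s = f3[, c(2, 1, 3)], n = f3[, c(2, 3, 1)]),
                     unit_norm = c("f", "s", "n"))
  path <- tempfile(fileext = ".vtu")
  write_fields(m, fb, path)
  x <- xml2::read_xml(path)
  da <- xml2::xml_find_all(x, ".//PointData/DataArray")
  nms <- xml2::xml_attr(da, "Name")
  expect_setequal(nms, c("phi", "f", "s", "n"))
  got_phi <- scan(text = xml2::xml_text(da[[which(nms == "phi")]]), quiet = TRUE)
  expect_identical(got_phi, phi)
  vec_arrays <- da[!is.na(xml2::xml_attr(da, "NumberOfComponents"))]
  expect_length(vec_arrays, 3)
  got_f <- matrix(scan(text = xml2::xml_text(da[[which(nms == "f")]]), quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  expect_identical(got_f, f3)
  pts <- xml2::xml_find_first(x, ".//Points/DataArray")
  expect_identical(matrix(scan(text = xml2::xml_text(pts), quiet = TRUE),
                          ncol = 3, byrow = TRUE), m$vertices)
})

test_that("disabled output writes nothing; misaligned fields are rejected", {
  m <- read_msh(msh22_minimal(tempfile(fileext = ".msh")))
  fb <- field_bundle(scalars = list(phi = c(0, 0, 0, 1)))
  path <- tempfile(fileext = ".vtu")
  expect_null(write_fields(m, fb, path, enabled = FALSE))
  expect_false(file.exists(path))

  bad <- field_bundle(scalars = list(phi = c(0, 1)))
  expect_error(write_fields(m, bad, path), "aligned")
  badv <- field_bundle(vectors = list(f = matrix(2, 4, 3)), unit_norm = "f")
  expect_error(write_fields(m, badv, path), "unit")
})
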