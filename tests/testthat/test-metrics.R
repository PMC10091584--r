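# Angular error, cross-mesh field transfer and the sensitivity protocol.

test_that("angular error has the documented values, symmetry and clamping", {
  expect_equal(angular_error(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angular_error(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angular_error(c(1, 0, 0), c(-1, 0, 0)), 180)
  # clamping guards the arccos domain against round-off
  expect_equal(angular_error(c(1, 0, 0), c(1 + 1e-16, 0, 0)), 0)
  a <- c(0.6, 0.8, 0); b <- c(0, 0.8, -0.6)
  expect_equal(angular_error(a, b), angular_error(b, a))
  expect_error(angular_error(c(2, 0, 0), c(1, 0, 0)), "unit")
})

test_that("field transfer is nodally exact and linear-exact", {
  m <- make_slab(1, 1, 1, 3, 3, 3, "tet")
  nv <- nrow(m$vertices)
  # constant field: same constant anywhere (partition of unity)
  const <- matrix(c(0, 0.6, 0.8), nv, 3, byrow = TRUE)
  set.seed(1)
  pts <- matrix(runif(3 * 40, 0.05, 0.95), ncol = 3)
  got <- transfer_field(m, const, pts)
  expect_lt(max(abs(sweep(got, 2, c(0, 0.6, 0.8)))), 1e-12)

  # at a node: that node's vector exactly
  f <- matrix(rnorm(nv * 3), nv, 3)
  f <- f / sqrt(rowSums(f^2))
  idx <- c(1, 17, nv)
  got2 <- transfer_field(m, f, m$vertices[idx, , drop = FALSE])
  expect_lt(max(abs(got2 - f[idx, ])), 1e-12)

  # linear vector field sampled at tet centroids equals the cell average
  lin <- cbind(m$vertices[, 1], 2 * m$vertices[, 2] - m$vertices[, 3],
               1 + m$vertices[, 3])
  cent <- (m$vertices[m$cells[, 1], ] + m$vertices[m$cells[, 2], ] +
           m$vertices[m$cells[, 3], ] + m$vertices[m$cells[, 4], ]) / 4
  got3 <- transfer_field(m, lin, cent[1:25, ], normalize = FALSE)
  exp3 <- cbind(cent[1:25, 1], 2 * cent[1:25, 2] - cent[1:25, 3],
                1 + cent[1:25, 3])
  expect_lt(max(abs(got3 - exp3)), 1e-12)

  expect_error(transfer_field(m, f, matrix(c(5, 5, 5), 1)), "outside")
})

test_that("hex transfer inverts the trilinear map", {
  m <- make_slab(1, 2, 1.5, 3, 3, 3, "hex")
  nv <- nrow(m$vertices)
  lin <- cbind(m$vertices[, 1] + m$vertices[, 2], m$vertices[, 3], 1 + 0 * m$vertices[, 1])
  set.seed(2)
  pts <- cbind(runif(30, 0.01, 0.99), runif(30, 0.01, 1.99), runif(30, 0.01, 1.49))
  got <- transfer_field(m, lin, pts, normalize = FALSE)
  expect_lt(max(abs(got - cbind(pts[, 1] + pts[, 2], pts[, 3], 1))), 1e-10)
})

test_that("self-comparison of a refinement family reports zero error", {
  m <- make_slab(0.024, 0.04, 0.04, 3, 3, 3, "hex")
  rep0 <- sensitivity_study(list(m, m), slab_cfg())
  # identical fields; the residual ~1e-6 degrees is the double-precision
  # floor of arccos near 1, not a field difference
  expect_lt(rep0$avg_deg[1], 1e-5)
  expect_lt(rep0$max_deg[1], 1e-5)
  expect_true(is.na(rep0$avg_deg[2]))
})

test_that("nested structured hex slabs agree to interpolation exactness", {
  # both levels resolve the linear potentials exactly and the fine vertices
  # sit at coarse nodes/midpoints, so any angular error is frame-logic error
  meshes <- list(make_slab(0.024, 0.04, 0.04, 2, 2, 2, "hex"),
                 make_slab(0.024, 0.04, 0.04, 4, 4, 4, "hex"))
  cfg <- slab_cfg()
  rep1 <- sensitivity_study(meshes, cfg)
  expect_lt(rep1$max_deg[1], 1e-5)
  # the vector-level statement is sharper than the angular one (which sits on
  # the arccos double-precision floor): the transferred coarse field equals
  # the fine nodal field componentwise
  coarse <- generate_fibers(meshes[[1]], cfg)
  fine <- generate_fibers(meshes[[2]], cfg)
  moved <- transfer_field(meshes[[1]], coarse$fields$vectors$f,
                          meshes[[2]]$vertices)
  expect_lt(max(abs(moved - fine$fields$vectors$f)), 1e-9)
})

test_that("the sensitivity report has the documented table structure", {
  meshes <- list(make_slab(0.024, 0.04, 0.04, 3, 4, 4, "tet"),
                 make_slab(0.024, 0.04, 0.04, 5, 7, 7, "tet"),
                 make_slab(0.024, 0.04, 0.04, 11, 15, 15, "tet"))
  rep2 <- sensitivity_study(meshes, slab_cfg())
  expect_s3_class(rep2, "sensitivity_report")
  expect_named(rep2, c("i", "h_mm", "dofs", "avg_deg", "max_deg"))
  expect_true(all(diff(rep2$h_mm) < 0))
  expect_true(all(rep2$avg_deg[1:2] >= 0))
  expect_true(all(rep2$avg_deg[1:2] <= rep2$max_deg[1:2]))
  expect_true(is.na(rep2$avg_deg[3]) && is.na(rep2$max_deg[3]))
  # errors decrease under refinement
  expect_lt(rep2$avg_deg[2], rep2$avg_deg[1])
  expect_lt(rep2$max_deg[2], rep2$max_deg[1])

  path <- tempfile(fileext = ".tsv")
  write_sensitivity_report(rep2, path)
  back <- utils::read.delim(path)
  expect_equal(back$avg_deg[1:2], rep2$avg_deg[1:2], tolerance = 1e-12)

  expect_error(sensitivity_study(list(meshes[[2]], meshes[[1]]), slab_cfg()),
               "decreasing")
})
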