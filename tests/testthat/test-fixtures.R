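# Programmatic labeled-mesh generators.

test_that("unit-cube slab has the expected counts and labels", {
  m <- make_slab(1, 1, 1, 1, 1, 1, "hex")
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$cells), 1)
  expect_equal(nrow(m$facets), 6)
  expect_setequal(m$label_set, 1:5)

  m2 <- make_slab(1, 1, 1, 2, 1, 1, "hex")
  expect_equal(nrow(m2$vertices), 12)
  expect_equal(nrow(m2$cells), 2)
  expect_equal(sum(m2$facet_labels == 1L), 1)  # endo face x = 0
  expect_equal(sum(m2$facet_labels == 2L), 1)  # epi face x = Lx
  # label placement
  endo_v <- m2$facets[m2$facet_labels == 1L, ]
  expect_true(all(m2$vertices[endo_v, 1] == 0))
  epi_v <- m2$facets[m2$facet_labels == 2L, ]
  expect_true(all(m2$vertices[epi_v, 1] == 1))
})

test_that("the hex-to-tet split conserves volume and conforms", {
  m <- make_slab(1, 1, 1, 1, 1, 1, "tet")
  expect_equal(nrow(m$cells), 6)
  expect_lt(abs(sum(cell_volumes(m)) - 1), 1e-12)
  m3 <- make_slab(0.5, 2, 1.5, 3, 2, 2, "tet")
  expect_lt(abs(sum(cell_volumes(m3)) - 0.5 * 2 * 1.5), 1e-12)
  expect_true(all(cell_volumes(m3) > 0))
})

test_that("slab generation is deterministic and labels partition the boundary", {
  a <- make_slab(0.024, 0.04, 0.04, 3, 4, 5, "tet")
  b <- make_slab(0.024, 0.04, 0.04, 3, 4, 5, "tet")
  expect_identical(a, b)
  # one label per boundary facet, and the facet count covers the whole boundary
  nxy <- 3 * 4; nxz <- 3 * 5; nyz <- 4 * 5
  expect_equal(nrow(a$facets), 2 * 2 * (nxy + nxz + nyz))  # 2 tris per quad
  expect_equal(length(a$facet_labels), nrow(a$facets))
})

test_that("spherical shell vertices stay between the radii and holes are labeled", {
  sh <- make_shell(1, 2, subdiv = 1, nr = 2)
  r <- sqrt(rowSums(sh$vertices^2))
  expect_true(all(r >= 1 - 1e-12 & r <= 2 + 1e-12))
  expect_setequal(sh$label_set, c(1L, 2L))
  expect_true(all(cell_volumes(sh) > 0))

  la <- la_fixture()
  labs <- attr(la, "labels")
  expect_setequal(names(labs), c("endo", "epi", "mv", "lpv", "rpv"))
  expect_setequal(la$label_set, unname(labs))

  expect_error(make_shell(1, 2, holes = list(
    a = list(dir = c(0, 0, 1), angle = 0.5),
    b = list(dir = c(0, 0.2, 1), angle = 0.5))), "overlap")
})

test_that("halving the shell edge length grows the vertex count 6-10x", {
  coarse <- make_shell(0.02, 0.03, subdiv = 1, nr = 2)
  fine <- make_shell(0.02, 0.03, subdiv = 2, nr = 4)
  ratio <- nrow(fine$vertices) / nrow(coarse$vertices)
  expect_gte(ratio, 6)
  expect_lte(ratio, 10)
  expect_lt(average_edge_length(fine) / average_edge_length(coarse), 0.65)
})

test_that("truncated-ellipsoid ventricle has a planar base and a reported apex", {
  # concentric spheres truncated at the equator
  lv <- make_lv(a_endo = 0.02, c_endo = 0.020001, a_epi = 0.03, c_epi = 0.030001,
                z_base = 0, n_s = 2, n_u = 6, n_v = 10)
  base_v <- unique(as.vector(lv$facets[lv$facet_labels == 3L, ]))
  expect_lt(max(abs(lv$vertices[base_v, 3])), 1e-10)

  epi_v <- unique(as.vector(lv$facets[lv$facet_labels == 2L, ]))
  apex <- attr(lv, "apex")
  expect_equal(min(lv$vertices[epi_v, 3]), apex[3])
  expect_equal(apex[3], -0.030001)

  # wall thickness along the equator ~ semi-axis difference
  endo_v <- unique(as.vector(lv$facets[lv$facet_labels == 1L, ]))
  eq_endo <- endo_v[abs(lv$vertices[endo_v, 3]) < 1e-6]
  eq_epi <- epi_v[abs(lv$vertices[epi_v, 3]) < 1e-6]
  thick <- min(sqrt(rowSums(lv$vertices[eq_epi, , drop = FALSE]^2))) -
    max(sqrt(rowSums(lv$vertices[eq_endo, , drop = FALSE]^2)))
  h <- average_edge_length(lv)
  expect_lt(abs(thick - 0.01), h)

  expect_true(all(cell_volumes(lv) > 0))
  expect_error(make_lv(z_base = 0.07), "truncation")
})

test_that("generated fixtures survive a .msh export/import cycle", {
  for (m in list(make_slab(0.02, 0.02, 0.02, 2, 2, 2, "hex"),
                 make_shell(0.01, 0.02, subdiv = 1, nr = 1),
                 make_lv(n_s = 2, n_u = 4, n_v = 6))) {
    f <- tempfile(fileext = ".msh")
    write_msh(m, f)
    m2 <- read_msh(f)
    expect_identical(m2$cells, m$cells)
    expect_identical(m2$facet_labels, m$facet_labels)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-15)
  }
})
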