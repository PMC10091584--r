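# Frame construction, normal-direction variants and axis rotations.

test_that("transmural direction on the slab is exact and antisymmetric in tags", {
  m <- make_slab(0.024, 0.04, 0.04, 3, 3, 3, "hex")
  tm <- transmural_direction(m, 1L, 2L)
  expect_lt(max(abs(tm$phi - m$vertices[, 1] / 0.024)), 1e-10)
  expect_lt(max(abs(tm$e_t - matrix(c(1, 0, 0), nrow(m$vertices), 3, byrow = TRUE))),
            1e-10)
  swapped <- transmural_direction(m, 2L, 1L)
  expect_lt(max(abs(swapped$phi - (1 - tm$phi))), 1e-10)
  expect_lt(max(abs(swapped$e_t + tm$e_t)), 1e-10)
})

test_that("transmural direction on the shell converges to the radial field", {
  errs <- vapply(1:2, function(lev) {
    sh <- make_shell(0.02, 0.03, subdiv = lev + 1, nr = 2^lev)
    tm <- transmural_direction(sh, 1L, 2L)
    radial <- sh$vertices / sqrt(rowSums(sh$vertices^2))
    max(angular_error(tm$e_t, radial))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 2)  # degrees, on the moderately refined level
})

test_that("normal-direction variants reduce to each other on the slab", {
  m <- make_slab(0.024, 0.04, 0.04, 3, 3, 3, "hex")
  Lz <- 0.04
  rl <- normal_rl(m, c(0, 0, 2))
  expect_identical(rl$k[1, ], c(0, 0, 2))
  expect_identical(rl$k, matrix(c(0, 0, 2), nrow(m$vertices), 3, byrow = TRUE))
  expect_error(normal_rl(m, c(0, 0, 0)), "nonzero")

  bt <- normal_bt(m, base_tags = 3L, apex_tags = 4L)
  expect_lt(max(abs(bt$psi - m$vertices[, 3] / Lz)), 1e-10)
  expect_lt(max(abs(sweep(bt$k, 2, c(0, 0, 1 / Lz)))), 1e-8)

  tm <- transmural_direction(m, 1L, 2L)
  fr_rl <- build_frame(tm$e_t, normal_rl(m, c(0, 0, 1))$k, m)
  fr_bt <- build_frame(tm$e_t, bt$k, m)
  expect_lt(max(abs(fr_rl$e_n - fr_bt$e_n)), 1e-10)
  expect_lt(max(abs(fr_rl$e_n - matrix(c(0, 0, 1), nrow(m$vertices), 3,
                                       byrow = TRUE))), 1e-10)
})

test_that("pole-constrained apico-basal potential respects its bounds on the shell", {
  sh <- make_shell(0.02, 0.03, subdiv = 2, nr = 2)
  nd <- normal_bt(sh, base_point = c(0, 0, 0.03), apex_point = c(0, 0, -0.03))
  expect_gte(min(nd$psi), -1e-8)
  expect_lte(max(nd$psi), 1 + 1e-8)
  north <- which.min(rowSums(sweep(sh$vertices, 2, c(0, 0, 0.03))^2))
  south <- which.min(rowSums(sweep(sh$vertices, 2, c(0, 0, -0.03))^2))
  expect_equal(nd$psi[north], 1)
  expect_equal(nd$psi[south], 0)
})

test_that("apex on the basal surface is rejected", {
  m <- make_slab(1, 1, 1, 2, 2, 2, "tet")
  expect_error(normal_bt(m, base_tags = 3L, apex_point = c(0.5, 0.5, 1)),
               "basal")
})

test_that("Doste blend is exact when the two ring potentials coincide", {
  # duplicate the top-face facets under a second label: the mitral and aortic
  # rings are then geometrically identical, psi_ab == psi_ot, and k must be
  # the common gradient regardless of w
  m <- make_slab(1, 1, 1, 2, 2, 2, "tet")
  top <- m$facet_labels == 3L
  m2 <- labeled_mesh(m$vertices, m$cells,
                     rbind(m$facets, m$facets[top, , drop = FALSE]),
                     c(m$facet_labels, rep(6L, sum(top))), "tet")
  nd <- normal_doste(m2, mv_tags = 3L, av_tags = 6L, apex_point = c(0.5, 0.5, 0))
  expect_identical(nd$psi_ab, nd$psi_ot)
  g <- fem_gradient(m2, nd$psi_ab)
  expect_lt(max(abs(nd$k - g)), 1e-14)
  expect_gte(min(nd$w), -1e-8)
  expect_lte(max(nd$w), 1 + 1e-8)
  # at a vertex with w = 1 (the mitral ring), k = grad(psi_ab) exactly
  mv_v <- m2$facets[m2$facet_labels == 3L, ][1]
  expect_equal(nd$w[mv_v], 1)
  expect_identical(nd$k[mv_v, ], g[mv_v, ])
  expect_error(normal_doste(m2, 3L, 3L, c(0.5, 0.5, 0)), "disjoint")
})

test_that("atrial bundle assignment is total, thresholded and degenerates to default", {
  la <- la_fixture()
  apex <- c(0, 0, 0.03)
  nd <- normal_atrial(la, 3L, 4L, 5L, apex,
                      taus = c(mv = 0.2, lpv = 0.15, rpv = 0.15))
  expect_false(anyNA(nd$bundle_id))
  expect_equal(length(nd$bundle_id), nrow(la$vertices))
  expect_true(all(levels(nd$bundle_id) == c("mv", "lpv", "rpv", "ab")))
  expect_true(all(table(nd$bundle_id) > 0))
  # the documented rule, replayed on the returned potentials
  expect_identical(unname(nd$bundle_id == "mv"), nd$psi_r > 1 - 0.2)
  lpv_expect <- nd$psi_v > 1 - 0.15 & !(nd$psi_r > 1 - 0.2)
  expect_identical(unname(nd$bundle_id == "lpv"), lpv_expect)

  nd0 <- normal_atrial(la, 3L, 4L, 5L, apex, taus = c(mv = 0, lpv = 0, rpv = 0))
  expect_true(all(nd0$bundle_id == "ab"))
  expect_identical(nd0$k, fem_gradient(la, nd0$psi_ab))
  expect_error(normal_atrial(la, 3L, 4L, 5L, apex,
                             taus = c(mv = -0.1, lpv = 0, rpv = 0)), "\\[0, 1\\]")
})

test_that("build_frame reproduces hand values and matrix-algebra invariants", {
  one <- function(v) matrix(v, 1, 3)
  fr <- build_frame(one(c(1, 0, 0)), one(c(0, 0, 1)))
  expect_equal(fr$e_n[1, ], c(0, 0, 1))
  expect_equal(fr$e_l[1, ], c(0, 1, 0))

  fr2 <- build_frame(one(c(1, 0, 0)), one(c(1, 0, 1)))
  expect_equal(fr2$e_n[1, ], c(0, 0, 1))

  set.seed(7)
  for (k in 1:20) {
    et <- rnorm(3); et <- et / sqrt(sum(et^2))
    kk <- rnorm(3)
    if (abs(sum(kk * et)) / sqrt(sum(kk^2)) > 0.99) next
    fr <- build_frame(one(et), one(kk))
    Q <- cbind(fr$e_l[1, ], fr$e_n[1, ], fr$e_t[1, ])
    expect_lt(max(abs(crossprod(Q) - diag(3))), 1e-12)
    expect_lt(abs(det(Q) - 1), 1e-12)
  }
  expect_error(build_frame(one(c(1, 0, 0)), one(c(2, 0, 0))),
               "parallel")
})

test_that("axis rotation follows the right-hand rule and the linear angle law", {
  one <- function(v) matrix(v, 1, 3)
  fr <- build_frame(one(c(1, 0, 0)), one(c(0, 0, 1)))
  # identity at alpha = beta = 0
  rot0 <- rotate_frame(fr, 0, list(alpha_endo = 0, alpha_epi = 0,
                                   beta_endo = 0, beta_epi = 0))
  expect_equal(rot0$f, fr$e_l)
  expect_equal(rot0$n, fr$e_n)
  expect_equal(rot0$s, fr$e_t)
  # e_l = (0,1,0) rotated +90 deg about e_t = (1,0,0) gives (0,0,1)
  rot90 <- rotate_frame(fr, 0, list(alpha_endo = 90, alpha_epi = 90,
                                    beta_endo = 0, beta_epi = 0))
  expect_lt(max(abs(rot90$f[1, ] - c(0, 0, 1))), 1e-12)

  # midpoint of the linear law: alpha(0.5) = 0 for -60/+60
  m <- make_slab(0.024, 0.04, 0.04, 2, 2, 2, "hex")
  res <- generate_fibers(m, slab_cfg())
  mid <- which(abs(res$phi - 0.5) < 1e-12)
  ang <- helical_angle(res$fields$vectors$f, res$frame)
  expect_lt(max(abs(ang[mid])), 1e-8)
  # endpoint values are attained exactly
  expect_lt(max(abs(ang[res$phi == 0] - (-60))), 1e-8)
  expect_lt(max(abs(ang[res$phi == 1] - 60)), 1e-8)
})

test_that("spherical slab produces tangential or radial fibers on demand", {
  sh <- make_shell(0.02, 0.03, subdiv = 2, nr = 2)
  base <- ldrbm_config("Slab", tags = list(endo = 1L, epi = 2L),
                       sphere_slab = TRUE,
                       north_pole = c(0, 0, 0.03), south_pole = c(0, 0, -0.03))
  tang <- generate_fibers(sh, base)
  expect_lt(max(abs(rowSums(tang$fields$vectors$f * tang$frame$e_t))), 1e-8)

  rad <- generate_fibers(sh, ldrbm_config("Slab", tags = list(endo = 1L, epi = 2L),
    sphere_slab = TRUE, sphere_radial_fibers = TRUE,
    north_pole = c(0, 0, 0.03), south_pole = c(0, 0, -0.03)))
  expect_lt(max(abs(abs(rowSums(rad$fields$vectors$f * rad$frame$e_t)) - 1)), 1e-8)
})

test_that("atrial runs return the unrotated frame as the fiber triad", {
  la <- la_fixture()
  cfg <- ldrbm_config("Left atrium", tags = list(endo = 1L, epi = 2L, mv = 3L,
                                                 lpv = 4L, rpv = 5L))
  res <- generate_fibers(la, cfg)
  expect_identical(res$fields$vectors$f, res$frame$e_l)
  expect_identical(res$fields$vectors$n, res$frame$e_n)
  expect_identical(res$fields$vectors$s, res$frame$e_t)
  expect_false(anyNA(res$bundle_id))
})

test_that("configuration errors name the offending parameter", {
  m <- make_slab(1, 1, 1, 2, 2, 2, "tet")
  expect_error(generate_fibers(m, ldrbm_config("Slab", tags = list(endo = 1L, epi = 2L))),
               "Tags base up")
  lv <- make_lv(n_s = 2, n_u = 4, n_v = 6)
  expect_error(generate_fibers(lv,
    ldrbm_config("Left ventricle", tags = list(endo = 1L, epi = 2L))),
    "Tags base")
  expect_error(generate_fibers(lv,
    ldrbm_config("Left ventricle", tags = list(endo = 1L, epi = 2L, base = 3L))),
    "Apex")
  expect_error(ldrbm_config("Left atrium", tags = list(endo = 1L, epi = 2L),
                            taus = c(mv = 2, lpv = 0, rpv = 0)),
               "Tau")
})
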