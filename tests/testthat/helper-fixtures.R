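# Shared fixtures and independent oracles for the test suite.

# hand-written minimal Gmsh 2.2 file: one unit tet, four labeled triangles
msh22_minimal <- function(path) {
  writeLines(c(
    "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
    "$Nodes", "4",
    "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
    "$EndNodes",
    "$Elements", "5",
    "1 2 2 10 1 1 3 2",
    "2 2 2 20 2 1 2 4",
    "3 2 2 30 3 2 3 4",
    "4 2 2 40 4 1 4 3",
    "5 4 2 0 1 1 2 3 4",
    "$EndElements"), path)
  path
}

# the same mesh in Gmsh 4.1 with physical tags attached through $Entities
msh41_minimal <- function(path) {
  writeLines(c(
    "$MeshFormat", "4.1 0 8", "$EndMeshFormat",
    "$Entities",
    "0 0 4 1",
    "1 0 0 0 1 1 1 1 10 0",
    "2 0 0 0 1 1 1 1 20 0",
    "3 0 0 0 1 1 1 1 30 0",
    "4 0 0 0 1 1 1 1 40 0",
    "1 0 0 0 1 1 1 0 0",
    "$EndEntities",
    "$Nodes",
    "1 4 1 4",
    "3 1 0 4",
    "1", "2", "3", "4",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "$EndNodes",
    "$Elements",
    "5 5 1 5",
    "2 1 2 1",
    "1 1 3 2",
    "2 2 2 1",
    "2 1 2 4",
    "2 3 2 1",
    "3 2 3 4",
    "2 4 2 1",
    "4 1 4 3",
    "3 1 4 1",
    "5 1 2 3 4",
    "$EndElements"), path)
  path
}

# independent P1 stiffness oracle: shape-function gradients from the inverse
# of the [1 | x y z] nodal matrix, entirely distinct from the package's
# vectorized cofactor assembly
oracle_stiffness_tet <- function(verts, tets) {
  n <- nrow(verts)
  K <- matrix(0, n, n)
  for (e in seq_len(nrow(tets))) {
    id <- tets[e, ]
    M <- cbind(1, verts[id, , drop = FALSE])
    C <- solve(M)
    vol <- abs(det(M)) / 6
    G <- C[2:4, , drop = FALSE]
    K[id, id] <- K[id, id] + vol * t(G) %*% G
  }
  K
}

expect_orthonormal_triad <- function(f, n, s, tol = 1e-8) {
  expect_lt(max(abs(sqrt(rowSums(f^2)) - 1)), tol)
  expect_lt(max(abs(sqrt(rowSums(n^2)) - 1)), tol)
  expect_lt(max(abs(sqrt(rowSums(s^2)) - 1)), tol)
  expect_lt(max(abs(rowSums(f * n))), tol)
  expect_lt(max(abs(rowSums(f * s))), tol)
  expect_lt(max(abs(rowSums(n * s))), tol)
  # right-handedness: f = n x s, i.e. det [f n s] = +1
  cr <- cbind(n[, 2] * s[, 3] - n[, 3] * s[, 2],
              n[, 3] * s[, 1] - n[, 1] * s[, 3],
              n[, 1] * s[, 2] - n[, 2] * s[, 1])
  expect_lt(max(abs(rowSums(cr * f) - 1)), tol)
}

slab_cfg <- function(...) {
  ldrbm_config("Slab",
               tags = list(endo = 1L, epi = 2L, base_up = 3L, base_down = 4L),
               ...)
}

# small left-atrium shell with mitral + two pulmonary-vein ring holes
la_fixture <- function(subdiv = 2L, nr = 2L) {
  make_shell(0.02, 0.03, subdiv = subdiv, nr = nr,
             holes = list(mv = list(dir = c(0, 0, -1), angle = 0.5),
                          lpv = list(dir = c(0.8, 0.3, 0.6), angle = 0.35),
                          rpv = list(dir = c(-0.8, -0.3, 0.6), angle = 0.35)))
}
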