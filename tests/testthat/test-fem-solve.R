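test_that("a single regular tet has a symmetric stiffness with 6 rigid modes", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 1e6  # um
  mesh <- structure(list(nodes = nodes, elems = matrix(1:4, 1),
                         region = "tissue",
                         volumes = 1e18 / 6, hex = 1L,
                         fixed_outer = integer(0), probe_top = integer(0)),
                    class = "tet_mesh")
  sys <- assemble_elasticity(mesh, list(tissue = list(young_modulus = 1,
                                                      poisson_ratio = 0)))
  K <- as.matrix(sys$K)
  expect_lt(max(abs(K - t(K))), 1e-15)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < max(ev) * 1e-10), 6)   # rigid-body null space
  expect_true(all(ev > -max(ev) * 1e-10))           # positive semidefinite

  # stiffness is linear in the Young's modulus
  sys2 <- assemble_elasticity(mesh, list(tissue = list(young_modulus = 2,
                                                       poisson_ratio = 0)))
  expect_equal(as.matrix(sys2$K), 2 * K)
})

test_that("the patch test reproduces a constant strain field exactly", {
  fx <- box_fixture(l = 100, n = 3, E = 6e3, nu = 0.43)
  bnd <- boundary_nodes(fx$mesh, 100)
  cons <- tibble::tibble(node = rep(bnd, each = 3),
                         dof = rep(1:3, length(bnd)),
                         value = as.vector(rbind(0.001 * fx$mesh$nodes[bnd, 1],
                                                 0, 0)))
  u <- solve_displacements(apply_boundary_conditions(fx$sys, fx$mesh,
                                                     constraints = cons))
  eps <- compute_element_strains(fx$mesh, u)
  expect_lt(max(abs(eps[, "exx"] - 0.001)) / 0.001, 1e-10)
  expect_lt(max(abs(eps[, c("eyy", "ezz", "gxy", "gyz", "gzx")])), 1e-13)
})

test_that("rigid-body motion produces zero strain", {
  fx <- box_fixture(l = 50, n = 2)
  bnd <- boundary_nodes(fx$mesh, 50)
  cons <- tibble::tibble(node = rep(bnd, each = 3),
                         dof = rep(1:3, length(bnd)),
                         value = rep(c(5, -3, 2), length(bnd)))
  u <- solve_displacements(apply_boundary_conditions(fx$sys, fx$mesh,
                                                     constraints = cons))
  eps <- compute_element_strains(fx$mesh, u)
  expect_lt(max(abs(eps)), 1e-12)
  # every node shares the imposed translation
  expect_lt(max(abs(sweep(u / 1e-6, 2, c(5, -3, 2)))), 1e-9)

  # small rotation about z: linearized strain vanishes
  th <- 1e-6
  rot <- cbind(-th * fx$mesh$nodes[bnd, 2], th * fx$mesh$nodes[bnd, 1], 0)
  cons2 <- tibble::tibble(node = rep(bnd, each = 3),
                          dof = rep(1:3, length(bnd)),
                          value = as.vector(t(rot)))
  u2 <- solve_displacements(apply_boundary_conditions(fx$sys, fx$mesh,
                                                      constraints = cons2))
  eps2 <- compute_element_strains(fx$mesh, u2)
  expect_lt(max(abs(eps2)), 1e-12)
})

test_that("a uniaxial bar matches the closed-form stretch solution", {
  L <- 200
  mesh <- mesh_box(50, 50, L, 2, 2, 6)
  sys <- assemble_elasticity(mesh, list(tissue = list(young_modulus = 6e3,
                                                      poisson_ratio = 0.3)))
  tol <- 1e-9
  bot <- which(mesh$nodes[, 3] < tol)
  top <- which(mesh$nodes[, 3] > L - tol)
  delta <- 2   # um -> ezz = 0.01
  cons <- dplyr::bind_rows(
    tibble::tibble(node = bot, dof = 3L, value = 0),
    tibble::tibble(node = top, dof = 3L, value = delta))
  ctr <- which(abs(mesh$nodes[, 1] - 25) < tol &
               abs(mesh$nodes[, 2] - 25) < tol & mesh$nodes[, 3] < tol)
  edge <- which(abs(mesh$nodes[, 1] - 50) < tol &
                abs(mesh$nodes[, 2] - 25) < tol & mesh$nodes[, 3] < tol)
  cons <- dplyr::bind_rows(cons,
    tibble::tibble(node = ctr, dof = 1L, value = 0),
    tibble::tibble(node = ctr, dof = 2L, value = 0),
    tibble::tibble(node = edge, dof = 2L, value = 0))
  u <- solve_displacements(apply_boundary_conditions(sys, mesh,
                                                     constraints = cons))
  eps <- compute_element_strains(mesh, u)
  target <- delta / L
  expect_lt(max(abs(eps[, "ezz"] - target)) / target, 0.01)
  expect_lt(max(abs(eps[, "exx"] + 0.3 * target)) / target, 0.01)

  # interior axial displacement is linear in z
  uz <- u[, 3] / 1e-6
  expect_lt(max(abs(uz - delta * mesh$nodes[, 3] / L)), delta * 1e-8)

  # von Mises equals the axial strain for the uniaxial-stress state
  pr <- principal_strains(eps)
  vm <- von_mises_strain(pr[, 1], pr[, 2], pr[, 3], 0.3)
  expect_lt(max(abs(vm - target)) / target, 0.01)
})

test_that("solutions satisfy constraints exactly and scale linearly", {
  model <- build_model_geometry(fem_config("mouse"))
  mesh <- generate_mesh(model, coarse_size = 800, fine_size = 250)
  sys <- assemble_elasticity(mesh, list(
    tissue = model$tissue[c("young_modulus", "poisson_ratio")],
    probe = model$probe[c("young_modulus", "poisson_ratio")]))

  u0 <- solve_displacements(apply_boundary_conditions(sys, mesh,
                                                      displacement = 0))
  expect_lt(max(abs(u0)), 1e-18)

  u20 <- solve_displacements(apply_boundary_conditions(sys, mesh,
                                                       displacement = 20))
  expect_equal(max(abs(u20[mesh$fixed_outer, ])), 0)
  expect_equal(unique(u20[mesh$probe_top, 1]), 20e-6)
  expect_equal(max(abs(u20[mesh$probe_top, 2:3])), 0)

  u40 <- solve_displacements(apply_boundary_conditions(sys, mesh,
                                                       displacement = 40))
  expect_lt(max(abs(u40 - 2 * u20)), 1e-12)

  # x-only prescription leaves the probe top free vertically
  ux <- solve_displacements(apply_boundary_conditions(sys, mesh,
                                                      displacement = 20,
                                                      pin_lateral = FALSE))
  expect_equal(unique(ux[mesh$probe_top, 1]), 20e-6)
  expect_gt(max(abs(ux[mesh$probe_top, 3])), 0)
})

test_that("degenerate meshes and empty boundary sets are rejected", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0)) * 1e6
  flat <- structure(list(nodes = nodes, elems = matrix(1:4, 1),
                         region = "tissue", volumes = 0, hex = 1L,
                         fixed_outer = integer(0), probe_top = integer(0)),
                    class = "tet_mesh")
  expect_error(assemble_elasticity(flat, list(tissue = list(young_modulus = 1,
                                                            poisson_ratio = 0))),
               class = "imetk_assembly_error")

  fx <- box_fixture(l = 50, n = 2)
  expect_error(apply_boundary_conditions(fx$sys, fx$mesh, displacement = 20),
               class = "imetk_configuration_error")
})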