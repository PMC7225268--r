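test_that("species geometry matches the model parameter table", {
  rat <- build_model_geometry(fem_config("rat"))
  expect_equal(c(rat$tissue$x_extent, rat$tissue$y_extent, rat$tissue$depth),
               c(5000, 5000, 2500))
  expect_equal(rat$probe$insertion_depth, 2000)
  expect_equal(rat$probe$taper_length, 1500)

  mouse <- build_model_geometry(fem_config("mouse"))
  expect_equal(mouse$tissue$depth, 1250)
  expect_equal(mouse$probe$insertion_depth, 1000)
  expect_equal(mouse$probe$taper_length, 750)
  expect_equal(mouse$probe$young_modulus, 200e9)
  expect_equal(mouse$tissue$young_modulus, 6e3)

  bad <- fem_config("rat")
  bad$probe$insertion_depth <- 3000
  expect_error(build_model_geometry(bad), class = "imetk_invalid_parameter")
  bad2 <- fem_config("rat")
  bad2$probe$min_width <- 200
  expect_error(build_model_geometry(bad2), class = "imetk_invalid_parameter")
})

test_that("the shank width profile is constant, tapering, then pointed", {
  m <- build_model_geometry(fem_config("rat"))
  expect_equal(probe_halfwidth(m, 0), 123 / 2)
  expect_equal(probe_halfwidth(m, 450), 123 / 2)          # end of constant run
  expect_equal(probe_halfwidth(m, 450 + 750), (123 + 33) / 4)  # taper midpoint
  expect_equal(probe_halfwidth(m, 1950), 33 / 2)          # start of tip
  expect_equal(probe_halfwidth(m, 1975), 33 / 4)
  expect_equal(probe_halfwidth(m, 2000), 0)
  expect_equal(probe_halfwidth(m, 2400), 0)               # below the tip
})

test_that("bundled JSON configs reproduce the built-in parameters", {
  rat_json <- read_fem_config(system.file("extdata", "rat.json",
                                          package = "imetk"))
  expect_equal(rat_json$probe$insertion_depth,
               fem_config("rat")$probe$insertion_depth)
  expect_equal(rat_json$tissue$poisson_ratio, 0.43)
  m <- build_model_geometry(rat_json)
  expect_s3_class(m, "fem_model")
})

test_that("meshes conserve volume, refine monotonically, and are deterministic", {
  model <- build_model_geometry(fem_config("mouse"))
  mesh <- generate_mesh(model, coarse_size = 600, fine_size = 200)
  expect_true(all(mesh$volumes > 0))
  block <- 5000 * 5000 * 1250
  expect_lt(abs(sum(mesh$volumes) - block) / block, 1e-9)

  finer <- generate_mesh(model, coarse_size = 600, fine_size = 100)
  expect_gt(nrow(finer$elems), nrow(mesh$elems))

  again <- generate_mesh(model, coarse_size = 600, fine_size = 200, seed = 42)
  expect_identical(mesh$nodes, again$nodes)
  expect_identical(mesh$elems, again$elems)

  expect_error(generate_mesh(model, coarse_size = 100, fine_size = 200),
               class = "imetk_invalid_parameter")
})

test_that("mesh regions and boundary sets respect the model geometry", {
  model <- build_model_geometry(fem_config("mouse"))
  mesh <- generate_mesh(model, coarse_size = 600, fine_size = 200)
  expect_setequal(unique(mesh$region), c("tissue", "probe"))

  cen <- element_centroids(mesh)
  probe <- mesh$region == "probe"
  expect_true(all(abs(cen[probe, 2]) < model$probe$thickness / 2))
  expect_true(all(cen[probe, 3] < model$probe$insertion_depth))

  # probe volume close to the exact prism volume of the tapered shank
  p <- model$probe
  const_len <- p$insertion_depth - p$taper_length - p$tip_length
  exact <- p$thickness * (p$max_width * const_len +
    (p$max_width + p$min_width) / 2 * p$taper_length +
    p$min_width / 2 * p$tip_length)
  expect_lt(abs(sum(mesh$volumes[probe]) - exact) / exact, 0.25)

  # fixed outer nodes lie on the sides or the bottom, none at the top center
  fo <- mesh$nodes[mesh$fixed_outer, , drop = FALSE]
  expect_true(all(abs(fo[, 1]) > 2499 | abs(fo[, 2]) > 2499 |
                  fo[, 3] > 1249))
  # probe-top nodes sit on the brain surface inside the shank footprint
  pt <- mesh$nodes[mesh$probe_top, , drop = FALSE]
  expect_true(all(pt[, 3] == 0))
  expect_true(all(abs(pt[, 1]) <= p$max_width / 2 + 1e-9))
})

test_that("the mesh is exactly mirror-symmetric about the probe's XZ plane", {
  model <- build_model_geometry(fem_config("mouse"))
  mesh <- generate_mesh(model, coarse_size = 600, fine_size = 200)
  key <- function(M) paste(round(M[, 1], 6), round(M[, 2], 6),
                           round(M[, 3], 6))
  nodes_m <- mesh$nodes; nodes_m[, 2] <- -nodes_m[, 2]
  expect_setequal(key(mesh$nodes), key(nodes_m))
  # element centroid multiset is mirror-invariant too (split included)
  cen <- element_centroids(mesh)
  cen_m <- cen; cen_m[, 2] <- -cen_m[, 2]
  expect_setequal(key(cen), key(cen_m))
})

test_that("box fixture meshes tile the box exactly", {
  b <- mesh_box(10, 20, 30, 2, 3, 4)
  expect_equal(sum(b$volumes), 10 * 20 * 30)
  expect_equal(nrow(b$elems), 2 * 3 * 4 * 6)
  expect_true(all(b$volumes > 0))
})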