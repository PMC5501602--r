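test_that("uniform translation gives zero shear stress everywhere", {
  g <- tube_grid(radius = 1e-3, length = 4e-3, spacing = 1e-4)
  sol <- uniform_flow_solution(g, u_const = 0, w_const = 2e-3)
  tau <- shear_stress(sol)$tau
  # cells away from the no-slip ghost boundaries see a strictly uniform field
  interior <- tau[2:(g$nr - 1L), 2:(g$nz - 1L)]
  expect_equal(max(abs(interior)), 0)
})

test_that("simple shear u_z = G r gives tau = mu G", {
  g <- tube_grid(radius = 2e-3, length = 4e-3, spacing = 1e-4)
  G <- 10
  sol <- uniform_flow_solution(g)
  sol$W <- matrix(G * g$r_centers, g$nr, g$nz + 1L)
  mu <- 6.91e-4
  tau <- shear_stress(sol, mu = mu)$tau
  interior <- tau[2:(g$nr - 1L), 2:(g$nz - 1L)]
  expect_equal(unname(interior[5, 5]), mu * G, tolerance = 1e-12)
  expect_lt(max(abs(interior - mu * G)) / (mu * G), 1e-10)
})

test_that("shear stress scales linearly with viscosity and inlet velocity (Stokes)", {
  geom <- build_geometry()
  grid <- rasterize(geom, 200e-6)
  s1 <- solve_flow(grid, bc = flow_bc(v = 1e-3, tube_radius = geom$tube_radius),
                   include_inertia = FALSE)
  s61 <- solve_flow(grid, bc = flow_bc(v = 61e-3, tube_radius = geom$tube_radius),
                    include_inertia = FALSE)
  t1 <- shear_stress(s1); t61 <- shear_stress(s61)
  m1 <- max_in_region(t1, "porous"); m61 <- max_in_region(t61, "porous")
  expect_lt(abs(m61 - 61 * m1) / m61, 1e-10)
  # viscosity scaling on the same solution
  t2 <- shear_stress(s1, mu = 2 * 6.91e-4)
  expect_equal(max_in_region(t2, "porous"), 2 * m1, tolerance = 1e-12)
})

test_that("cross-section maxima are bounded by the whole-region maximum", {
  geom <- build_geometry()
  grid <- rasterize(geom, 200e-6)
  sol <- solve_flow(grid, bc = flow_bc(v = 1e-3, tube_radius = geom$tube_radius),
                    include_inertia = FALSE)
  tau <- shear_stress(sol)
  expect_lte(max_in_region(tau, "porous", "horizontal-mid"),
             max_in_region(tau, "porous"))
  expect_equal(max_in_region(tau, "porous", "vertical-mid"),
               max_in_region(tau, "porous"))
})

test_that("revolution reproduces constant fields, nodes, and axisymmetry", {
  geom <- build_geometry()
  grid <- rasterize(geom, 200e-6)
  sol <- solve_flow(grid, bc = flow_bc(v = 1e-3, tube_radius = geom$tube_radius),
                    include_inertia = FALSE)
  field <- shear_stress(sol)

  # constant field -> constant volume on valid voxels
  cfield <- field
  cfield$tau[grid$label != label_outside()] <- 3.5e-3
  vs <- 150e-6
  nxy <- as.integer(ceiling(2 * geom$scaffold_radius / vs))
  nzv <- as.integer(ceiling(geom$scaffold_height / vs))
  smp <- revolve_to_voxels(cfield, vs, c(nxy, nxy, nzv),
                           axis_xy = c(nxy, nxy) / 2 * vs,
                           z_offset = -geom$z_sections[["scaffold"]])
  expect_true(any(smp$valid))
  expect_equal(max(abs(smp$tau[smp$valid] - 3.5e-3)), 0, tolerance = 1e-15)

  # a voxel centred on a grid node reproduces the nodal value exactly
  i <- 10L; j <- 80L   # a cell-centre node inside the scaffold
  vs2 <- grid$dr
  smp2 <- revolve_to_voxels(field, vs2, c(3L, 3L, 3L),
                            origin = c(grid$r_centers[i] - 1.5 * vs2,
                                       -0.5 * vs2,
                                       grid$z_centers[j] - 1.5 * vs2),
                            axis_xy = c(0, 0))
  expect_equal(smp2$tau[2, 1, 2], field$tau[i, j], tolerance = 1e-12)

  # rotational symmetry: lattice-mirror voxels share a radius, hence tau
  nv <- as.integer(ceiling(2 * geom$scaffold_radius / vs))
  smp3 <- revolve_to_voxels(field, vs, c(nv, nv, 4L),
                            axis_xy = c(nv, nv) / 2 * vs,
                            z_offset = -geom$z_sections[["scaffold"]] - 1e-3)
  k <- 2L
  for (ij in list(c(10L, 20L), c(18L, 30L), c(25L, 25L))) {
    i <- ij[1]; j <- ij[2]
    mirrors <- rbind(c(i, j), c(nv + 1L - i, j), c(i, nv + 1L - j),
                     c(j, i), c(nv + 1L - j, nv + 1L - i))
    expect_true(all(smp3$valid[cbind(mirrors, k)]))
    vals <- smp3$tau[cbind(mirrors, k)]
    expect_lt(diff(range(vals)), 1e-9 * max(abs(vals), 1e-12))
  }

  # min/max preservation: no overshoot beyond nodal extremes
  expect_gte(min(smp3$tau[smp3$valid]), min(field$tau, na.rm = TRUE) - 1e-15)
  expect_lte(max(smp3$tau[smp3$valid]), max(field$tau, na.rm = TRUE) + 1e-15)
})

test_that("degenerate stress queries fail loudly", {
  g <- tube_grid(radius = 1e-3, length = 4e-3, spacing = 2e-4)
  sol <- uniform_flow_solution(g)
  field <- shear_stress(sol)
  expect_error(max_in_region(field, "porous"), "empty")
  expect_error(revolve_to_voxels(field, 1e-4, c(4L, 4L, 4L),
                                 origin = c(1, 1, 1)), "outside")
  sol$converged <- FALSE
  expect_error(shear_stress(sol), "not converged")
})
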