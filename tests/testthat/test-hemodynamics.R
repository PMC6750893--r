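test_that("plasma resistance follows the Poiseuille closed form and scalings", {
  # 128 * mu * L / (pi D^4) evaluated independently at high precision
  expect_equal(plasma_resistance(100e-6, 8e-6, 1.2e-3),
               128 * 1.2e-3 * 100e-6 / (pi * (8e-6)^4), tolerance = 1e-12)
  expect_equal(plasma_resistance(100e-6, 8e-6, 1.2e-3) / 1e15, 1.1937,
               tolerance = 1e-4)
  r <- plasma_resistance(50e-6, 5e-6)
  expect_equal(plasma_resistance(50e-6, 10e-6), r / 16, tolerance = 1e-12)
  expect_equal(plasma_resistance(100e-6, 5e-6), r * 2, tolerance = 1e-12)
  expect_error(plasma_resistance(0, 5e-6), "positive")
})

test_that("viscosity law: plasma limit, diameter minimum, hematocrit monotone", {
  d_grid <- c(3, 5, 7, 10, 20, 50, 100, 300)
  expect_equal(relative_apparent_viscosity(d_grid, 0), rep(1, length(d_grid)))
  # the law's minimum sits near 7 um, not at the largest diameter
  expect_lt(relative_apparent_viscosity(7, 0.45),
            relative_apparent_viscosity(50, 0.45))
  expect_false(relative_apparent_viscosity(10, 0.45) >
               relative_apparent_viscosity(100, 0.45))
  # strictly increasing in H_d at fixed D, and >= 1 up to H_d = 0.6
  for (d in c(4, 6, 10, 40)) {
    h <- seq(0, 0.6, by = 0.05)
    eta <- relative_apparent_viscosity(d, h)
    expect_true(all(diff(eta) > 0), info = paste("D =", d))
    expect_true(all(eta >= 1))
  }
  expect_error(relative_apparent_viscosity(6, 1.2), "hematocrit")
})

test_that("effective resistance factorizes into plasma part times viscosity ratio", {
  expect_equal(effective_resistance(100e-6, 8e-6, 0),
               plasma_resistance(100e-6, 8e-6), tolerance = 1e-14)
  expect_equal(effective_resistance(100e-6, 8e-6, 0.45),
               plasma_resistance(100e-6, 8e-6) *
                 relative_apparent_viscosity(8, 0.45), tolerance = 1e-14)
  expect_gte(effective_resistance(70e-6, 5e-6, 0.2),
             plasma_resistance(70e-6, 5e-6))
})

test_that("Fahraeus relation: fixed points, large-vessel limit, exact inverse", {
  expect_equal(tube_from_discharge(8, 0), 0)
  expect_equal(tube_from_discharge(8, 1), 1)
  expect_equal(tube_from_discharge(1000, 0.45), 0.45, tolerance = 1e-3)
  h_t <- tube_from_discharge(8, 0.3)
  expect_lt(h_t, 0.3)
  expect_equal(discharge_from_tube(8, h_t), 0.3, tolerance = 1e-10)
  # round trip across the (D, H) plane, against a bisection oracle
  for (d in c(2.2, 3, 5, 8, 15, 40)) {
    for (h in c(0.05, 0.2, 0.45, 0.7, 0.95)) {
      ht <- tube_from_discharge(d, h)
      expect_lte(ht, h + 1e-12)
      expect_equal(discharge_from_tube(d, ht), h, tolerance = 1e-10)
      root <- uniroot(function(x) tube_from_discharge(d, x) - ht,
                      c(0, 1), tol = 1e-13)$root
      expect_equal(discharge_from_tube(d, ht), root, tolerance = 1e-8)
    }
  }
  expect_error(tube_from_discharge(8, 1.2), "hematocrit")
})

test_that("pressure solve matches symmetry cases and conserves mass", {
  # equal-resistance path: midpoint pressure is the average
  g <- path_graph(p_a_mmHg = 1 / 133.322, p_c_mmHg = 0)
  fl <- solve_pressures(g, rep(1e15, 2))
  expect_equal(fl$p_pa[2], 0.5, tolerance = 1e-12)
  # symmetric Y: daughters split the mother flow exactly in half
  gy <- generate_toy_bifurcation(8, 8, 8, p_out1_mmHg = 29.85, p_out2_mmHg = 29.85)
  re <- effective_resistance(gy$vessels$length_um * 1e-6,
                             gy$vessels$diameter_um * 1e-6, 0)
  fy <- solve_pressures(gy, re)
  expect_equal(fy$q[2], fy$q[3], tolerance = 1e-12)
  expect_equal(fy$q[2] + fy$q[3], fy$q[1], tolerance = 1e-12)
  # unequal daughters under pure plasma: flows proportional to D^4
  gz <- generate_toy_bifurcation(8, 6, 4, p_out1_mmHg = 29.8, p_out2_mmHg = 29.8)
  rz <- effective_resistance(gz$vessels$length_um * 1e-6,
                             gz$vessels$diameter_um * 1e-6, 0)
  fz <- solve_pressures(gz, rz)
  expect_equal(fz$q[2] / fz$q[3], (6 / 4)^4, tolerance = 1e-12)
})

test_that("pressures agree with a dense-matrix oracle on random graphs", {
  for (seed in 1:25) {
    rg <- random_solver_graph(seed)
    fl <- solve_pressures(rg$g, rg$r)
    oracle <- dense_solve_oracle(rg$g, rg$r)
    expect_equal(fl$p_pa, as.numeric(oracle), tolerance = 1e-10)
    # interior mass balance
    gi <- capflow:::graph_index(rg$g)
    net <- rep(0, gi$n_nodes)
    for (e in seq_len(gi$n_vessels)) {
      net[gi$ifrom[e]] <- net[gi$ifrom[e]] - fl$q[e]
      net[gi$ito[e]] <- net[gi$ito[e]] + fl$q[e]
    }
    scale <- max(abs(fl$q))
    expect_lt(max(abs(net[!gi$is_boundary])), 1e-10 * scale)
    # imposed boundary pressures are exact
    expect_equal(fl$p_pa[gi$is_boundary],
                 rg$g$nodes$boundary_pressure_pa[gi$is_boundary])
  }
})

test_that("an isolated component without boundary raises a topology error", {
  g <- path_graph()
  expect_error(solve_pressures(g, c(1e15, -2)), "finite positive")
  nd <- g$nodes; nd$is_boundary <- FALSE; nd$boundary_pressure_pa <- NA
  vs <- g$vessels
  expect_error(vascular_graph(nd, vs), "degree")
})

test_that("dilating one vessel never decreases its own flow (monotonicity)", {
  for (seed in 1:10) {
    rg <- random_solver_graph(seed + 100)
    fl <- solve_pressures(rg$g, rg$r)
    e <- which.max(abs(fl$q))
    r2 <- rg$r
    r2[e] <- r2[e] / 1.1^4 # diameter increase by 10 %
    fl2 <- solve_pressures(rg$g, r2)
    expect_gte(abs(fl2$q[e]) + 1e-16, abs(fl$q[e]))
  }
})

test_that("uniform whole-vessel dilation scales flow by f^4 under pure plasma", {
  g <- path_graph(p_a_mmHg = 50, p_c_mmHg = 10, d_um = 5)
  r1 <- plasma_resistance(g$vessels$length_um * 1e-6,
                          g$vessels$diameter_um * 1e-6)
  r2 <- plasma_resistance(g$vessels$length_um * 1e-6,
                          g$vessels$diameter_um * 1.1 * 1e-6)
  q1 <- solve_pressures(g, r1)$q[1]
  q2 <- solve_pressures(g, r2)$q[1]
  expect_equal(q2 / q1, 1.1^4, tolerance = 1e-12)
  expect_equal(1.1^4, 1.4641, tolerance = 1e-12)
})
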