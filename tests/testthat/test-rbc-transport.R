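test_that("RBC velocity honours the Fahraeus factor per variant", {
  expect_equal(rbc_velocity(1, 0.3, 0.3, "with_rbcs"), 1)
  expect_equal(rbc_velocity(2, 0.1, 0.1, "passive_particles"), 2)
  h_t <- tube_from_discharge(8, 0.3)
  v <- rbc_velocity(1, h_t, 0.3, "with_rbcs")
  expect_equal(v, 0.3 / h_t, tolerance = 1e-12)
  expect_gt(v, 1)
  # never below the bulk velocity
  expect_gte(rbc_velocity(1, 0.5, 0.4, "no_phase_separation"), 1)
})

test_that("phase-separation law: symmetry, skimming threshold, complement rule", {
  expect_equal(pries_split_fraction(0.5, 20, 14, 14, 0.45), 0.5, tolerance = 1e-12)
  # below the plasma-skimming threshold X0 no RBCs enter
  x0 <- 0.964 * (1 - 0.45) / 20
  expect_equal(pries_split_fraction(x0 * 0.9, 20, 14, 14, 0.45), 0)
  expect_equal(pries_split_fraction(1 - x0 * 0.9, 20, 14, 14, 0.45), 1)
  # published-coefficient evaluation at an asymmetric operating point
  fqe <- pries_split_fraction(0.7, 20, 14, 14, 0.45)
  expect_gt(fqe, 0.7)
  b <- 1 + 6.98 * 0.55 / 20
  x <- (0.7 - x0) / (1 - 2 * x0)
  expect_equal(fqe, stats::plogis(b * stats::qlogis(x)), tolerance = 1e-12)
  # swapped-daughter complement: FQE(FQB) + FQE'(1 - FQB) = 1
  for (fqb in c(0.2, 0.45, 0.6, 0.8)) {
    a <- pries_split_fraction(fqb, 18, 12, 15, 0.4)
    b2 <- pries_split_fraction(1 - fqb, 18, 15, 12, 0.4)
    expect_equal(a + b2, 1, tolerance = 1e-12)
  }
  # maps [0,1] to [0,1]
  f <- pries_split_fraction(seq(0, 1, 0.05), 12, 8, 9, 0.3)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("bifurcation rule picks the larger pressure force, with tie and blocking contracts", {
  expect_equal(bifurcation_rule_choice(c(2, 1)), 1L)
  expect_equal(bifurcation_rule_choice(c(1, 2)), 2L)
  # exact tie: reproducible fair coin
  set.seed(42)
  draws <- replicate(400, bifurcation_rule_choice(c(1, 1)))
  expect_true(all(draws %in% 1:2))
  expect_gt(mean(draws == 1), 0.4)
  expect_lt(mean(draws == 1), 0.6)
  set.seed(42)
  expect_identical(replicate(20, bifurcation_rule_choice(c(1, 1))), draws[1:20])
  # preferred daughter blocked -> the other; both blocked -> no entry
  expect_equal(bifurcation_rule_choice(c(2, 1), blocked = c(TRUE, FALSE)), 2L)
  expect_equal(bifurcation_rule_choice(c(2, 1), blocked = c(TRUE, TRUE)), 0L)
  # a daughter with reversed (negative) force is excluded
  expect_equal(bifurcation_rule_choice(c(-1, 0.5)), 2L)
})

test_that("advection kinematics: unblocked motion and the jam spacing contract", {
  g <- path_graph(p_a_mmHg = 30.45, p_c_mmHg = 30, d_um = 8)
  re <- effective_resistance(g$vessels$length_um * 1e-6,
                             g$vessels$diameter_um * 1e-6, 0)
  fl <- solve_pressures(g, re)
  gi <- capflow:::graph_index(g, 49)
  v_bulk_um <- abs(fl$v[1]) / 1e-6
  st <- rbc_state(vessel = c(1L, 1L), s_um = c(30, 10))
  out <- advance_rbcs(st, g, fl, 1e-3, "passive_particles")
  expect_equal(sort(out$s), sort(c(30, 10) + v_bulk_um * 1e-3), tolerance = 1e-9)
  # follower at exact spacing behind a stalled leader does not advance
  l_rbc <- gi$l_rbc[1]
  fl0 <- fl; fl0$q[] <- 0; fl0$v[] <- 0
  st2 <- rbc_state(vessel = c(1L, 1L), s_um = c(60, 60 - l_rbc))
  out2 <- advance_rbcs(st2, g, fl0, 1e-3, "with_rbcs")
  expect_equal(sort(out2$s), sort(st2$s))
  # follower approaching a stalled leader stops at one RBC length
  st3 <- rbc_state(vessel = 1L, s_um = 99.9) # nearly at the node, dead-end flow
  fl3 <- fl; fl3$q[2] <- 0; fl3$v[2] <- 0
  out3 <- advance_rbcs(st3, g, fl3, 1e-3, "with_rbcs")
  expect_gte(attr(out3, "min_slack"), -1e-9)
})

test_that("passive particles split like the bulk flow (binomial oracle)", {
  # dilute 70/30 split (routing statistics without traffic-jam interference)
  g <- generate_toy_bifurcation(8, 8, 8, p_in_mmHg = 31.5,
                                p_out1_mmHg = 28.95, p_out2_mmHg = 29.55)
  cf <- sim_config(seed = 5, variant = "passive_particles", h_in = 0.05,
                   t_warmup_s = 0.5, t_avg_s = 8)
  s <- run_simulation(g, cf)
  flux <- s$field$flux_mean
  routed <- (flux[2] + flux[3]) * s$t_avg_s
  expect_gt(routed, 1000) # enough routed cells for the binomial check
  frac <- flux[2] / (flux[2] + flux[3])
  se <- sqrt(0.7 * 0.3 / routed)
  expect_lt(abs(frac - 0.7), 2 * se)
})

test_that("injection meets the target flux and defers when blocked", {
  g <- path_graph(p_a_mmHg = 30.45, p_c_mmHg = 30, d_um = 8)
  re <- effective_resistance(g$vessels$length_um * 1e-6,
                             g$vessels$diameter_um * 1e-6, 0)
  fl <- solve_pressures(g, re)
  # H_in = 0 -> never any insertion
  st <- rbc_state()
  out <- inject_inflow_rbcs(st, g, fl, 1e-3, h_in = 0)
  expect_equal(length(out$vessel), 0)
  # expected long-run rate: q * H_in / V_RBC
  q_um3_s <- abs(fl$q[1]) * 1e18
  rate <- q_um3_s * 0.3 / 49
  acc <- NULL; st <- rbc_state()
  n_steps <- 5000
  for (i in seq_len(n_steps)) {
    st <- inject_inflow_rbcs(st, g, fl, 1e-3, h_in = 0.3, acc = acc)
    acc <- attr(st, "acc")
    st$vessel <- st$vessel[0]; st$s <- st$s[0]; st$id <- st$id[0] # drain
  }
  expect_equal(st$injected / (n_steps * 1e-3), rate, tolerance = 0.01)
  # a blocked inlet carries the deficit forward
  stb <- rbc_state(vessel = 1L, s_um = 0.1) # entrance occupied
  stb2 <- inject_inflow_rbcs(stb, g, fl, 1, h_in = 0.3, acc = NULL)
  expect_equal(stb2$injected, 0)
  expect_gt(attr(stb2, "acc"), 1) # deficit retained, not dropped
})

test_that("RBC ledger and spacing hold over a full stochastic run", {
  g <- generate_lattice_mvn(synth_config(seed = 6, nx = 5, ny = 5, nz = 5))
  s <- run_simulation(g, quick_sim(9, "with_rbcs", warm = 0.3, avg = 0.7))
  expect_identical(s$counts$n_end,
                   s$counts$n0 + s$counts$injected - s$counts$ejected)
  expect_gte(s$min_slack_um, -1e-9)
})

test_that("RBC snapshots resolve vessel ids and positions", {
  g <- path_graph()
  st <- rbc_state(vessel = c(2L, 1L), s_um = c(12.5, 40))
  snap <- rbc_snapshot_table(st, g, t_s = 0.25)
  expect_equal(snap$vessel_id, c(2L, 1L))
  expect_equal(snap$s_um, c(12.5, 40))
  expect_equal(unique(snap$t), 0.25)
})
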