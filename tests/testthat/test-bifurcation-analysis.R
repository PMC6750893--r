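test_that("relative velocity difference: identities, bounds, scale invariance", {
  expect_equal(relative_velocity_difference(1.7, 1.7), 0)
  expect_equal(relative_velocity_difference(3, 1), 1.0)
  expect_equal(relative_velocity_difference(1, 0), 2.0)
  expect_error(relative_velocity_difference(0, 0), "undefined")
  set.seed(4)
  v1 <- runif(50, 0, 5); v2 <- runif(50, 0, 5)
  drv <- relative_velocity_difference(v1, v2)
  expect_true(all(drv >= 0 & drv <= 2))
  for (k in c(0.2, 3, 17)) {
    expect_equal(relative_velocity_difference(k * v1, k * v2), drv,
                 tolerance = 1e-12)
  }
})

test_that("balance classes partition [0,2] and respond to threshold shifts", {
  expect_equal(as.character(balance_class(0.05)), "well_balanced")
  expect_equal(as.character(balance_class(0.20)), "well_balanced") # boundary inclusive
  expect_equal(as.character(balance_class(0.30)), "intermediate")
  expect_equal(as.character(balance_class(0.41)), "unbalanced")
  set.seed(5)
  drv <- runif(300, 0, 2)
  cls <- balance_class(drv)
  expect_false(anyNA(cls))
  # +-10 % thresholds only move records lying between old and new boundaries
  cls2 <- balance_class(drv, t_wb = 0.22, t_ub = 0.44)
  moved <- which(cls != cls2)
  expect_true(all((drv[moved] > 0.20 & drv[moved] <= 0.22) |
                  (drv[moved] > 0.40 & drv[moved] <= 0.44)))
})

test_that("bifurcation classification matches exhaustive enumeration on a lattice", {
  g <- generate_lattice_mvn(synth_config(seed = 2, nx = 6, ny = 6, nz = 6))
  re <- effective_resistance(g$vessels$length_um * 1e-6,
                             g$vessels$diameter_um * 1e-6, 0.3)
  fl <- solve_pressures(g, re)
  field <- data.frame(vessel_id = g$vessels$vessel_id, q_med = fl$q, v_med = fl$v,
                      ht_med = 0.2, n_rbc_mean = 1)
  recs <- classify_bifurcations(g, field)
  # oracle: enumerate capillary-only degree-3 nodes by hand
  gi <- capflow:::graph_index(g)
  all3 <- 0L
  for (node in which(gi$deg == 3 & !gi$is_boundary)) {
    vv <- which(gi$ifrom == node | gi$ito == node)
    if (all(gi$type[vv] == "capillary")) all3 <- all3 + 1L
  }
  expect_equal(nrow(recs) + attr(recs, "excluded"), all3)
  expect_true(all(recs$kind %in% c("divergent", "convergent")))
  # a toy Y is divergent; reversing the boundary pressures makes it convergent
  gy <- generate_toy_bifurcation(8, 8, 8)
  fy <- solve_pressures(gy, effective_resistance(
    gy$vessels$length_um * 1e-6, gy$vessels$diameter_um * 1e-6, 0))
  fld <- data.frame(vessel_id = 1:3, q_med = fy$q, v_med = fy$v,
                    ht_med = 0, n_rbc_mean = 0)
  expect_equal(classify_bifurcations(gy, fld)$kind, "divergent")
  fld$q_med <- -fld$q_med; fld$v_med <- -fld$v_med
  expect_equal(classify_bifurcations(gy, fld)$kind, "convergent")
})

test_that("DoWB is a plain fraction with a counting oracle", {
  rec <- data.frame(kind = rep("divergent", 4),
                    class = factor(c("well_balanced", "intermediate",
                                     "unbalanced", "unbalanced"),
                                   levels = levels(balance_class(0))))
  expect_equal(degree_of_well_balanced(rec, "divergent"), 0.25)
  rec$class[] <- "well_balanced"
  expect_equal(degree_of_well_balanced(rec, "divergent"), 1.0)
  set.seed(6)
  rec2 <- data.frame(kind = "divergent", class = balance_class(runif(200, 0, 2)))
  expect_equal(degree_of_well_balanced(rec2, "divergent"),
               sum(rec2$class == "well_balanced") / nrow(rec2))
  expect_error(degree_of_well_balanced(rec2, "convergent"), "no records")
})

test_that("distribution comparison: null case, dominance, exact small-sample p", {
  set.seed(7)
  x <- runif(40)
  null_cmp <- compare_distributions(x, x, "paired")
  expect_gt(null_cmp$p_value, 0.9)
  y <- runif(500); z <- y - 0.5
  dom <- compare_distributions(z, y, "unpaired_one_sided")
  expect_lt(dom$p_value, 1e-3)
  # exact permutation oracle at n = 4 vs 4
  a <- c(0.1, 0.4, 0.8, 1.3); b <- c(0.5, 0.9, 1.4, 2.0)
  res <- compare_distributions(a, b, "unpaired_one_sided")
  pool <- c(a, b)
  u_stat <- function(aa, bb) sum(outer(aa, bb, ">")) # Mann-Whitney U of a over b
  obs <- u_stat(a, b)
  combs <- utils::combn(8, 4)
  perm <- apply(combs, 2, function(idx) u_stat(pool[idx], pool[-idx]))
  p_exact <- mean(perm <= obs) # one-sided: a stochastically smaller
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  # summaries carry quartiles and adjusted Fisher-Pearson skewness
  expect_named(res$summary_a, c("q1", "median", "q3", "skewness"))
  expect_error(compare_distributions(1:3, 1:4, "paired"), "equal-length")
})

test_that("measured-velocity tables ingest with replicate handling", {
  withr::with_tempdir({
    tab <- data.frame(
      bifurcation_id = rep(c("b1", "b2"), each = 6),
      kind = rep(c("divergent", "convergent"), each = 6),
      vessel_role = rep(rep(c("d1", "d2"), each = 3), 2),
      replicate = rep(1:3, 4),
      velocity_mm_s = c(1.0, 1.2, 1.1, 0.9, 1.0, 0.8,   # b1: medians 1.1, 0.9
                        2.0, 2.2, 2.1, 0.5, 0.6, 0.7))  # b2: medians 2.1, 0.6
    write.csv(tab, "meas.csv", row.names = FALSE)
    res <- read_measured_velocities("meas.csv", use = "median")
    expect_equal(res$v1, c(1.1, 2.1))
    expect_equal(res$v2, c(0.9, 0.6))
    expect_equal(res$drv[1], 2 * 0.2 / 2.0, tolerance = 1e-12)
    # a single chosen replicate instead of the median
    res2 <- read_measured_velocities("meas.csv", use = 2)
    expect_equal(res2$v1, c(1.2, 2.2))
    expect_equal(res2$v2, c(1.0, 0.6))
    tab_bad <- tab[, -3]
    write.csv(tab_bad, "bad.csv", row.names = FALSE)
    expect_error(read_measured_velocities("bad.csv"), "missing column")
  })
})
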