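test_that("layer assignment uses the half-open 200 um convention", {
  expect_equal(assign_layers(350), 2L, ignore_attr = TRUE)
  # boundary depth belongs to the next layer (half-open convention)
  expect_equal(assign_layers(200), 2L, ignore_attr = TRUE)
  expect_equal(assign_layers(0), 1L, ignore_attr = TRUE)
  out <- assign_layers(c(-5, 150, 999, 1000))
  expect_equal(as.integer(out), c(NA, 1L, 5L, NA))
  expect_equal(attr(out, "excluded"), 2)
  set.seed(9)
  d <- runif(200, 0, 1000)
  expect_equal(as.integer(assign_layers(d)),
               vapply(d, function(x) as.integer(x %/% 200) + 1L, integer(1)))
})

test_that("well-balanced fraction per layer matches manual tabulation", {
  set.seed(10)
  rec <- data.frame(kind = "divergent", depth_um = runif(120, 0, 1000),
                    class = balance_class(runif(120, 0, 2)))
  res <- wb_fraction_per_layer(rec)
  lay <- floor(rec$depth_um / 200) + 1
  for (k in 1:5) {
    sel <- lay == k
    expect_equal(res$per_layer$fraction[k],
                 mean(rec$class[sel] == "well_balanced"))
  }
  expect_equal(res$cv, sd(res$per_layer$fraction) / mean(res$per_layer$fraction))
  # uniform assignment: zero coefficient of variation
  rec2 <- data.frame(kind = "divergent",
                     depth_um = rep(seq(50, 950, by = 200), each = 4),
                     class = factor(rep(c("well_balanced", "unbalanced"), 10),
                                    levels = levels(balance_class(0))))
  expect_equal(wb_fraction_per_layer(rec2)$cv, 0)
})

test_that("minimum Euclidean distances match a brute-force oracle", {
  expect_equal(min_euclidean_distances(rbind(c(0, 0, 0)), rbind(c(30, 0, 0))), 30)
  set.seed(11)
  a <- matrix(runif(60, 0, 500), ncol = 3)
  b <- matrix(runif(90, 0, 500), ncol = 3)
  d <- min_euclidean_distances(a, b)
  oracle <- vapply(seq_len(nrow(a)), function(i)
    min(sqrt(colSums((t(b) - a[i, ])^2))), numeric(1))
  expect_equal(d, oracle, tolerance = 1e-12)
  # self-distance: nearest other point, never zero
  dself <- min_euclidean_distances(a, a, exclude_self = TRUE)
  expect_true(all(dself > 0))
  oracle_self <- vapply(seq_len(nrow(a)), function(i)
    min(sqrt(colSums((t(a[-i, ]) - a[i, ])^2))), numeric(1))
  expect_equal(dself, oracle_self, tolerance = 1e-12)
  # a point lying on the target set has distance zero
  expect_equal(min_euclidean_distances(a[3, , drop = FALSE], a), 0)
})

test_that("main branches and polyline sampling cover the trunks", {
  g <- generate_lattice_mvn(synth_config(seed = 3, nx = 6, ny = 6, nz = 6))
  da <- main_branch_vessels(g, "descending_arteriole")
  av <- main_branch_vessels(g, "ascending_venule")
  expect_setequal(da, g$vessels$vessel_id[g$vessels$type == "descending_arteriole"])
  expect_setequal(av, g$vessels$vessel_id[g$vessels$type == "ascending_venule"])
  pts <- polyline_points(g, da[1], step_um = 1)
  expect_gt(nrow(pts), g$vessels$length_um[match(da[1], g$vessels$vessel_id)] - 2)
  # consecutive samples at most 1 um apart along the segment
  expect_lt(max(abs(diff(pts[, 3]))), 1 + 1e-9)
})

test_that("flow path lengths to penetrating vessels match a Dijkstra oracle", {
  g <- generate_lattice_mvn(synth_config(seed = 1, nx = 6, ny = 6, nz = 6))
  re <- effective_resistance(g$vessels$length_um * 1e-6,
                             g$vessels$diameter_um * 1e-6, 0.3)
  fl <- solve_pressures(g, re)
  field <- data.frame(vessel_id = g$vessels$vessel_id, q_med = fl$q, v_med = fl$v,
                      ht_med = 0.2, n_rbc_mean = 1)
  recs <- classify_bifurcations(g, field)
  wb_nodes <- utils::head(recs$node_id[recs$kind == "divergent"], 6)
  for (target in c("descending_arteriole", "ascending_venule")) {
    pl <- min_path_length_to_penetrating(g, field, wb_nodes, target)
    for (i in seq_along(wb_nodes)) {
      expect_equal(pl[i], dijkstra_oracle(g, field, wb_nodes[i], target),
                   info = paste(target, wb_nodes[i]))
    }
    # path length dominates the Euclidean distance to the same trunk set
    tv <- main_branch_vessels(g, target)
    pts <- polyline_points(g, tv, step_um = 1)
    pos <- as.matrix(g$nodes[match(wb_nodes, g$nodes$node_id),
                             c("x_um", "y_um", "z_um")])
    eu <- min_euclidean_distances(pos, pts)
    fini <- is.finite(pl)
    expect_true(all(pl[fini] >= eu[fini] - 1e-6))
  }
})

test_that("tissue grid: centre counts, zero-distance vessel, segment oracle", {
  g <- generate_lattice_mvn(synth_config(seed = 2, nx = 5, ny = 5, nz = 5))
  wb <- g$vessels$vessel_id[1:4]
  tg <- tissue_distance_grid(g, wb, dims = c(5, 5, 5))
  expect_equal(tg$n_centres, 125)
  expect_equal(nrow(tg$centres), 125)
  # large grids lay out without distance computation
  tg2 <- tissue_distance_grid(g, wb, dims = c(100, 100, 132),
                              compute_distances = FALSE)
  expect_equal(tg2$n_centres, 1320000L)
  expect_equal(tissue_distance_grid(g, wb, dims = c(100, 100, 114),
                                    compute_distances = FALSE)$n_centres, 1140000L)
  # brute-force point-to-segment oracle on the small grid
  gi <- capflow:::graph_index(g)
  idx <- match(wb, g$vessels$vessel_id)
  oracle <- rep(Inf, 125)
  for (i in seq_len(125)) {
    p <- tg$centres[i, ]
    for (e in idx) {
      a <- gi$pos[gi$ifrom[e], ]; b <- gi$pos[gi$ito[e], ]
      for (t in seq(0, 1, length.out = 2001)) {
        x <- a + t * (b - a)
        oracle[i] <- min(oracle[i], sqrt(sum((p - x)^2)))
      }
    }
  }
  expect_equal(tg$distance_um, oracle, tolerance = 1e-3)
  # a centre on a chosen vessel has distance ~0
  mid <- (gi$pos[gi$ifrom[idx[1]], ] + gi$pos[gi$ito[idx[1]], ]) / 2
  g3 <- g
  tg3 <- tissue_distance_grid(g, wb, dims = c(1, 1, 1))
  expect_lte(tg3$distance_um,
             sqrt(sum((tg3$centres[1, ] - mid)^2)) + 1e-9)
  expect_error(tissue_distance_grid(g, integer(0), dims = c(2, 2, 2)),
               "no well-balanced")
})
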