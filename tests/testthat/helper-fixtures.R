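# Fixtures and hand-rolled oracles shared by the tests. Oracles deliberately
# avoid the code paths (and libraries) used by the implementation.

# three-node path graph A - B - C with boundary pressures at A and C
path_graph <- function(p_a_mmHg = 1 / 133.322, p_c_mmHg = 0, d_um = 8, l_um = 100) {
  nodes <- data.frame(node_id = 1:3,
                      x_um = c(0, l_um, 2 * l_um), y_um = 0, z_um = 0,
                      is_boundary = c(TRUE, FALSE, TRUE),
                      boundary_pressure_pa = c(p_a_mmHg, NA, p_c_mmHg) * 133.322)
  vessels <- data.frame(vessel_id = 1:2, node_from = c(1L, 2L), node_to = c(2L, 3L),
                        length_um = l_um, diameter_um = d_um, type = "capillary",
                        stringsAsFactors = FALSE)
  vascular_graph(nodes, vessels)
}

# random connected graph with <= n_nodes nodes: random tree plus extra edges,
# random resistances, >= 2 boundary leaves
random_solver_graph <- function(seed, n_nodes = 30) {
  set.seed(seed)
  n <- sample(5:n_nodes, 1)
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
  ef <- parent[-1]; et <- 2:n
  extra <- max(0, rpois(1, n / 4))
  for (k in seq_len(extra)) {
    ab <- sample(n, 2)
    ef <- c(ef, ab[1]); et <- c(et, ab[2])
  }
  dup <- duplicated(cbind(pmin(ef, et), pmax(ef, et))) | ef == et
  ef <- ef[!dup]; et <- et[!dup]
  deg <- tabulate(c(ef, et), nbins = n)
  bnd <- which(deg == 1) # every leaf is a boundary node with a pressure
  if (length(bnd) < 2) return(random_solver_graph(seed + 1000, n_nodes))
  nb <- length(bnd)
  nodes <- data.frame(node_id = 1:n, x_um = runif(n, 0, 500),
                      y_um = runif(n, 0, 500), z_um = runif(n, 0, 500),
                      is_boundary = seq_len(n) %in% bnd,
                      boundary_pressure_pa = NA_real_)
  nodes$boundary_pressure_pa[bnd] <- runif(nb, 1000, 8000)
  eucl <- sqrt((nodes$x_um[ef] - nodes$x_um[et])^2 +
               (nodes$y_um[ef] - nodes$y_um[et])^2 +
               (nodes$z_um[ef] - nodes$z_um[et])^2)
  vessels <- data.frame(vessel_id = seq_along(ef), node_from = ef, node_to = et,
                        length_um = eucl * runif(length(ef), 1, 1.3),
                        diameter_um = runif(length(ef), 3, 9),
                        type = "capillary", stringsAsFactors = FALSE)
  list(g = vascular_graph(nodes, vessels),
       r = 10^runif(length(ef), 14, 16)) # Pa s / m^3
}

# dense full-matrix pressure solve: the independent oracle for solve_pressures
dense_solve_oracle <- function(g, r_eff) {
  nd <- g$nodes; vs <- g$vessels
  n <- nrow(nd)
  ifrom <- match(vs$node_from, nd$node_id)
  ito <- match(vs$node_to, nd$node_id)
  gcond <- 1 / r_eff
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(vs))) {
    i <- ifrom[e]; j <- ito[e]
    A[i, i] <- A[i, i] + gcond[e]; A[j, j] <- A[j, j] + gcond[e]
    A[i, j] <- A[i, j] - gcond[e]; A[j, i] <- A[j, i] - gcond[e]
  }
  isb <- which(nd$is_boundary)
  int <- setdiff(seq_len(n), isb)
  p <- rep(0, n)
  p[isb] <- nd$boundary_pressure_pa[isb]
  # eliminate the Dirichlet rows: solve the reduced interior system
  p[int] <- solve(A[int, int, drop = FALSE],
                  -A[int, isb, drop = FALSE] %*% p[isb])
  p
}

# breadth-first walk over the flow-directed graph: oracle for the generation
# bookkeeping (smallest |generation| wins, ties upstream)
bfs_generations_oracle <- function(g, field, site, n) {
  nd <- g$nodes; vs <- g$vessels
  ifrom <- match(vs$node_from, nd$node_id)
  ito <- match(vs$node_to, nd$node_id)
  qm <- field$q_med[match(vs$vessel_id, field$vessel_id)]
  up <- ifelse(qm > 0, ifrom, ifelse(qm < 0, ito, NA))
  dn <- ifelse(qm > 0, ito, ifelse(qm < 0, ifrom, NA))
  s <- match(site, nd$node_id)
  vv <- which(ifrom == s | ito == s)
  mother <- vv[!is.na(dn[vv]) & dn[vv] == s]
  daughters <- vv[!is.na(up[vv]) & up[vv] == s]
  assigned <- c(mother, daughters)
  out <- list()
  fr_up <- up[mother]; fr_dn <- dn[daughters]
  for (gidx in seq_len(n)) {
    new_up <- integer(0)
    for (node in fr_up) {
      take <- setdiff(which(!is.na(dn) & dn == node), assigned)
      new_up <- union(new_up, take)
    }
    assigned <- c(assigned, new_up)
    new_dn <- integer(0)
    for (node in fr_dn) {
      take <- setdiff(which(!is.na(up) & up == node), assigned)
      new_dn <- union(new_dn, take)
    }
    assigned <- c(assigned, new_dn)
    out[[as.character(-gidx)]] <- sort(vs$vessel_id[new_up])
    out[[as.character(gidx)]] <- sort(vs$vessel_id[new_dn])
    fr_up <- unique(up[new_up]); fr_dn <- unique(dn[new_dn])
  }
  out
}

# hand-rolled Dijkstra on the flow-directed capillary subgraph: oracle for
# min_path_length_to_penetrating
dijkstra_oracle <- function(g, field, start_id, target_type) {
  nd <- g$nodes; vs <- g$vessels
  n <- nrow(nd)
  ifrom <- match(vs$node_from, nd$node_id)
  ito <- match(vs$node_to, nd$node_id)
  qm <- field$q_med[match(vs$vessel_id, field$vessel_id)]
  up <- ifelse(qm > 0, ifrom, ifelse(qm < 0, ito, NA))
  dn <- ifelse(qm > 0, ito, ifelse(qm < 0, ifrom, NA))
  upstream <- target_type == "descending_arteriole"
  cap <- which(vs$type == "capillary" & !is.na(up))
  src <- if (upstream) dn[cap] else up[cap]
  dst <- if (upstream) up[cap] else dn[cap]
  wt <- vs$length_um[cap]
  dist <- rep(Inf, n)
  dist[match(start_id, nd$node_id)] <- 0
  done <- rep(FALSE, n)
  tv <- which(vs$type == target_type)
  targets <- unique(c(ifrom[tv], ito[tv]))
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (k in which(src == u)) {
      if (dist[u] + wt[k] < dist[dst[k]]) dist[dst[k]] <- dist[u] + wt[k]
    }
  }
  min(dist[targets])
}

# tiny simulation settings used across tests
quick_sim <- function(seed, variant = "with_rbcs", warm = 0.5, avg = 1) {
  sim_config(seed = seed, variant = variant, t_warmup_s = warm, t_avg_s = avg)
}
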