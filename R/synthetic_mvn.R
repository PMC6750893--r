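#' Configuration for the synthetic microvascular network generator
#'
#' The generator emulates the statistical structure of the cortical capillary
#' bed: a jittered cubic capillary mesh with ~50 um inter-capillary spacing,
#' capillary diameters strictly below 10 um (so the pressure-force bifurcation
#' rule governs RBC routing in the whole bed), penetrating descending
#' arterioles (DA) feeding the mesh from the top face and ascending venules
#' (AV) draining it. All randomness is drawn from one stream seeded here.
#'
#' @param seed integer seed (sole source of randomness)
#' @param nx,ny,nz lattice dimensions (node counts per axis, each >= 3)
#' @param spacing_um capillary spacing (um)
#' @param cap_d_median_um,cap_d_gsd capillary diameter law: lognormal with this
#'   median and geometric standard deviation, truncated to `cap_d_range_um`
#' @param cap_d_range_um open truncation interval for capillary diameters (um)
#' @param trunk_d_um DA/AV trunk diameter (um)
#' @param n_da,n_av number of descending arterioles / ascending venules
#' @param jitter node position jitter as a fraction of the spacing
#' @param p_in_mmHg,p_out_mmHg boundary pressures at DA tops / AV tops
#' @param depth_um cortical depth spanned by the lattice; `NULL` (default)
#'   derives it as `(nz - 1) * spacing_um`
#' @param loop_fraction fraction of eligible extra lattice edges added on top
#'   of the spanning tree (controls the density of capillary loops, hence the
#'   number of degree-3 nodes)
#' @return a `synth_config` list
#' @export
synth_config <- function(seed, nx = 8, ny = 8, nz = 8, spacing_um = 50,
                         cap_d_median_um = 4, cap_d_gsd = 1.2,
                         cap_d_range_um = c(2, 9.9), trunk_d_um = 15,
                         n_da = 4, n_av = 4, jitter = 0.2,
                         p_in_mmHg = 50, p_out_mmHg = 10,
                         depth_um = NULL, loop_fraction = 0.55) {
  stopifnot(nx >= 3, ny >= 3, nz >= 3, spacing_um > 0, cap_d_median_um > 0,
            cap_d_gsd >= 1, trunk_d_um > 0, n_da >= 1, n_av >= 1,
            jitter >= 0, jitter < 0.5, p_in_mmHg > p_out_mmHg,
            cap_d_range_um[1] > 0, cap_d_range_um[2] < 10)
  if (is.null(depth_um)) depth_um <- (nz - 1) * spacing_um
  structure(list(seed = as.integer(seed), nx = nx, ny = ny, nz = nz,
                 spacing_um = spacing_um, cap_d_median_um = cap_d_median_um,
                 cap_d_gsd = cap_d_gsd, cap_d_range_um = cap_d_range_um,
                 trunk_d_um = trunk_d_um, n_da = n_da, n_av = n_av,
                 jitter = jitter, p_in_mmHg = p_in_mmHg,
                 p_out_mmHg = p_out_mmHg, depth_um = depth_um,
                 loop_fraction = loop_fraction),
            class = "synth_config")
}

# deterministic trunk column placement: DAs at quadrant centres (then the
# centre), AVs at the four corners (then edge midpoints).
trunk_columns <- function(nx, ny, n_da, n_av) {
  f <- function(fx, fy) c(round((nx - 1) * fx), round((ny - 1) * fy))
  da_cand <- list(f(.3, .3), f(.3, .7), f(.7, .3), f(.7, .7), f(.5, .5))
  av_cand <- list(f(0, 0), f(0, 1), f(1, 0), f(1, 1),
                  f(.5, 0), f(.5, 1), f(0, .5), f(1, .5))
  if (n_da > length(da_cand) || n_av > length(av_cand))
    stop("unsupported number of trunks for this lattice size")
  da <- do.call(rbind, da_cand[seq_len(n_da)])
  av <- do.call(rbind, av_cand[seq_len(n_av)])
  if (anyDuplicated(rbind(da, av))) stop("trunk columns collide; enlarge the lattice")
  list(da = da, av = av)
}

#' Generate a synthetic cortical microvascular network
#'
#' Builds a jittered cubic capillary mesh with node degrees capped at 3
#' (bifurcations), spanned by a randomized depth-first tree plus a configurable
#' fraction of loop edges, and couples it to straight penetrating DA/AV trunks
#' via capillary offshoots. The top node of each trunk is the only boundary
#' node of that trunk and carries the inlet (DA) or outlet (AV) pressure.
#' Deterministic for a fixed config (bit-identical CSV files on re-run).
#'
#' @param config a [synth_config()]
#' @return a validated `vascular_graph`
#' @export
generate_lattice_mvn <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  rng <- local({ set.seed(cf$seed); NULL }) # single stream, seeded once
  h <- cf$spacing_um
  hz <- cf$depth_um / (cf$nz - 1)
  tc <- trunk_columns(cf$nx, cf$ny, cf$n_da, cf$n_av)
  trunk_xy <- rbind(tc$da, tc$av)
  trunk_kind <- rep(c("da", "av"), c(nrow(tc$da), nrow(tc$av)))

  # mesh nodes: all lattice sites except trunk columns
  grid <- expand.grid(i = 0:(cf$nx - 1), j = 0:(cf$ny - 1), k = 0:(cf$nz - 1))
  is_trunk_col <- rep(FALSE, nrow(grid))
  for (t in seq_len(nrow(trunk_xy)))
    is_trunk_col <- is_trunk_col | (grid$i == trunk_xy[t, 1] & grid$j == trunk_xy[t, 2])
  mesh <- grid[!is_trunk_col, ]
  nm <- nrow(mesh)
  key <- function(i, j, k) i + cf$nx * (j + cf$ny * k) + 1L
  mesh_id <- rep(NA_integer_, cf$nx * cf$ny * cf$nz)
  mesh_id[key(mesh$i, mesh$j, mesh$k)] <- seq_len(nm)

  pos <- cbind(mesh$i * h, mesh$j * h, mesh$k * hz)
  pos <- pos + matrix(runif(3 * nm, -cf$jitter * h, cf$jitter * h), ncol = 3)

  # candidate lattice edges between mesh nodes (6-neighbourhood)
  nb <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  edges <- NULL
  for (d in 1:3) {
    a <- mesh
    b <- data.frame(i = mesh$i + nb[d, 1], j = mesh$j + nb[d, 2], k = mesh$k + nb[d, 3])
    ok <- b$i < cf$nx & b$j < cf$ny & b$k < cf$nz
    ia <- mesh_id[key(a$i, a$j, a$k)][ok]
    ib <- mesh_id[key(b$i, b$j, b$k)[ok]]
    keep <- !is.na(ib)
    edges <- rbind(edges, cbind(ia[keep], ib[keep]))
  }

  # degree-capped randomized spanning structure: DFS tree with degree cap 3,
  # then loop edges while both endpoints stay below degree 3
  adj <- vector("list", nm)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], e)
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], e)
  }
  deg <- integer(nm)
  used <- logical(nrow(edges))
  visited <- logical(nm)
  stack <- sample.int(nm, 1)
  visited[stack] <- TRUE
  while (length(stack)) {
    u <- stack[length(stack)]
    cand <- adj[[u]]
    cand <- cand[!used[cand]]
    vopp <- ifelse(edges[cand, 1] == u, edges[cand, 2], edges[cand, 1])
    cand <- cand[!visited[vopp]]
    if (!length(cand) || deg[u] >= 3L) {
      stack <- stack[-length(stack)]
      next
    }
    e <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1)]
    v <- if (edges[e, 1] == u) edges[e, 2] else edges[e, 1]
    used[e] <- TRUE; deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    visited[v] <- TRUE
    stack <- c(stack, v)
  }
  # repair pass: attach any node the capped DFS could not reach
  for (rep_round in 1:3) {
    todo <- which(!visited)
    if (!length(todo)) break
    for (u in todo) {
      cand <- adj[[u]]
      vopp <- ifelse(edges[cand, 1] == u, edges[cand, 2], edges[cand, 1])
      ok <- visited[vopp] & deg[vopp] < 3L
      if (any(ok)) {
        e <- cand[ok][1]
        v <- vopp[ok][1]
        used[e] <- TRUE; deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
        visited[u] <- TRUE
      }
    }
  }
  if (any(!visited)) stop("internal error: generator produced a disconnected mesh")
  free <- which(!used)
  free <- free[sample.int(length(free))]
  n_extra <- round(cf$loop_fraction * length(free))
  added <- 0L
  for (e in free) {
    if (added >= n_extra) break
    a <- edges[e, 1]; b <- edges[e, 2]
    if (deg[a] < 3L && deg[b] < 3L) {
      used[e] <- TRUE; deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      added <- added + 1L
    }
  }
  mesh_edges <- edges[used, , drop = FALSE]

  # prune degree-1 leaves iteratively: interior mesh nodes must be bifurcations
  # or path joints (degree >= 2). Removing a leaf never disconnects the mesh.
  repeat {
    dg <- tabulate(c(mesh_edges[, 1], mesh_edges[, 2]), nbins = nm)
    leaves <- which(dg == 1L)
    if (!length(leaves)) break
    drop_e <- mesh_edges[, 1] %in% leaves | mesh_edges[, 2] %in% leaves
    mesh_edges <- mesh_edges[!drop_e, , drop = FALSE]
  }
  keep_nodes <- sort(unique(c(mesh_edges[, 1], mesh_edges[, 2])))
  remap <- rep(NA_integer_, nm)
  remap[keep_nodes] <- seq_along(keep_nodes)
  mesh_edges[, 1] <- remap[mesh_edges[, 1]]
  mesh_edges[, 2] <- remap[mesh_edges[, 2]]
  pos <- pos[keep_nodes, , drop = FALSE]
  mesh_id_full <- mesh_id
  mesh_id <- rep(NA_integer_, length(mesh_id_full))
  ok_full <- !is.na(mesh_id_full)
  mesh_id[ok_full] <- remap[mesh_id_full[ok_full]]
  nm <- length(keep_nodes)
  deg <- tabulate(c(mesh_edges[, 1], mesh_edges[, 2]), nbins = nm)

  # trunk nodes and vessels
  n_trunk <- nrow(trunk_xy)
  tn_id <- matrix(0L, n_trunk, cf$nz)
  node_x <- pos[, 1]; node_y <- pos[, 2]; node_z <- pos[, 3]
  nid <- nm
  for (t in seq_len(n_trunk)) {
    for (k in 0:(cf$nz - 1)) {
      nid <- nid + 1L
      tn_id[t, k + 1L] <- nid
      node_x <- c(node_x, trunk_xy[t, 1] * h)
      node_y <- c(node_y, trunk_xy[t, 2] * h)
      node_z <- c(node_z, k * hz)
    }
  }
  n_nodes <- nid
  vfrom <- mesh_edges[, 1]; vto <- mesh_edges[, 2]
  vtype <- rep("capillary", nrow(mesh_edges))
  for (t in seq_len(n_trunk)) {
    vfrom <- c(vfrom, tn_id[t, 1:(cf$nz - 1)])
    vto <- c(vto, tn_id[t, 2:cf$nz])
    vtype <- c(vtype, rep(if (trunk_kind[t] == "da") "descending_arteriole"
                          else "ascending_venule", cf$nz - 1))
  }

  # offshoots: trunk levels 1..nz-1 connect to up to 2 lateral mesh neighbours
  # whose degree still allows a bifurcation; a trunk that finds none (tight
  # lattices) force-attaches to its least-connected neighbour (the resulting
  # degree-4 joint is legal and excluded from bifurcation statistics anyway)
  deg_all <- c(deg, rep(0L, n_nodes - nm))
  for (t in seq_len(n_trunk)) {
    got_any <- FALSE
    fallback <- NULL # c(level k, mesh node)
    for (k in 1:(cf$nz - 1)) {
      lat <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
      lat <- lat[sample.int(4), , drop = FALSE]
      taken <- 0L
      for (d in seq_len(4)) {
        ii <- trunk_xy[t, 1] + lat[d, 1]; jj <- trunk_xy[t, 2] + lat[d, 2]
        if (ii < 0 || jj < 0 || ii >= cf$nx || jj >= cf$ny) next
        m <- mesh_id[key(ii, jj, k)]
        if (is.na(m)) next
        if (deg_all[m] >= 3L) {
          if (is.null(fallback) || deg_all[m] < deg_all[fallback[2]])
            fallback <- c(k, m)
          next
        }
        vfrom <- c(vfrom, tn_id[t, k + 1L]); vto <- c(vto, m)
        vtype <- c(vtype, "capillary")
        deg_all[m] <- deg_all[m] + 1L
        taken <- taken + 1L; got_any <- TRUE
        if (taken >= 2L) break
      }
      if (k == cf$nz - 1 && taken == 0L) {
        # the trunk bottom must drain/feed somewhere: force-attach
        best <- NULL
        for (d in seq_len(4)) {
          ii <- trunk_xy[t, 1] + lat[d, 1]; jj <- trunk_xy[t, 2] + lat[d, 2]
          if (ii < 0 || jj < 0 || ii >= cf$nx || jj >= cf$ny) next
          m <- mesh_id[key(ii, jj, k)]
          if (is.na(m)) next
          if (is.null(best) || deg_all[m] < deg_all[best]) best <- m
        }
        if (is.null(best)) stop("internal error: trunk ", t, " bottom is isolated")
        vfrom <- c(vfrom, tn_id[t, k + 1L]); vto <- c(vto, best)
        vtype <- c(vtype, "capillary")
        deg_all[best] <- deg_all[best] + 1L
        got_any <- TRUE
      }
    }
    if (!got_any) {
      if (is.null(fallback))
        stop("internal error: trunk ", t, " has no reachable mesh neighbour")
      k <- fallback[1]; m <- fallback[2]
      vfrom <- c(vfrom, tn_id[t, k + 1L]); vto <- c(vto, m)
      vtype <- c(vtype, "capillary")
      deg_all[m] <- deg_all[m] + 1L
    }
  }

  # diameters and lengths
  n_v <- length(vfrom)
  is_cap <- vtype == "capillary"
  diam <- numeric(n_v)
  diam[!is_cap] <- cf$trunk_d_um
  ncap <- sum(is_cap)
  draw <- function(n) {
    d <- rlnorm(n, meanlog = log(cf$cap_d_median_um), sdlog = log(cf$cap_d_gsd))
    bad <- d <= cf$cap_d_range_um[1] | d >= cf$cap_d_range_um[2]
    while (any(bad)) {
      d[bad] <- rlnorm(sum(bad), meanlog = log(cf$cap_d_median_um), sdlog = log(cf$cap_d_gsd))
      bad <- d <= cf$cap_d_range_um[1] | d >= cf$cap_d_range_um[2]
    }
    d
  }
  diam[is_cap] <- draw(ncap)
  len <- sqrt((node_x[vfrom] - node_x[vto])^2 + (node_y[vfrom] - node_y[vto])^2 +
              (node_z[vfrom] - node_z[vto])^2)

  is_b <- rep(FALSE, n_nodes)
  p_b <- rep(NA_real_, n_nodes)
  for (t in seq_len(n_trunk)) {
    top <- tn_id[t, 1]
    is_b[top] <- TRUE
    p_b[top] <- mmHg_to_Pa(if (trunk_kind[t] == "da") cf$p_in_mmHg else cf$p_out_mmHg)
  }

  nodes <- data.frame(node_id = seq_len(n_nodes), x_um = node_x, y_um = node_y,
                      z_um = node_z, is_boundary = is_b, boundary_pressure_pa = p_b)
  vessels <- data.frame(vessel_id = seq_len(n_v), node_from = vfrom, node_to = vto,
                        length_um = len, diameter_um = diam, type = vtype,
                        stringsAsFactors = FALSE)
  vascular_graph(nodes, vessels)
}

#' Build a four-node Y bifurcation graph
#'
#' A mother vessel feeding two daughter vessels at a single interior junction:
#' the standard toy fixture for phase-separation, routing and balancing tests.
#' All vessels are capillaries. The inlet and both outlets are boundary nodes.
#'
#' @param d_mother,d_d1,d_d2 diameters (um)
#' @param l_um vessel length, shared by all three vessels (um)
#' @param p_in_mmHg inlet pressure
#' @param p_out1_mmHg,p_out2_mmHg outlet pressures of daughters 1 and 2
#' @return a validated `vascular_graph`; vessel ids are 1 (mother), 2, 3
#' @export
generate_toy_bifurcation <- function(d_mother, d_d1, d_d2, l_um = 100,
                                     p_in_mmHg = 30.5, p_out1_mmHg = 29.65,
                                     p_out2_mmHg = 29.85) {
  if (!(l_um > 0)) stop("value error: vessel length must be positive")
  if (any(c(d_mother, d_d1, d_d2) <= 0)) stop("value error: diameters must be positive")
  nodes <- data.frame(
    node_id = 1:4,
    x_um = c(0, l_um, l_um + l_um / sqrt(2), l_um + l_um / sqrt(2)),
    y_um = c(0, 0, l_um / sqrt(2), -l_um / sqrt(2)),
    z_um = 0,
    is_boundary = c(TRUE, FALSE, TRUE, TRUE),
    boundary_pressure_pa = mmHg_to_Pa(c(p_in_mmHg, NA, p_out1_mmHg, p_out2_mmHg)))
  vessels <- data.frame(
    vessel_id = 1:3, node_from = c(1L, 2L, 2L), node_to = c(2L, 3L, 4L),
    length_um = l_um, diameter_um = c(d_mother, d_d1, d_d2),
    type = "capillary", stringsAsFactors = FALSE)
  vascular_graph(nodes, vessels)
}
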