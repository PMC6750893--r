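#' Assign bifurcations to cortical analysis layers
#'
#' Layers are half-open depth slabs `[k*thickness, (k+1)*thickness)`,
#' numbered from 1 at the pial surface (depth = z coordinate, 0 at the
#' surface). Out-of-range depths are excluded and counted.
#'
#' @param depth_um depth coordinates (um)
#' @param n_layers number of layers (default 5)
#' @param thickness_um layer thickness (default 200)
#' @return integer layer index (1-based), `NA` for out-of-range depths;
#'   attribute `excluded` counts them
#' @export
assign_layers <- function(depth_um, n_layers = 5, thickness_um = 200) {
  lay <- floor(depth_um / thickness_um) + 1
  bad <- depth_um < 0 | lay > n_layers
  lay[bad] <- NA_integer_
  out <- as.integer(lay)
  attr(out, "excluded") <- sum(bad)
  out
}

#' Well-balanced fraction per analysis layer
#'
#' Relative number of well-balanced divergent bifurcations per layer, and the
#' coefficient of variation of that fraction across layers. Empty layers are
#' excluded with a warning.
#'
#' @param records output of [classify_bifurcations()]
#' @param n_layers,thickness_um layer geometry (see [assign_layers()])
#' @return list `per_layer` (data frame `layer, n, n_wb, fraction`) and `cv`
#' @export
wb_fraction_per_layer <- function(records, n_layers = 5, thickness_um = 200) {
  div <- records[records$kind == "divergent", ]
  lay <- assign_layers(div$depth_um, n_layers, thickness_um)
  tab <- lapply(seq_len(n_layers), function(k) {
    sel <- which(!is.na(lay) & lay == k)
    data.frame(layer = k, n = length(sel),
               n_wb = sum(div$class[sel] == "well_balanced"),
               fraction = if (length(sel)) mean(div$class[sel] == "well_balanced")
                          else NA_real_)
  })
  per <- do.call(rbind, tab)
  if (any(per$n == 0)) warning("empty analysis layer(s): ",
                               paste(per$layer[per$n == 0], collapse = ", "))
  f <- per$fraction[per$n > 0]
  list(per_layer = per, cv = stats::sd(f) / mean(f))
}

#' Minimum Euclidean distances between point sets
#'
#' For each point of `a`, the distance to the nearest point of `b`. With
#' `exclude_self = TRUE` (nearest-neighbour distance within one set) a point
#' is never matched to itself.
#'
#' @param a,b numeric matrices with 3 columns (um)
#' @param exclude_self set `TRUE` when `a` and `b` are the same set
#' @return numeric vector of length `nrow(a)` (um)
#' @export
min_euclidean_distances <- function(a, b, exclude_self = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(b)) stop("b must be non-empty")
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    if (exclude_self) d2[d2 < 1e-18] <- Inf
    out[i] <- sqrt(min(d2))
  }
  out
}

#' Main branch of a penetrating vessel
#'
#' Operational definition: starting from each boundary vessel of the given
#' type at the pial surface, follow same-type vessels with non-increasing
#' diameter (ties resolved toward the larger diameter) until none continues.
#'
#' @param g a `vascular_graph`
#' @param type `"descending_arteriole"` or `"ascending_venule"`
#' @return vessel ids on the main branches (all trunks of that type)
#' @export
main_branch_vessels <- function(g, type = "descending_arteriole") {
  gi <- graph_index(g)
  inc <- incidence_csr(gi)
  at_node <- function(i) inc$ves[seq.int(inc$ptr[i], inc$ptr[i + 1L] - 1L)]
  starts <- which(gi$is_boundary)
  out <- integer(0)
  for (b in starts) {
    e <- at_node(b)
    if (gi$type[e] != type) next
    node <- if (gi$ifrom[e] == b) gi$ito[e] else gi$ifrom[e]
    cur_d <- gi$D[e]
    path <- e
    repeat {
      nxt <- setdiff(at_node(node), path)
      nxt <- nxt[gi$type[nxt] == type & gi$D[nxt] <= cur_d + 1e-9]
      if (!length(nxt)) break
      e2 <- nxt[which.max(gi$D[nxt])]
      path <- c(path, e2)
      cur_d <- gi$D[e2]
      node <- if (gi$ifrom[e2] == node) gi$ito[e2] else gi$ifrom[e2]
    }
    out <- c(out, path)
  }
  g$vessels$vessel_id[out]
}

#' Sample points densely along vessel polylines
#'
#' Vessels are straight segments between their endpoints; points are placed
#' every `step_um` along each segment (both endpoints included).
#'
#' @param g a `vascular_graph`
#' @param vessel_ids vessels to sample
#' @param step_um sampling step (default 1)
#' @return numeric matrix (n x 3) of positions (um)
#' @export
polyline_points <- function(g, vessel_ids, step_um = 1) {
  gi <- graph_index(g)
  idx <- match(vessel_ids, g$vessels$vessel_id)
  pts <- lapply(idx, function(e) {
    p0 <- gi$pos[gi$ifrom[e], ]; p1 <- gi$pos[gi$ito[e], ]
    len <- sqrt(sum((p1 - p0)^2))
    tt <- unique(c(seq(0, len, by = step_um), len)) / max(len, 1e-12)
    cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]),
          p0[3] + tt * (p1[3] - p0[3]))
  })
  do.call(rbind, pts)
}

#' Minimum flow path length to a penetrating vessel
#'
#' Walks the flow-directed graph from a bifurcation node upstream until a
#' descending arteriole is reached (or downstream until an ascending venule),
#' and returns the minimum cumulative vessel length over all such walks.
#' Implemented as a shortest path on the directed graph weighted by vessel
#' length; unreachable targets return `Inf`.
#'
#' @param g a `vascular_graph`
#' @param field `time_averaged_field` providing flow directions
#' @param node_ids bifurcation nodes (e.g. well-balanced sites)
#' @param target `"descending_arteriole"` (upstream walk) or
#'   `"ascending_venule"` (downstream walk)
#' @return numeric vector of path lengths (um), `Inf` when unreachable
#' @export
min_path_length_to_penetrating <- function(g, field, node_ids,
                                           target = "descending_arteriole") {
  gi <- graph_index(g)
  qm <- field$q_med[match(g$vessels$vessel_id, field$vessel_id)]
  up <- ifelse(qm > 0, gi$ifrom, ifelse(qm < 0, gi$ito, NA_integer_))
  dn <- ifelse(qm > 0, gi$ito, ifelse(qm < 0, gi$ifrom, NA_integer_))
  ok <- !is.na(up) & gi$type == "capillary"
  # direction of travel: upstream for DA (traverse edges dn -> up),
  # downstream for AV (up -> dn)
  upstream <- target == "descending_arteriole"
  el <- if (upstream) cbind(dn[ok], up[ok]) else cbind(up[ok], dn[ok])
  ig <- igraph::graph_from_edgelist(el, directed = TRUE)
  n_have <- igraph::vcount(ig)
  if (n_have < gi$n_nodes) ig <- igraph::add_vertices(ig, gi$n_nodes - n_have)
  igraph::E(ig)$weight <- gi$L[ok]
  # target nodes: endpoints of vessels of the target type
  tv <- which(gi$type == target)
  tnodes <- unique(c(gi$ifrom[tv], gi$ito[tv]))
  dm <- igraph::distances(ig, v = match(node_ids, g$nodes$node_id),
                          to = tnodes, mode = "out")
  apply(dm, 1, min)
}

#' Tissue grid of distances to well-balanced outflow vessels
#'
#' Divides the graph's bounding box into `dims` cubes and computes, for each
#' cube centre, the distance to the nearest point on any outflow vessel of a
#' well-balanced bifurcation (vessels as straight segments, exact
#' point-to-segment distance). Summaries include the median distance and the
#' fraction of tissue within an influence radius (default 50 um, the average
#' inter-capillary distance).
#'
#' @param g a `vascular_graph`
#' @param wb_vessel_ids outflow vessel ids of well-balanced bifurcations
#' @param dims integer length-3: grid dimensions
#' @param influence_um influence radius for the coverage fraction (default 50)
#' @param compute_distances set `FALSE` to lay out the grid only (centres can
#'   number millions; distances are then skipped)
#' @return a `tissue_grid` list: `centres` (n x 3), `dims`, and (when
#'   computed) `distance_um`, `median_um`, `fraction_within`
#' @export
tissue_distance_grid <- function(g, wb_vessel_ids, dims,
                                 influence_um = 50, compute_distances = TRUE) {
  stopifnot(length(dims) == 3, all(dims >= 1))
  if (!length(wb_vessel_ids)) stop("no well-balanced outflow vessels given")
  pos <- as.matrix(g$nodes[, c("x_um", "y_um", "z_um")])
  lo <- apply(pos, 2, min); hi <- apply(pos, 2, max)
  step <- (hi - lo) / dims
  ax <- function(d) lo[d] + step[d] * (seq_len(dims[d]) - 0.5)
  centres <- as.matrix(expand.grid(x = ax(1), y = ax(2), z = ax(3)))
  out <- list(centres = centres, dims = as.integer(dims),
              n_centres = nrow(centres))
  if (compute_distances) {
    gi <- graph_index(g)
    idx <- match(wb_vessel_ids, g$vessels$vessel_id)
    dmin <- rep(Inf, nrow(centres))
    for (e in idx) {
      p0 <- gi$pos[gi$ifrom[e], ]; p1 <- gi$pos[gi$ito[e], ]
      dseg <- point_segment_distance(centres, p0, p1)
      dmin <- pmin(dmin, dseg)
    }
    out$distance_um <- dmin
    out$median_um <- stats::median(dmin)
    out$fraction_within <- mean(dmin <= influence_um)
  }
  structure(out, class = "tissue_grid")
}

# exact point-to-segment distance, vectorized over points
point_segment_distance <- function(pts, p0, p1) {
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - p0[1])^2 + (pts[, 2] - p0[2])^2 + (pts[, 3] - p0[3])^2))
  }
  t <- ((pts[, 1] - p0[1]) * d[1] + (pts[, 2] - p0[2]) * d[2] +
        (pts[, 3] - p0[3]) * d[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pts[, 1] - (p0[1] + t * d[1]))^2 + (pts[, 2] - (p0[2] + t * d[2]))^2 +
       (pts[, 3] - (p0[3] + t * d[3]))^2)
}
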