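#' Vascular network graphs
#'
#' A `vascular_graph` is the substrate of every computation in capflow: a set
#' of nodes (bifurcations and endpoints, with 3-D positions in micrometres)
#' connected by vessels (edges with length, diameter and an anatomical type
#' label). Boundary nodes are network in-/outlets and carry a fixed pressure.
#'
#' Internally the graph is a list of two data frames:
#' \describe{
#'   \item{nodes}{`node_id, x_um, y_um, z_um, is_boundary, boundary_pressure_pa`
#'     (pressure is `NA` for interior nodes; stored in Pa, files use mmHg)}
#'   \item{vessels}{`vessel_id, node_from, node_to, length_um, diameter_um, type`}
#' }
#' Vessel orientation (`node_from` -> `node_to`) is a storage convention only;
#' the sign of the computed flow defines the physical direction.
#'
#' @param nodes,vessels data frames as described above
#' @param validate check invariants (default `TRUE`)
#' @return an object of class `vascular_graph`
#' @export
vascular_graph <- function(nodes, vessels, validate = TRUE) {
  nodes <- as.data.frame(nodes)
  vessels <- as.data.frame(vessels)
  g <- structure(list(nodes = nodes, vessels = vessels), class = "vascular_graph")
  if (validate) validate_graph(g)
  g
}

VESSEL_TYPES <- c("pial_arteriole", "descending_arteriole", "capillary",
                  "ascending_venule", "pial_venule")

#' Validate a vascular graph
#'
#' Checks every structural invariant: column presence, finite positive
#' geometry, tortuosity (length at least the Euclidean end-to-end distance,
#' within 1% tolerance), no self loops, no dangling node references, boundary
#' nodes of degree one with a pressure, interior nodes of degree at least two,
#' and global connectivity. Errors identify the offending row.
#'
#' @param g a `vascular_graph`
#' @return `g`, invisibly
#' @export
validate_graph <- function(g) {
  nd <- g$nodes; vs <- g$vessels
  need_n <- c("node_id", "x_um", "y_um", "z_um", "is_boundary", "boundary_pressure_pa")
  need_v <- c("vessel_id", "node_from", "node_to", "length_um", "diameter_um", "type")
  miss <- setdiff(need_n, names(nd))
  if (length(miss)) stop("graph format error: nodes missing column(s) ", paste(miss, collapse = ", "))
  miss <- setdiff(need_v, names(vs))
  if (length(miss)) stop("graph format error: vessels missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(nd$node_id)) stop("integrity error: duplicated node_id ",
                                      nd$node_id[duplicated(nd$node_id)][1])
  if (anyDuplicated(vs$vessel_id)) stop("integrity error: duplicated vessel_id ",
                                        vs$vessel_id[duplicated(vs$vessel_id)][1])
  pos <- as.matrix(nd[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(pos))) stop("value error: non-finite node position, node_id ",
                                 nd$node_id[!stats::complete.cases(pos)][1])
  bad <- which(!(vs$length_um > 0))
  if (length(bad)) stop("value error: non-positive length, vessel_id ", vs$vessel_id[bad[1]])
  bad <- which(!(vs$diameter_um > 0))
  if (length(bad)) stop("value error: non-positive diameter, vessel_id ", vs$vessel_id[bad[1]])
  bad <- which(!(vs$type %in% VESSEL_TYPES))
  if (length(bad)) stop("value error: unknown vessel type '", vs$type[bad[1]],
                        "', vessel_id ", vs$vessel_id[bad[1]])
  idx_from <- match(vs$node_from, nd$node_id)
  idx_to <- match(vs$node_to, nd$node_id)
  if (anyNA(idx_from)) stop("integrity error: vessel_id ",
                            vs$vessel_id[which(is.na(idx_from))[1]],
                            " references missing node ", vs$node_from[which(is.na(idx_from))[1]])
  if (anyNA(idx_to)) stop("integrity error: vessel_id ",
                          vs$vessel_id[which(is.na(idx_to))[1]],
                          " references missing node ", vs$node_to[which(is.na(idx_to))[1]])
  loops <- which(idx_from == idx_to)
  if (length(loops)) stop("integrity error: self-loop, vessel_id ", vs$vessel_id[loops[1]])
  eucl <- sqrt(rowSums((pos[idx_from, , drop = FALSE] - pos[idx_to, , drop = FALSE])^2))
  bad <- which(vs$length_um < eucl * (1 - 0.01))
  if (length(bad)) stop("value error: length below end-to-end distance (tortuosity < 1), vessel_id ",
                        vs$vessel_id[bad[1]])
  deg <- tabulate(c(idx_from, idx_to), nbins = nrow(nd))
  isb <- as.logical(nd$is_boundary)
  bad <- which(isb & deg != 1L)
  if (length(bad)) stop("integrity error: boundary node ", nd$node_id[bad[1]],
                        " has degree ", deg[bad[1]], " (must be 1)")
  bad <- which(isb & !is.finite(nd$boundary_pressure_pa))
  if (length(bad)) stop("value error: boundary node ", nd$node_id[bad[1]], " lacks a pressure")
  bad <- which(!isb & deg < 2L)
  if (length(bad)) stop("integrity error: interior node ", nd$node_id[bad[1]],
                        " has degree ", deg[bad[1]], " (must be >= 2)")
  ig <- igraph::graph_from_edgelist(cbind(idx_from, idx_to), directed = FALSE)
  if (igraph::vcount(ig) < nrow(nd) || !igraph::is_connected(ig))
    stop("integrity error: graph is not connected")
  invisible(g)
}

#' @export
print.vascular_graph <- function(x, ...) {
  nb <- sum(x$nodes$is_boundary)
  cat("vascular_graph:", nrow(x$nodes), "nodes (", nb, "boundary ),",
      nrow(x$vessels), "vessels\n")
  cat("  types:", paste(sprintf("%s=%d", names(table(x$vessels$type)),
                                as.integer(table(x$vessels$type))), collapse = ", "), "\n")
  invisible(x)
}

#' Read a vascular graph from a nodes/vessels CSV pair
#'
#' The file dialect is UTF-8 CSV with a mandatory header and `.` decimal
#' separator. `nodes.csv` columns:
#' `node_id,x_um,y_um,z_um,is_boundary,boundary_pressure_mmHg` (pressure empty
#' for interior nodes); `vessels.csv` columns:
#' `vessel_id,node_from,node_to,length_um,diameter_um,type`. Pressures are
#' converted from mmHg to Pa on read; the graph is validated.
#'
#' @param nodes_path,vessels_path file paths
#' @return a validated `vascular_graph`
#' @export
read_graph <- function(nodes_path, vessels_path) {
  nd <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  vs <- utils::read.csv(vessels_path, stringsAsFactors = FALSE)
  if (!"boundary_pressure_mmHg" %in% names(nd))
    stop("graph format error: nodes missing column boundary_pressure_mmHg")
  nd$boundary_pressure_pa <- mmHg_to_Pa(as.numeric(nd$boundary_pressure_mmHg))
  nd$boundary_pressure_mmHg <- NULL
  nd$is_boundary <- as.logical(nd$is_boundary)
  vascular_graph(nd, vs)
}

#' Write a vascular graph to a nodes/vessels CSV pair
#'
#' Inverse of [read_graph()]; pressures are written in mmHg.
#'
#' @param g a `vascular_graph`
#' @param nodes_path,vessels_path output file paths
#' @return the two paths, invisibly
#' @export
write_graph <- function(g, nodes_path, vessels_path) {
  nd <- g$nodes
  out <- data.frame(node_id = nd$node_id, x_um = nd$x_um, y_um = nd$y_um,
                    z_um = nd$z_um, is_boundary = nd$is_boundary,
                    boundary_pressure_mmHg = Pa_to_mmHg(nd$boundary_pressure_pa))
  utils::write.csv(out, nodes_path, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(g$vessels, vessels_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(nodes_path, vessels_path))
}

# internal indexed view: everything downstream work needs, with 0/1-based indices
# resolved once. Returns vessel endpoint indices, lengths/diameters, areas (um^2),
# RBC length per vessel (um), node degree, incidence list.
graph_index <- function(g, v_rbc_um3 = 49) {
  nd <- g$nodes; vs <- g$vessels
  ifrom <- match(vs$node_from, nd$node_id)
  ito <- match(vs$node_to, nd$node_id)
  area <- pi * vs$diameter_um^2 / 4
  list(
    n_nodes = nrow(nd), n_vessels = nrow(vs),
    ifrom = ifrom, ito = ito,
    L = vs$length_um, D = vs$diameter_um, area = area,
    l_rbc = v_rbc_um3 / area,
    type = vs$type,
    is_boundary = as.logical(nd$is_boundary),
    p_bound = nd$boundary_pressure_pa,
    deg = tabulate(c(ifrom, ito), nbins = nrow(nd)),
    pos = as.matrix(nd[, c("x_um", "y_um", "z_um")])
  )
}

# incidence in CSR form: for node i, vessels adj_ves[adj_ptr[i]:(adj_ptr[i+1]-1)]
incidence_csr <- function(gi) {
  ord <- order(c(gi$ifrom, gi$ito))
  ves <- rep.int(seq_len(gi$n_vessels), 2L)[ord]
  nodes <- c(gi$ifrom, gi$ito)[ord]
  ptr <- cumsum(c(1L, tabulate(nodes, nbins = gi$n_nodes)))
  list(ptr = ptr, ves = ves)
}

#' Vessel generations up- and downstream of a bifurcation
#'
#' Walks the flow-directed graph away from a divergent bifurcation. The site
#' itself (mother and both daughters) is generation 0 and excluded. Upstream
#' generation 1 contains the vessels delivering flow into the mother's
#' upstream node; generation 2 the vessels feeding those, and so on. Downstream
#' generation 1 contains the first vessels downstream of the two daughters.
#' A vessel reachable at several depths is assigned the smallest absolute
#' generation; an upstream/downstream tie (a loop) is assigned upstream.
#' Vessels with zero median flow are skipped.
#'
#' @param g a `vascular_graph`
#' @param field a `time_averaged_field` (see [run_simulation()]) carrying
#'   median flows, hence flow directions
#' @param site node id of a degree-3 bifurcation
#' @param n number of generations on each side
#' @return named list `"-n" ... "-1", "1" ... "n"` of vessel-id vectors
#' @export
generations_up_downstream <- function(g, field, site, n = 3) {
  gi <- graph_index(g)
  s <- match(site, g$nodes$node_id)
  if (is.na(s)) stop("unknown node id ", site)
  if (gi$deg[s] != 3L) stop("site must be a degree-3 node (degree ", gi$deg[s], ")")
  qm <- field$q_med[match(g$vessels$vessel_id, field$vessel_id)]
  if (anyNA(qm)) stop("field does not cover every vessel")
  # directed endpoints: flow runs up[e] -> dn[e]; zero-flow vessels get NA
  up <- ifelse(qm > 0, gi$ifrom, ifelse(qm < 0, gi$ito, NA_integer_))
  dn <- ifelse(qm > 0, gi$ito, ifelse(qm < 0, gi$ifrom, NA_integer_))
  inc <- incidence_csr(gi)
  at_node <- function(i) inc$ves[seq.int(inc$ptr[i], inc$ptr[i + 1L] - 1L)]
  vs_site <- at_node(s)
  mother <- vs_site[which(!is.na(dn[vs_site]) & dn[vs_site] == s)]
  daughters <- vs_site[which(!is.na(up[vs_site]) & up[vs_site] == s)]
  if (length(mother) != 1L || length(daughters) != 2L)
    stop("site is not a divergent bifurcation under the given field")
  gen0 <- c(mother, daughters)

  walk <- function(seed_nodes, direction) {
    # direction "up": from a node, take vessels delivering flow INTO it (dn == node)
    # and continue from their upstream endpoints; "down": vessels leaving it.
    res <- vector("list", n)
    seen <- gen0
    frontier <- seed_nodes
    for (gidx in seq_len(n)) {
      new_v <- integer(0)
      nxt <- integer(0)
      for (node in frontier) {
        vv <- at_node(node)
        if (direction == "up") {
          take <- vv[!is.na(dn[vv]) & dn[vv] == node]
        } else {
          take <- vv[!is.na(up[vv]) & up[vv] == node]
        }
        take <- setdiff(take, seen)
        new_v <- union(new_v, take)
        nxt <- union(nxt, if (direction == "up") up[take] else dn[take])
      }
      res[[gidx]] <- sort(new_v)
      seen <- union(seen, new_v)
      frontier <- setdiff(nxt, NA_integer_)
      if (!length(frontier)) break
    }
    res
  }
  ups <- walk(up[mother], "up")
  dns <- walk(dn[daughters], "down")
  # smallest |generation| wins; ties go upstream: remove from downstream any vessel
  # already claimed upstream at the same or smaller depth, and vice versa at larger depth
  claimed_up <- integer(0)
  claimed_dn <- integer(0)
  out <- list()
  for (gidx in seq_len(n)) {
    u <- setdiff(if (is.null(ups[[gidx]])) integer(0) else ups[[gidx]], c(claimed_up, claimed_dn))
    claimed_up <- c(claimed_up, u)
    d <- setdiff(if (is.null(dns[[gidx]])) integer(0) else dns[[gidx]], c(claimed_up, claimed_dn))
    claimed_dn <- c(claimed_dn, d)
    out[[as.character(-gidx)]] <- g$vessels$vessel_id[u]
    out[[as.character(gidx)]] <- g$vessels$vessel_id[d]
  }
  out[order(as.integer(names(out)))]
}
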