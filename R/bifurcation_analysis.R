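#' Relative velocity difference at a bifurcation
#'
#' `2 |v1 - v2| / (v1 + v2)` on velocity magnitudes: 0 for perfectly balanced
#' outflows, 2 when one branch is stalled.
#'
#' @param v1,v2 velocity magnitudes (same unit)
#' @return dimensionless difference in `[0, 2]`; vectorized
#' @export
relative_velocity_difference <- function(v1, v2) {
  v1 <- abs(v1); v2 <- abs(v2)
  if (any(v1 + v2 == 0)) stop("undefined: both velocities are zero")
  2 * abs(v1 - v2) / (v1 + v2)
}

#' Balance class of a bifurcation
#'
#' Well-balanced when the relative velocity difference is at most `t_wb`
#' (default 20%), unbalanced above `t_ub` (default 40%), intermediate
#' between.
#'
#' @param drv relative velocity difference(s)
#' @param t_wb,t_ub class thresholds, `0 < t_wb < t_ub`
#' @return factor with levels `well_balanced`, `intermediate`, `unbalanced`
#' @export
balance_class <- function(drv, t_wb = 0.20, t_ub = 0.40) {
  stopifnot(t_wb > 0, t_ub > t_wb)
  cls <- ifelse(drv <= t_wb, "well_balanced",
                ifelse(drv > t_ub, "unbalanced", "intermediate"))
  factor(cls, levels = c("well_balanced", "intermediate", "unbalanced"))
}

#' Classify capillary bifurcations from a time-averaged field
#'
#' Degree-3 nodes whose three incident vessels are all capillaries are
#' classified by the signs of the median flows: divergent (one inflow, two
#' outflows) or convergent (two inflows, one outflow). Divergent records
#' carry the daughter velocities, convergent records the mother velocities;
#' both get the relative velocity difference and its balance class. Nodes
#' with a zero-median-flow incident vessel (or a degenerate 3-in/3-out sign
#' pattern) are excluded and counted in the `excluded` attribute.
#'
#' @param g a `vascular_graph`
#' @param field a `time_averaged_field`
#' @param t_wb,t_ub balance-class thresholds (see [balance_class()])
#' @return data frame of `bifurcation_records`: `node_id, kind, mother, d1,
#'   d2, v1, v2, drv, class, depth_um`; attribute `excluded` counts skipped
#'   nodes
#' @export
classify_bifurcations <- function(g, field, t_wb = 0.20, t_ub = 0.40) {
  gi <- graph_index(g)
  inc <- incidence_csr(gi)
  qm <- field$q_med[match(g$vessels$vessel_id, field$vessel_id)]
  vm <- field$v_med[match(g$vessels$vessel_id, field$vessel_id)]
  cand <- which(gi$deg == 3L & !gi$is_boundary)
  out <- list(); excluded <- 0L
  for (node in cand) {
    vv <- inc$ves[seq.int(inc$ptr[node], inc$ptr[node + 1L] - 1L)]
    if (!all(gi$type[vv] == "capillary")) next
    if (any(qm[vv] == 0)) { excluded <- excluded + 1L; next }
    into <- (gi$ito[vv] == node & qm[vv] > 0) | (gi$ifrom[vv] == node & qm[vv] < 0)
    n_in <- sum(into)
    if (n_in == 1L) {
      kind <- "divergent"; mother <- vv[into]; dd <- vv[!into]
    } else if (n_in == 2L) {
      kind <- "convergent"; mother <- vv[!into]; dd <- vv[into]
    } else { excluded <- excluded + 1L; next }
    # divergent: daughter velocities; convergent: the two mother velocities
    pair <- if (kind == "divergent") dd else dd
    v1 <- abs(vm[pair[1]]); v2 <- abs(vm[pair[2]])
    out[[length(out) + 1L]] <- data.frame(
      node_id = g$nodes$node_id[node], kind = kind,
      mother = g$vessels$vessel_id[if (kind == "divergent") mother else vv[!into]],
      d1 = g$vessels$vessel_id[pair[1]], d2 = g$vessels$vessel_id[pair[2]],
      v1 = v1, v2 = v2,
      drv = relative_velocity_difference(v1, v2),
      depth_um = g$nodes$z_um[node],
      stringsAsFactors = FALSE)
  }
  rec <- if (length(out)) do.call(rbind, out) else
    data.frame(node_id = integer(0), kind = character(0), mother = integer(0),
               d1 = integer(0), d2 = integer(0), v1 = numeric(0),
               v2 = numeric(0), drv = numeric(0), depth_um = numeric(0))
  rec$class <- balance_class(rec$drv, t_wb, t_ub)
  attr(rec, "excluded") <- excluded
  class(rec) <- c("bifurcation_records", "data.frame")
  rec
}

#' Degree of well-balanced bifurcations (DoWB)
#'
#' Fraction of bifurcations of the given kind classified well-balanced.
#'
#' @param records output of [classify_bifurcations()]
#' @param kind `"divergent"` or `"convergent"`
#' @return fraction in `[0, 1]`
#' @export
degree_of_well_balanced <- function(records, kind = "divergent") {
  r <- records[records$kind == kind, ]
  if (!nrow(r)) stop("no records of kind ", kind)
  mean(r$class == "well_balanced")
}

#' Compare two distributions of relative velocity differences
#'
#' The statistical battery used throughout: one-sided Mann-Whitney U
#' (`unpaired_one_sided`, alternative: `a` stochastically smaller than `b`),
#' Wilcoxon signed-rank on aligned pairs (`paired`), or one-sided two-sample
#' Kolmogorov-Smirnov (`ks_one_sided`, alternative: the cumulative density of
#' `a` lies above that of `b`). Summaries report quartiles and the adjusted
#' Fisher-Pearson skewness.
#'
#' @param a,b numeric samples (paired mode requires equal length and
#'   alignment)
#' @param mode one of `"unpaired_one_sided"`, `"paired"`, `"ks_one_sided"`
#' @return list with `summary_a`, `summary_b` (Q1/median/Q3/skewness),
#'   `p_value`, `mode`
#' @export
compare_distributions <- function(a, b,
                                  mode = c("unpaired_one_sided", "paired",
                                           "ks_one_sided")) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  if (mode == "paired" && length(a) != length(b))
    stop("paired mode requires equal-length, aligned samples")
  p <- switch(mode,
    unpaired_one_sided = stats::wilcox.test(a, b, alternative = "less",
                                            exact = NULL)$p.value,
    paired = if (all(a == b)) 1 else # degenerate null: no non-zero differences
      stats::wilcox.test(a, b, paired = TRUE)$p.value,
    ks_one_sided = stats::ks.test(a, b, alternative = "less")$p.value)
  summ <- function(x) {
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(q1 = qs[1], median = qs[2], q3 = qs[3],
         skewness = e1071::skewness(x, type = 2))
  }
  list(summary_a = summ(a), summary_b = summ(b), p_value = p, mode = mode)
}

#' Read measured bifurcation velocities
#'
#' Ingests a table of per-vessel velocity measurements at bifurcations
#' (columns `bifurcation_id, kind, vessel_role, replicate, velocity_mm_s`,
#' up to three consecutive replicates per vessel). Per vessel either the
#' median over replicates or one chosen replicate is used.
#'
#' @param path CSV file path
#' @param use `"median"` or a replicate number
#' @return data frame `bifurcation_id, kind, v1, v2, drv, class` (one row per
#'   bifurcation; roles `d1`/`d2` for divergent daughters, `m1`/`m2` for
#'   convergent mothers)
#' @export
read_measured_velocities <- function(path, use = "median") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bifurcation_id", "kind", "vessel_role", "replicate", "velocity_mm_s")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  if (any(x$velocity_mm_s < 0)) stop("value error: negative velocity magnitude")
  pick <- function(v, r) {
    if (identical(use, "median")) stats::median(v) else v[r == as.integer(use)][1]
  }
  ids <- unique(x$bifurcation_id)
  out <- lapply(ids, function(id) {
    xx <- x[x$bifurcation_id == id, ]
    roles <- sort(unique(xx$vessel_role))
    if (length(roles) != 2) stop("bifurcation ", id, " must have exactly two rated vessels")
    v1 <- pick(xx$velocity_mm_s[xx$vessel_role == roles[1]],
               xx$replicate[xx$vessel_role == roles[1]])
    v2 <- pick(xx$velocity_mm_s[xx$vessel_role == roles[2]],
               xx$replicate[xx$vessel_role == roles[2]])
    data.frame(bifurcation_id = id, kind = xx$kind[1], v1 = v1, v2 = v2,
               drv = relative_velocity_difference(v1, v2))
  })
  res <- do.call(rbind, out)
  res$class <- balance_class(res$drv)
  res
}
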