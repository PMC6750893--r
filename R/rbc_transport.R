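#' Model variants
#'
#' `"with_rbcs"` is the full model: RBCs raise vessel resistance
#' (Fahraeus-Lindqvist), travel faster than the bulk flow (Fahraeus) and
#' phase-separate at divergent bifurcations. `"passive_particles"` switches
#' off both the resistance effect and the phase separation: tracked cells are
#' advected at the bulk velocity and split in proportion to the bulk flow
#' (apart from traffic-jam effects). `"no_phase_separation"` keeps the
#' resistance and velocity effects of RBCs but routes them in proportion to
#' the bulk flow.
#'
#' @format character vector of the three variant names
#' @export
MODEL_VARIANTS <- c("with_rbcs", "passive_particles", "no_phase_separation")

variant_code <- function(variant) {
  match(match.arg(variant, MODEL_VARIANTS), MODEL_VARIANTS)
}

#' Create an RBC state
#'
#' The tracked-cell population: each RBC sits at arc-length position `s_um`
#' (measured from the vessel's `node_from` end) inside vessel `vessel`. The
#' per-vessel tube hematocrit derives from occupancy:
#' `H_t = n V_RBC / (A L)`, and the RBC length in a vessel is
#' `l_RBC = V_RBC / A`.
#'
#' @param vessel integer vector: vessel index (position in `g$vessels`)
#' @param s_um numeric vector: arc positions (um)
#' @param id integer ids (default sequential)
#' @param v_rbc_um3 RBC volume (um^3); configurable global constant,
#'   default 49 (mouse)
#' @return an `rbc_state`
#' @export
rbc_state <- function(vessel = integer(0), s_um = numeric(0), id = seq_along(vessel),
                      v_rbc_um3 = 49) {
  structure(list(vessel = as.integer(vessel), s = as.numeric(s_um),
                 id = as.integer(id),
                 next_id = if (length(id)) max(id) + 1L else 1L,
                 injected = 0L, ejected = 0L, v_rbc_um3 = v_rbc_um3),
            class = "rbc_state")
}

#' @export
print.rbc_state <- function(x, ...) {
  cat("rbc_state:", length(x$vessel), "RBCs (injected", x$injected,
      ", ejected", x$ejected, ")\n")
  invisible(x)
}

# per-vessel occupancy counts
rbc_counts <- function(state, n_vessels) {
  tabulate(state$vessel, nbins = n_vessels)
}

# tube hematocrit from occupancy; clamped to [0, 1] (transient packing can
# nudge n l_RBC marginally above L)
occupancy_hematocrit <- function(state, gi) {
  n <- rbc_counts(state, gi$n_vessels)
  pmin(n * state$v_rbc_um3 / (gi$area * gi$L), 1)
}

#' RBC velocity from bulk velocity
#'
#' In the full model RBCs travel faster than the bulk flow by the Fahraeus
#' factor `H_d / H_t` (cells concentrate near the axis where the velocity
#' profile peaks); passive particles move with the bulk flow.
#'
#' @param v_bulk bulk velocity (any unit; sign preserved)
#' @param h_t,h_d tube and discharge hematocrit (with `h_t <= h_d`)
#' @param variant one of [MODEL_VARIANTS]
#' @return RBC velocity, same unit as `v_bulk`; vectorized
#' @export
rbc_velocity <- function(v_bulk, h_t, h_d, variant = "with_rbcs") {
  code <- variant_code(variant)
  if (code == 2L) return(v_bulk)
  fac <- ifelse(h_t > 0, h_d / h_t, 1)
  v_bulk * pmax(fac, 1)
}

#' Empirical phase-separation split (mother vessels >= 10 um)
#'
#' The Pries logit law: the fractional RBC flux `FQE` entering daughter 1 as a
#' function of the fractional bulk flow `FQB` into daughter 1, the three
#' diameters and the mother discharge hematocrit. Below the plasma-skimming
#' threshold `X0` no RBCs enter; above `1 - X0` all do. The law satisfies
#' `FQE(FQB) + FQE'(1 - FQB) = 1` with daughters swapped.
#'
#' @param fqb fractional bulk flow into daughter 1, in `[0, 1]`
#' @param d_mother,d_d1,d_d2 diameters (um)
#' @param h_d mother discharge hematocrit
#' @return fractional RBC flux into daughter 1; vectorized over `fqb`
#' @export
pries_split_fraction <- function(fqb, d_mother, d_d1, d_d2, h_d) {
  stopifnot(all(fqb >= 0 & fqb <= 1))
  .cf_pries_fqe(as.numeric(fqb), d_mother, d_d1, d_d2, h_d)
}

#' Pressure-force routing at capillary bifurcations (< 10 um)
#'
#' Each RBC follows the daughter exerting the larger pressure force
#' `(pressure drop / length) * cross-section`. Exact ties are broken by a
#' fair coin. A daughter at its packing limit is skipped; if both are
#' blocked the RBC waits (`0` is returned). Daughters with negative force
#' (instantaneous outflow reversal) are excluded.
#'
#' @param forces numeric length-2 pressure forces of the daughters
#' @param blocked logical length-2: daughter entrance at packing limit
#' @return `1`, `2`, or `0` (no entry possible)
#' @export
bifurcation_rule_choice <- function(forces, blocked = c(FALSE, FALSE)) {
  stopifnot(length(forces) == 2, length(blocked) == 2)
  ok <- !blocked & forces > 0
  if (!any(ok)) return(0L)
  if (sum(ok) == 1L) return(which(ok))
  scale <- max(abs(forces))
  pref <- if (abs(forces[1] - forces[2]) <= 1e-12 * scale) {
    if (stats::runif(1) < 0.5) 1L else 2L
  } else which.max(forces)
  if (blocked[pref]) pref <- 3L - pref
  if (blocked[pref]) 0L else pref
}

#' Snapshot of the RBC population as a data frame
#'
#' @param state an [rbc_state()]
#' @param g a `vascular_graph` (to resolve vessel ids)
#' @param t_s time stamp to attach (s)
#' @return data frame `t, rbc_id, vessel_id, s_um`
#' @export
rbc_snapshot_table <- function(state, g, t_s = 0) {
  data.frame(t = t_s, rbc_id = state$id,
             vessel_id = g$vessels$vessel_id[state$vessel],
             s_um = state$s)
}

#' Advance all RBCs by one time step
#'
#' Moves every RBC by its vessel's RBC velocity times `dt`, enforcing a
#' minimum spacing of one RBC length behind its leader (traffic-jam
#' contract), and routes RBCs arriving at nodes: divergent bifurcations by
#' the empirical logit split (mother >= 10 um) or the pressure-force
#' bifurcation rule (mother < 10 um) in the full model, and by a Bernoulli
#' draw on the bulk-flow fraction in the passive and no-phase-separation
#' variants; convergent arrivals merge in arrival order; boundary arrivals
#' are removed and counted.
#'
#' @param state an [rbc_state()]
#' @param g a `vascular_graph`
#' @param flow a `capflow_flow` (frozen for this step)
#' @param dt_s time step (s); must satisfy `max(v_rbc) * dt < min(L)`
#' @param variant one of [MODEL_VARIANTS]
#' @param params a [resistance_params()]
#' @return updated `rbc_state`; attributes `crossings` (per-vessel counts),
#'   `min_slack` (spacing audit, um) and `blocked` (jam events)
#' @export
advance_rbcs <- function(state, g, flow, dt_s, variant = "with_rbcs",
                         params = resistance_params()) {
  gi <- graph_index(g, state$v_rbc_um3)
  inc <- incidence_csr(gi)
  code <- variant_code(variant)
  h_t <- occupancy_hematocrit(state, gi)
  h_d <- discharge_from_tube(gi$D, h_t)
  v_bulk_um <- abs(flow$v) / UM_M # um/s magnitude
  v_rbc <- abs(rbc_velocity(v_bulk_um, h_t, h_d, variant))
  if (max(v_rbc * dt_s) >= min(gi$L))
    stop("dt violation: an RBC could traverse a whole vessel in one step (",
         "max v_rbc*dt = ", signif(max(v_rbc * dt_s), 4), " um >= min L = ",
         signif(min(gi$L), 4), " um)")
  res <- .cf_advance(state$vessel, state$s, state$id,
                     gi$ifrom, gi$ito, gi$L, gi$D, gi$l_rbc,
                     flow$q, v_rbc, h_d,
                     gi$is_boundary, flow$p_pa,
                     inc$ptr, inc$ves, dt_s, code, 10)
  out <- state
  out$vessel <- res$vessel; out$s <- res$s; out$id <- res$id
  out$ejected <- state$ejected + res$ejected
  attr(out, "crossings") <- res$crossings
  attr(out, "min_slack") <- res$min_slack
  attr(out, "blocked") <- res$blocked
  out
}

# inflow boundary vessels under a given flow state: boundary node whose single
# vessel carries flow into the network
inflow_vessels <- function(gi, flow) {
  b <- which(gi$is_boundary)
  inc <- incidence_csr(gi)
  ves <- vapply(b, function(i) inc$ves[inc$ptr[i]], integer(1))
  into <- (gi$ifrom[ves] == b & flow$q[ves] > 0) |
          (gi$ito[ves] == b & flow$q[ves] < 0)
  ves[into]
}

#' Inject RBCs at inflow boundaries
#'
#' Inserts RBCs at the entrance of every inflow boundary vessel so the
#' long-run injected RBC volume flux equals `q * h_in`. A fractional-count
#' accumulator carries the deficit across steps; insertions blocked by the
#' packing limit are deferred, never dropped.
#'
#' @param state an [rbc_state()]
#' @param g a `vascular_graph`
#' @param flow a `capflow_flow`
#' @param dt_s time step (s)
#' @param h_in inflow discharge hematocrit in `[0, 1)` (default 0.3)
#' @param acc named accumulator vector from the previous step (internal use;
#'   `NULL` starts at zero)
#' @return updated `rbc_state`; attribute `acc` holds the carried accumulator
#' @export
inject_inflow_rbcs <- function(state, g, flow, dt_s, h_in = 0.3, acc = NULL) {
  stopifnot(h_in >= 0, h_in < 1)
  gi <- graph_index(g, state$v_rbc_um3)
  iv <- inflow_vessels(gi, flow)
  if (!length(iv)) return(state)
  rate <- abs(flow$q[iv]) * 1e18 * h_in / state$v_rbc_um3 # RBC per second
  if (is.null(acc)) acc <- numeric(length(iv))
  res <- .cf_inject(state$vessel, state$s, state$id,
                    gi$ifrom, gi$ito, gi$L, gi$l_rbc, flow$q,
                    iv, rate, acc, dt_s, state$next_id)
  out <- state
  out$vessel <- res$vessel; out$s <- res$s; out$id <- res$id
  out$next_id <- res$next_id
  out$injected <- state$injected + res$injected
  attr(out, "acc") <- res$acc
  out
}
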