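#' Simulation configuration
#'
#' @param seed integer seed; the single source of randomness of a run
#' @param variant one of [MODEL_VARIANTS]
#' @param dt_s time step (s); default 5e-4, within the 0.5-0.75 ms range the
#'   model is designed for
#' @param h_in inflow discharge hematocrit (default 0.3)
#' @param m perfusion multiplicity of the averaging rule: the interval must
#'   let the covered vessels be perfused at least `m` times (default 10)
#' @param coverage fraction of vessels the averaging rule must cover
#'   (default 0.9)
#' @param warmup_mult warm-up length in multiples of the averaging interval
#'   (default 2)
#' @param t_avg_s,t_warmup_s explicit overrides (s) for the averaging and
#'   warm-up intervals; `NULL` applies the turnover-time rule
#' @param v_rbc_um3 RBC volume (um^3, default 49)
#' @param params a [resistance_params()]
#' @return a `sim_config`
#' @export
sim_config <- function(seed, variant = "with_rbcs", dt_s = 5e-4, h_in = 0.3,
                       m = 10, coverage = 0.9, warmup_mult = 2,
                       t_avg_s = NULL, t_warmup_s = NULL, v_rbc_um3 = 49,
                       params = resistance_params()) {
  stopifnot(dt_s > 0, coverage > 0, coverage <= 1, m >= 1, warmup_mult >= 1,
            h_in >= 0, h_in < 1)
  variant <- match.arg(variant, MODEL_VARIANTS)
  structure(list(seed = as.integer(seed), variant = variant, dt_s = dt_s,
                 h_in = h_in, m = m, coverage = coverage,
                 warmup_mult = warmup_mult, t_avg_s = t_avg_s,
                 t_warmup_s = t_warmup_s, v_rbc_um3 = v_rbc_um3,
                 params = params),
            class = "sim_config")
}

#' Vessel turnover time
#'
#' Time to perfuse a vessel once: length over flow speed. Zero-velocity
#' vessels return `Inf` and are excluded from the coverage rule.
#'
#' @param l_m vessel length (m)
#' @param v_m_s bulk velocity (m/s, sign ignored)
#' @return turnover time (s); vectorized
#' @export
turnover_time <- function(l_m, v_m_s) {
  ifelse(v_m_s == 0, Inf, l_m / abs(v_m_s))
}

#' Averaging interval from turnover times
#'
#' The interval over which the flow field is averaged: long enough that a
#' `coverage` fraction of vessels is completely perfused at least `m` times.
#' Implemented as `m` times the `coverage` quantile (lower-interpolation
#' convention) of the finite turnover times.
#'
#' @param turnovers_s per-vessel turnover times (s); `Inf` entries are excluded
#' @param m perfusion multiplicity (default 10)
#' @param coverage vessel coverage fraction (default 0.9)
#' @return averaging interval (s)
#' @export
averaging_interval <- function(turnovers_s, m = 10, coverage = 0.9) {
  fin <- turnovers_s[is.finite(turnovers_s)]
  if (!length(fin)) stop("all turnover times are infinite")
  m * as.numeric(stats::quantile(fin, coverage, type = 1))
}

#' Moving average of a time series (presentation smoothing)
#'
#' Arithmetic mean over a sliding window, sampled every `stride` steps; the
#' reported value sits at the window end.
#'
#' @param series numeric vector
#' @param window window length in steps (default 100)
#' @param stride sampling stride in steps (default 50)
#' @return numeric vector of window means (empty, with a warning, if the
#'   series is shorter than one window)
#' @export
moving_average <- function(series, window = 100, stride = 50) {
  n <- length(series)
  if (n < window) {
    warning("series shorter than one window; empty output")
    return(numeric(0))
  }
  ends <- seq.int(window, n, by = stride)
  cs <- cumsum(c(0, series))
  (cs[ends + 1] - cs[ends + 1 - window]) / window
}

# per-vessel constants of the empirical laws, precomputed once per run so the
# per-step work is a handful of vectorized power/exp calls
law_constants <- function(gi, params) {
  d <- gi$D
  eta45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + 1 / (1 + 1e-11 * d^12)) +
    1 / (1 + 1e-11 * d^12)
  list(r_plasma = plasma_resistance(gi$L * UM_M, gi$D * UM_M, params$mu_plasma_pas),
       eta45 = eta45, cc = cc,
       denom_inv = 1 / ((1 - 0.45)^cc - 1),
       x = fahraeus_x(d))
}

# one flow solve given per-vessel discharge hematocrit (internal fast path;
# solver carries the cached Cholesky)
step_flow <- function(gi, solver, h_d, cf, lc) {
  r_eff <- if (cf$variant == "passive_particles") {
    lc$r_plasma
  } else {
    hd <- pmin(h_d, 0.99)
    eta <- 1 + (lc$eta45 - 1) * ((1 - hd)^lc$cc - 1) * lc$denom_inv
    lc$r_plasma * eta
  }
  res <- solve_interior(solver, 1 / r_eff)
  p <- gi$p_bound
  p[res$solver$int_idx] <- res$p_int
  q <- (p[gi$ifrom] - p[gi$ito]) / r_eff
  list(solver = res$solver,
       flow = structure(list(p_pa = p, q = q, v = q / (gi$area * UM_M^2),
                             r_eff = r_eff, h_d = h_d),
                        class = "capflow_flow"))
}

# closed-form Fahraeus inverse with precomputed x(D)
fast_discharge <- function(h_t, x) {
  a <- 1 - x
  out <- (-x + sqrt(x^2 + 4 * a * h_t)) / (2 * a)
  deg <- abs(a) < 1e-12 # clamped-fit diameters: H_t = H_d
  if (any(deg)) out[deg] <- h_t[deg]
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

# homogeneous initial RBC loading: every vessel at the tube hematocrit implied
# by the inflow discharge hematocrit, cells evenly spaced
init_rbcs <- function(gi, cf) {
  h_t <- tube_from_discharge(gi$D, cf$h_in)
  n <- round(h_t * gi$area * gi$L / cf$v_rbc_um3)
  n <- pmin(n, floor(gi$L / gi$l_rbc)) # respect the packing limit
  vessel <- rep.int(seq_len(gi$n_vessels), n)
  s <- unlist(lapply(seq_len(gi$n_vessels), function(e) {
    if (n[e] == 0) return(numeric(0))
    gi$L[e] * (seq_len(n[e]) - 0.5) / n[e]
  }), use.names = FALSE)
  rbc_state(vessel, s, v_rbc_um3 = cf$v_rbc_um3)
}

#' Run a blood-flow simulation to its time-averaged field
#'
#' Couples the quasi-static pressure solve and the discrete RBC transport:
#' per step (1) tube hematocrit from RBC occupancy, (2) discharge hematocrit
#' by inverting the Fahraeus relation, (3) effective resistances and sparse
#' pressure solve, (4) inflow injection, (5) RBC advection and routing.
#' A warm-up of `warmup_mult` averaging intervals precedes recording (the
#' interval is re-derived from the warmed field unless overridden); per-vessel
#' medians over the recording window form the time-averaged field. Fully
#' reproducible for a fixed config.
#'
#' @param g a `vascular_graph`
#' @param config a [sim_config()]
#' @param init_state optional [rbc_state()] to start from (e.g. the terminal
#'   state of a baseline run when simulating an intervention)
#' @return a `capflow_sim` object: `field` (the time-averaged field data
#'   frame), `series` (per-step recordings), `state` (terminal RBC state),
#'   `counts`, `t_avg_s`, `t_warmup_s`, `min_slack_um`, `config`
#' @export
run_simulation <- function(g, config, init_state = NULL) {
  cf <- config
  set.seed(cf$seed)
  gi <- graph_index(g, cf$v_rbc_um3)
  inc <- incidence_csr(gi)
  solver <- make_solver(gi)
  code <- variant_code(cf$variant)
  passive <- cf$variant == "passive_particles"
  state <- if (is.null(init_state)) init_rbcs(gi, cf) else init_state
  n0 <- length(state$vessel)
  inj0 <- state$injected; ej0 <- state$ejected

  lc <- law_constants(gi, cf$params)
  h_t <- occupancy_hematocrit(state, gi)
  h_d <- fast_discharge(h_t, lc$x)
  sf <- step_flow(gi, solver, h_d, cf, lc)
  solver <- sf$solver; flow <- sf$flow

  tau <- turnover_time(gi$L * UM_M, flow$v)
  t_warm <- if (!is.null(cf$t_warmup_s)) cf$t_warmup_s else
    cf$warmup_mult * averaging_interval(tau, cf$m, cf$coverage)
  n_warm <- max(0L, as.integer(ceiling(t_warm / cf$dt_s)))

  min_slack <- Inf
  flux_acc <- integer(gi$n_vessels)
  bal_max <- 0

  # fixed injection context: boundary vessels and which end is the entrance
  # (inflow set judged per step from the instantaneous flow signs)
  bnodes <- which(gi$is_boundary)
  bves <- vapply(bnodes, function(i) inc$ves[inc$ptr[i]], integer(1))
  acc_all <- numeric(length(bves))

  do_step <- function() {
    h_t <<- occupancy_hematocrit(state, gi)
    if (!passive) {
      h_d <<- fast_discharge(h_t, lc$x)
      sf <- step_flow(gi, solver, h_d, cf, lc)
      solver <<- sf$solver; flow <<- sf$flow
    }
    into <- (gi$ifrom[bves] == bnodes & flow$q[bves] > 0) |
            (gi$ito[bves] == bnodes & flow$q[bves] < 0)
    iv <- bves[into]
    state2 <- state
    if (length(iv)) {
      rate <- abs(flow$q[iv]) * 1e18 * cf$h_in / cf$v_rbc_um3
      resj <- .cf_inject(state$vessel, state$s, state$id,
                         gi$ifrom, gi$ito, gi$L, gi$l_rbc, flow$q,
                         iv, rate, acc_all[into], cf$dt_s, state$next_id)
      state2$vessel <- resj$vessel; state2$s <- resj$s; state2$id <- resj$id
      state2$next_id <- resj$next_id
      state2$injected <- state$injected + resj$injected
      acc_all[into] <<- resj$acc
    }
    v_bulk_um <- abs(flow$v) / UM_M
    v_rbc <- if (passive) v_bulk_um else {
      fac <- h_d / h_t
      fac[!is.finite(fac) | fac < 1] <- 1
      fac * v_bulk_um
    }
    if (max(v_rbc) * cf$dt_s >= min(gi$L))
      stop("dt violation: max v_rbc*dt = ", signif(max(v_rbc) * cf$dt_s, 4),
           " um >= min L = ", signif(min(gi$L), 4), " um")
    res <- .cf_advance(state2$vessel, state2$s, state2$id,
                       gi$ifrom, gi$ito, gi$L, gi$D, gi$l_rbc,
                       flow$q, v_rbc, h_d, gi$is_boundary, flow$p_pa,
                       inc$ptr, inc$ves, cf$dt_s, code, 10)
    state2$vessel <- res$vessel; state2$s <- res$s; state2$id <- res$id
    state2$ejected <- state2$ejected + res$ejected
    state <<- state2
    min_slack <<- min(min_slack, res$min_slack)
    res$crossings
  }

  # fast-path injection context is rebuilt inside inject_inflow_rbcs; for the
  # passive variant the flow field never changes, so the solve above is final
  for (i in seq_len(n_warm)) do_step()

  t_avg <- if (!is.null(cf$t_avg_s)) cf$t_avg_s else {
    tau <- turnover_time(gi$L * UM_M, flow$v)
    averaging_interval(tau, cf$m, cf$coverage)
  }
  n_rec <- max(10L, as.integer(ceiling(t_avg / cf$dt_s)))

  rec_q <- matrix(0, n_rec, gi$n_vessels)
  rec_ht <- matrix(0, n_rec, gi$n_vessels)
  rec_n <- matrix(0L, n_rec, gi$n_vessels)
  n_total <- integer(n_rec)
  for (i in seq_len(n_rec)) {
    cr <- do_step()
    flux_acc <- flux_acc + cr
    rec_q[i, ] <- flow$q
    rec_ht[i, ] <- h_t
    rec_n[i, ] <- rbc_counts(state, gi$n_vessels)
    n_total[i] <- length(state$vessel)
  }
  # global balance at the final step: signed boundary flow must sum to ~0
  b <- which(gi$is_boundary)
  bves <- vapply(b, function(i) inc$ves[inc$ptr[i]], integer(1))
  qin <- ifelse(gi$ifrom[bves] == b, flow$q[bves], -flow$q[bves])
  bal_max <- abs(sum(qin)) / max(abs(qin))

  q_med <- apply(rec_q, 2, stats::median)
  ht_med <- apply(rec_ht, 2, stats::median)
  n_mean <- colMeans(rec_n)
  field <- data.frame(vessel_id = g$vessels$vessel_id,
                      q_med = q_med,
                      v_med = q_med / (gi$area * UM_M^2),
                      ht_med = ht_med,
                      n_rbc_mean = n_mean,
                      flux_mean = flux_acc / (n_rec * cf$dt_s),
                      direction = sign(q_med),
                      n_samples = n_rec)
  class(field) <- c("time_averaged_field", "data.frame")

  structure(list(field = field,
                 series = list(q = rec_q, ht = rec_ht, n = rec_n,
                               n_total = n_total, dt_s = cf$dt_s),
                 state = state,
                 counts = list(n0 = n0, n_end = length(state$vessel),
                               injected = state$injected - inj0,
                               ejected = state$ejected - ej0),
                 t_avg_s = t_avg, t_warmup_s = n_warm * cf$dt_s,
                 min_slack_um = min_slack, balance_residual = bal_max,
                 config = cf, graph = g),
            class = "capflow_sim")
}

#' @export
print.capflow_sim <- function(x, ...) {
  cat("capflow_sim:", x$config$variant, "| vessels:", nrow(x$field),
      "| warm-up", signif(x$t_warmup_s, 3), "s | averaged",
      signif(x$t_avg_s, 3), "s (", x$field$n_samples[1], "steps )\n")
  cat("  RBCs:", x$counts$n0, "->", x$counts$n_end,
      "( injected", x$counts$injected, ", ejected", x$counts$ejected, ")\n")
  cat("  median |v|:", signif(stats::median(abs(x$field$v_med)) * 1e3, 3),
      "mm/s | median Ht:", signif(stats::median(x$field$ht_med), 3), "\n")
  invisible(x)
}

#' @export
summary.capflow_sim <- function(object, ...) {
  x <- object
  recs <- classify_bifurcations(x$graph, x$field)
  div <- recs[recs$kind == "divergent", ]
  out <- list(variant = x$config$variant,
              n_vessels = nrow(x$field),
              n_divergent = nrow(div),
              median_drv_divergent = stats::median(div$drv),
              dowb = if (nrow(div)) degree_of_well_balanced(recs, "divergent") else NA,
              median_v_mm_s = stats::median(abs(x$field$v_med)) * 1e3,
              median_ht = stats::median(x$field$ht_med),
              counts = x$counts)
  class(out) <- "summary.capflow_sim"
  out
}

#' @export
print.summary.capflow_sim <- function(x, ...) {
  cat("Simulation (", x$variant, "): ", x$n_vessels, " vessels, ",
      x$n_divergent, " divergent capillary bifurcations\n", sep = "")
  cat("  median |dRv| divergent:", signif(100 * x$median_drv_divergent, 3), "%\n")
  cat("  degree of well-balanced bifurcations:", signif(100 * x$dowb, 3), "%\n")
  cat("  median |v|:", signif(x$median_v_mm_s, 3), "mm/s | median Ht:",
      signif(x$median_ht, 3), "\n")
  invisible(x)
}

#' @export
plot.capflow_sim <- function(x, vessels = NULL, window = 100, stride = 50, ...) {
  if (is.null(vessels)) {
    n <- x$series$n_total
    t <- seq_along(n) * x$series$dt_s
    ma <- moving_average(n, window, stride)
    tm <- (seq.int(window, length(n), by = stride)) * x$series$dt_s
    plot(t, n, type = "l", col = "grey70", xlab = "time [s]",
         ylab = "RBC count", ...)
    graphics::lines(tm, ma, lwd = 2)
  } else {
    idx <- match(vessels, x$field$vessel_id)
    v <- abs(x$series$q[, idx, drop = FALSE]) /
      (pi * (x$graph$vessels$diameter_um[idx] * UM_M)^2 / 4) * 1e3
    t <- seq_len(nrow(v)) * x$series$dt_s
    graphics::matplot(t, v, type = "l", lty = 1, xlab = "time [s]",
                      ylab = "bulk velocity [mm/s]", ...)
  }
  invisible(x)
}

#' Export the recorded time series as a long data frame
#'
#' @param sim a `capflow_sim`
#' @param every keep every `every`-th step (default 1)
#' @return data frame `step, vessel_id, q, ht, n_rbc`
#' @export
series_table <- function(sim, every = 1) {
  keep <- seq.int(1, nrow(sim$series$q), by = every)
  nv <- ncol(sim$series$q)
  data.frame(step = rep(keep, each = nv),
             vessel_id = rep(sim$field$vessel_id, times = length(keep)),
             q = as.vector(t(sim$series$q[keep, , drop = FALSE])),
             ht = as.vector(t(sim$series$ht[keep, , drop = FALSE])),
             n_rbc = as.vector(t(sim$series$n[keep, , drop = FALSE])))
}
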