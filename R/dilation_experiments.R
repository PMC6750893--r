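#' Specify a single capillary dilation
#'
#' The daughter capillary is split into a proximal segment of length
#' `6 l_RBC` (kept at the baseline diameter, so the pressure-force routing at
#' the bifurcation is untouched) and a distal segment whose diameter is
#' multiplied by `f_dil`.
#'
#' @param g a `vascular_graph`
#' @param node_id bifurcation node
#' @param vessel_id dilated daughter vessel
#' @param f_dil dilation factor `D_dilated / D_baseline` (> 1, default 1.1)
#' @param v_rbc_um3 RBC volume used for `l_RBC` (default 49)
#' @return a `dilation_spec` list with the derived constant and dilated
#'   segment lengths
#' @export
dilation_spec <- function(g, node_id, vessel_id, f_dil = 1.1, v_rbc_um3 = 49) {
  stopifnot(f_dil >= 1)
  e <- match(vessel_id, g$vessels$vessel_id)
  if (is.na(e)) stop("unknown vessel ", vessel_id)
  d <- g$vessels$diameter_um[e]
  l <- g$vessels$length_um[e]
  l_rbc <- v_rbc_um3 / (pi * d^2 / 4) # RBC length in the baseline vessel
  l_const <- 6 * l_rbc
  if (l - l_const <= 0)
    stop("spec error: vessel too short for a 6 l_RBC constant segment (",
         signif(l, 4), " um <= ", signif(l_const, 4), " um)")
  structure(list(node_id = node_id, vessel_id = vessel_id, f_dil = f_dil,
                 l_const_um = l_const, l_dilated_um = l - l_const,
                 v_rbc_um3 = v_rbc_um3),
            class = "dilation_spec")
}

#' Split a daughter capillary and dilate its distal segment
#'
#' Replaces the chosen daughter by two series vessels joined at a new
#' interior node: a proximal segment (length `6 l_RBC`, baseline diameter)
#' adjacent to the bifurcation and a distal segment (remaining length,
#' diameter times `f_dil`). Total length is preserved; every other vessel is
#' untouched. The proximal segment keeps the original vessel id; the distal
#' segment gets a fresh id returned in the attributes.
#'
#' @param g a `vascular_graph`
#' @param spec a [dilation_spec()]
#' @return a new `vascular_graph`; attributes `proximal_id`, `distal_id`,
#'   `new_node_id`
#' @export
split_and_dilate <- function(g, spec) {
  e <- match(spec$vessel_id, g$vessels$vessel_id)
  vs <- g$vessels; nd <- g$nodes
  bif <- match(spec$node_id, nd$node_id)
  if (is.na(bif)) stop("unknown node ", spec$node_id)
  from_bif <- vs$node_from[e] == spec$node_id
  if (!from_bif && vs$node_to[e] != spec$node_id)
    stop("vessel ", spec$vessel_id, " is not incident to node ", spec$node_id)
  near <- if (from_bif) vs$node_from[e] else vs$node_to[e]
  far <- if (from_bif) vs$node_to[e] else vs$node_from[e]
  inear <- match(near, nd$node_id); ifar <- match(far, nd$node_id)
  frac <- spec$l_const_um / vs$length_um[e]
  newpos <- (1 - frac) * unlist(nd[inear, c("x_um", "y_um", "z_um")]) +
    frac * unlist(nd[ifar, c("x_um", "y_um", "z_um")])
  new_node <- max(nd$node_id) + 1L
  nd <- rbind(nd, data.frame(node_id = new_node, x_um = newpos[1],
                             y_um = newpos[2], z_um = newpos[3],
                             is_boundary = FALSE, boundary_pressure_pa = NA_real_))
  new_ves <- max(vs$vessel_id) + 1L
  d0 <- vs$diameter_um[e]
  # proximal: bifurcation -> new node, baseline diameter
  vs$node_from[e] <- near; vs$node_to[e] <- new_node
  vs$length_um[e] <- spec$l_const_um
  vs <- rbind(vs, data.frame(vessel_id = new_ves, node_from = new_node,
                             node_to = far, length_um = spec$l_dilated_um,
                             diameter_um = d0 * spec$f_dil,
                             type = vs$type[e], stringsAsFactors = FALSE))
  out <- vascular_graph(nd, vs)
  attr(out, "proximal_id") <- spec$vessel_id
  attr(out, "distal_id") <- new_ves
  attr(out, "new_node_id") <- new_node
  out
}

#' Length-normalized relative flow change
#'
#' `((q_act - q_base)/q_base) * 100 um / L_dilated`: the relative flow change
#' rescaled to an equivalent dilation along a 100 um segment, since the raw
#' change grows with the dilated length.
#'
#' @param q_base,q_act baseline and activation flows (same unit)
#' @param l_dilated_um dilated segment length (um)
#' @return normalized relative change; vectorized
#' @export
relative_flow_change <- function(q_base, q_act, l_dilated_um) {
  if (any(q_base == 0)) stop("undefined: zero baseline flow")
  ((q_act - q_base) / q_base) * (100 / l_dilated_um)
}

#' Relative change in RBC count
#'
#' `(n_act - n_base)/n_base` on time-averaged per-vessel RBC counts; no
#' length normalization is needed.
#'
#' @param n_base,n_act baseline and activation mean RBC counts
#' @return relative change; vectorized
#' @export
relative_nrbc_change <- function(n_base, n_act) {
  if (any(n_base <= 0)) stop("undefined: zero baseline RBC count")
  (n_act - n_base) / n_base
}

#' Quotient of flow ratios
#'
#' `a = (q_d1/q_mother)_activation / (q_d1/q_mother)_baseline`: how the
#' fractional flow into the dilated daughter changes; above 1 whenever the
#' dilated branch gains share.
#'
#' @param q_d1_base,q_mother_base,q_d1_act,q_mother_act flows
#' @return the quotient `a`; vectorized
#' @export
flow_ratio_quotient <- function(q_d1_base, q_mother_base, q_d1_act, q_mother_act) {
  if (any(c(q_d1_base, q_mother_base, q_d1_act, q_mother_act) == 0))
    stop("undefined: zero flow in the quotient")
  (q_d1_act / q_mother_act) / (q_d1_base / q_mother_base)
}

#' Select candidate bifurcations for dilation
#'
#' Filters the divergent capillary bifurcations of a baseline run: balance
#' class equal to `target_class`; distance from the network centre below
#' `centre_frac` times the maximum node distance (avoids boundary artefacts);
#' mother discharge hematocrit at least `hd_min` (sufficient RBCs present).
#' Then samples `k` of them uniformly.
#'
#' @param g a `vascular_graph`
#' @param field baseline `time_averaged_field` (full model)
#' @param records output of [classify_bifurcations()] on that field
#' @param target_class `"well_balanced"` or `"unbalanced"`
#' @param k number of bifurcations to sample
#' @param centre_frac centre-distance criterion (default 0.6)
#' @param hd_min mother discharge-hematocrit floor (default 0.3; derived from
#'   the median tube hematocrit via the Fahraeus relation)
#' @return node ids (length `<= k`; a warning is issued if fewer candidates
#'   exist); attribute `candidates` holds the full filtered set
#' @export
select_candidate_bifurcations <- function(g, field, records,
                                          target_class = "well_balanced",
                                          k = 10, centre_frac = 0.6,
                                          hd_min = 0.3) {
  div <- records[records$kind == "divergent" & records$class == target_class, ]
  pos <- as.matrix(g$nodes[, c("x_um", "y_um", "z_um")])
  ctr <- colMeans(pos)
  dist_all <- sqrt(rowSums((pos - matrix(ctr, nrow(pos), 3, byrow = TRUE))^2))
  rmax <- max(dist_all)
  idx <- match(div$node_id, g$nodes$node_id)
  near_centre <- dist_all[idx] < centre_frac * rmax
  mid <- match(div$mother, field$vessel_id)
  d_m <- g$vessels$diameter_um[match(div$mother, g$vessels$vessel_id)]
  hd_m <- discharge_from_tube(d_m, field$ht_med[mid])
  ok <- near_centre & hd_m >= hd_min
  cand <- div$node_id[ok]
  if (length(cand) < k) {
    warning("only ", length(cand), " candidates pass the filters (k = ", k, ")")
    sel <- cand
  } else {
    sel <- sample(cand, k)
  }
  attr(sel, "candidates") <- cand
  sel
}

#' Run a capillary dilation campaign
#'
#' For each selected bifurcation and each model variant: a baseline run on
#' the intact network, then one run per dilated daughter on the split-and-
#' dilated network. Activation runs restart from the baseline terminal RBC
#' state (RBCs in the split daughter are reassigned to the matching segment)
#' and re-warm for one averaging interval before recording. Relative changes
#' follow the length-normalized flow rule and the raw RBC-count rule; the
#' per-generation tables pool vessels over the flow-directed generations of
#' the baseline field.
#'
#' @param g a `vascular_graph`
#' @param config baseline [sim_config()] (its variant is ignored; use
#'   `variants`)
#' @param sites data frame with columns `node_id`, `vessel_id` (the daughter
#'   to dilate); one row per scenario
#' @param variants character vector of [MODEL_VARIANTS] to run
#' @param f_dil dilation factor (default 1.1)
#' @param n_generations generations up-/downstream to tabulate (default 3)
#' @return a `dilation_campaign` list: `results` (one data frame row per
#'   scenario x variant), `generations` (long data frame of per-generation
#'   relative changes), `baselines` (per-variant `capflow_sim`)
#' @export
run_dilation_campaign <- function(g, config, sites, variants = "with_rbcs",
                                  f_dil = 1.1, n_generations = 3) {
  stopifnot(nrow(sites) >= 1)
  baselines <- list()
  rows <- list(); gen_rows <- list()
  for (variant in variants) {
    cfb <- config; cfb$variant <- variant
    base <- run_simulation(g, cfb)
    baselines[[variant]] <- base
    bf <- base$field
    for (si in seq_len(nrow(sites))) {
      node <- sites$node_id[si]; dves <- sites$vessel_id[si]
      sp <- dilation_spec(g, node, dves, f_dil, config$v_rbc_um3)
      g2 <- split_and_dilate(g, sp)
      prox <- attr(g2, "proximal_id"); dist <- attr(g2, "distal_id")
      st <- remap_state_to_split(base$state, g, g2, dves, sp)
      cfa <- cfb
      cfa$t_warmup_s <- base$t_avg_s      # one averaging interval of re-warm
      cfa$t_avg_s <- base$t_avg_s
      act <- run_simulation(g2, cfa, init_state = st)
      af <- act$field
      # vessel bookkeeping around the bifurcation (from the baseline field)
      recs <- classify_bifurcations(g, bf)
      rec <- recs[recs$node_id == node, ]
      if (!nrow(rec) || rec$kind != "divergent") {
        rows[[length(rows) + 1L]] <- data.frame(
          node_id = node, vessel_id = dves, variant = variant, failed = TRUE,
          l_dilated_um = sp$l_dilated_um, drq_dilated = NA_real_,
          drq_mother = NA_real_, drq_constant = NA_real_,
          drn_dilated = NA_real_, drn_mother = NA_real_,
          drn_constant = NA_real_, a_quotient = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      mother <- rec$mother
      const_d <- if (rec$d1 == dves) rec$d2 else rec$d1
      bq <- function(id) bf$q_med[match(id, bf$vessel_id)]
      aq <- function(id) af$q_med[match(id, af$vessel_id)]
      bn <- function(id) bf$n_rbc_mean[match(id, bf$vessel_id)]
      an <- function(id) af$n_rbc_mean[match(id, af$vessel_id)]
      q_dil_b <- abs(bq(dves)); q_dil_a <- abs(aq(dist))
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = node, vessel_id = dves, variant = variant, failed = FALSE,
        l_dilated_um = sp$l_dilated_um,
        drq_dilated = relative_flow_change(q_dil_b, q_dil_a, sp$l_dilated_um),
        drq_mother = relative_flow_change(abs(bq(mother)), abs(aq(mother)),
                                          sp$l_dilated_um),
        drq_constant = relative_flow_change(abs(bq(const_d)), abs(aq(const_d)),
                                            sp$l_dilated_um),
        drn_dilated = relative_nrbc_change(bn(dves), an(prox) + an(dist)),
        drn_mother = relative_nrbc_change(bn(mother), an(mother)),
        drn_constant = relative_nrbc_change(bn(const_d), an(const_d)),
        a_quotient = flow_ratio_quotient(q_dil_b, abs(bq(mother)),
                                         q_dil_a, abs(aq(mother))),
        stringsAsFactors = FALSE)
      gens <- generations_up_downstream(g, bf, node, n_generations)
      for (gname in names(gens)) {
        ids <- gens[[gname]]
        if (!length(ids)) next
        gen_rows[[length(gen_rows) + 1L]] <- data.frame(
          node_id = node, vessel_id = dves, variant = variant,
          generation = as.integer(gname), target = ids,
          drq = relative_flow_change(abs(bq(ids)), abs(aq(ids)), sp$l_dilated_um),
          drn = ifelse(bn(ids) > 0, (an(ids) - bn(ids)) / bn(ids), NA_real_),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = do.call(rbind, rows),
                 generations = if (length(gen_rows)) do.call(rbind, gen_rows) else NULL,
                 baselines = baselines),
            class = "dilation_campaign")
}

#' Pooled capillary-dilation study on replicate synthetic networks
#'
#' The reference in-silico experiment: generate synthetic cortical lattices,
#' run the full-model baseline, select well-balanced divergent capillary
#' bifurcations through the standard filters (balance class, centre
#' criterion, mother discharge hematocrit), dilate each daughter once, and
#' pool scenarios across replicate lattices until `n_scenarios` are
#' available. One synthetic lattice passes only a handful of candidates
#' through the filters, so pooling replicates is how the study reaches the
#' sample sizes the statistics need.
#'
#' @param seed base seed; lattice seeds, simulation seeds and the selection
#'   draws all derive from it
#' @param n_scenarios scenarios to accumulate (default 10)
#' @param variants model variants to run (default full model and
#'   no-phase-separation)
#' @param t_warmup_s,t_avg_s baseline warm-up and averaging windows (s)
#' @param target_class balance class of the selected bifurcations
#' @param max_lattices replicate cap (default 3)
#' @param ... forwarded to [synth_config()]
#' @return list `results` (pooled scenario table), `generations` (pooled
#'   per-generation changes), `n_lattices`
#' @export
run_reference_campaign <- function(seed, n_scenarios = 10,
                                   variants = c("with_rbcs", "no_phase_separation"),
                                   t_warmup_s = 2, t_avg_s = 5,
                                   target_class = "well_balanced",
                                   max_lattices = 3, ...) {
  rows <- list(); gens <- list(); got <- 0; used <- 0
  for (li in 0:(max_lattices - 1)) {
    if (got >= n_scenarios) break
    g <- generate_lattice_mvn(synth_config(seed = seed + li, ...))
    cfb <- sim_config(seed = seed * 1000 + li, variant = "with_rbcs",
                      t_warmup_s = t_warmup_s, t_avg_s = t_avg_s)
    sr <- run_simulation(g, cfb)
    rr <- classify_bifurcations(g, sr$field)
    set.seed(seed * 100 + li)
    k_bif <- ceiling((n_scenarios - got) / 2)
    sel <- suppressWarnings(
      select_candidate_bifurcations(g, sr$field, rr, target_class, k = k_bif))
    if (!length(sel)) next
    div <- rr[rr$kind == "divergent" & rr$node_id %in% sel, ]
    sites <- rbind(data.frame(node_id = div$node_id, vessel_id = div$d1),
                   data.frame(node_id = div$node_id, vessel_id = div$d2))
    camp <- run_dilation_campaign(g, cfb, sites, variants = variants)
    camp$results$lattice <- li
    rows[[length(rows) + 1]] <- camp$results
    if (!is.null(camp$generations)) {
      camp$generations$lattice <- li
      gens[[length(gens) + 1]] <- camp$generations
    }
    got <- got + nrow(sites)
    used <- used + 1
  }
  list(results = if (length(rows)) do.call(rbind, rows) else NULL,
       generations = if (length(gens)) do.call(rbind, gens) else NULL,
       n_lattices = used)
}

# carry a terminal RBC state over to the split graph: RBCs in the split
# daughter are assigned to the proximal or distal segment by arc position
remap_state_to_split <- function(state, g, g2, dves, sp) {
  e_old <- match(dves, g$vessels$vessel_id)
  prox <- attr(g2, "proximal_id"); dist <- attr(g2, "distal_id")
  e_prox <- match(prox, g2$vessels$vessel_id)
  e_dist <- match(dist, g2$vessels$vessel_id)
  # map old vessel indices to new (ids are preserved except the split one)
  map <- match(g$vessels$vessel_id, g2$vessels$vessel_id)
  new_ves <- map[state$vessel]
  new_s <- state$s
  on_split <- state$vessel == e_old
  # arc position measured from node_from; the proximal segment starts at the
  # bifurcation end, which may be either end of the original vessel
  from_bif <- g$vessels$node_from[e_old] == sp$node_id
  s_from_bif <- if (from_bif) state$s[on_split] else
    g$vessels$length_um[e_old] - state$s[on_split]
  in_prox <- s_from_bif <= sp$l_const_um
  nv <- new_ves; ns <- new_s
  nv[on_split][in_prox] <- e_prox
  ns[on_split][in_prox] <- s_from_bif[in_prox] # prox runs bif -> new node
  nv[on_split][!in_prox] <- e_dist
  ns[on_split][!in_prox] <- s_from_bif[!in_prox] - sp$l_const_um
  out <- state
  out$vessel <- as.integer(nv); out$s <- ns
  out
}
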