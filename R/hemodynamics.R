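#' Resistance-law parameters
#'
#' Bundles the plasma viscosity and the coefficient set of the empirical
#' relative-apparent-viscosity law. The default coefficient set is the
#' in vitro parameterization of Pries et al. (1992), in which the relative
#' apparent viscosity of blood in a tube of diameter D (um) at discharge
#' hematocrit H_d is
#' \deqn{\eta_{rel} = 1 + (\eta_{0.45} - 1)\frac{(1-H_d)^C - 1}{(1-0.45)^C - 1}}
#' with \eqn{\eta_{0.45} = 220 e^{-1.3D} + 3.2 - 2.44 e^{-0.06 D^{0.645}}} and
#' shape exponent
#' \eqn{C = (0.8 + e^{-0.075D})(-1 + (1 + 10^{-11} D^{12})^{-1}) + (1 + 10^{-11} D^{12})^{-1}.}
#' The coefficient set lives behind this object so an alternative
#' parameterization can be swapped in.
#'
#' @param mu_plasma_pas dynamic plasma viscosity (Pa s); a configurable model
#'   parameter, default 1.2e-3
#' @param law coefficient set name; only `"pries_invitro_1992"` is shipped
#' @return a `resistance_params` list
#' @export
resistance_params <- function(mu_plasma_pas = 1.2e-3, law = "pries_invitro_1992") {
  stopifnot(mu_plasma_pas > 0)
  law <- match.arg(law)
  structure(list(mu_plasma_pas = mu_plasma_pas, law = law),
            class = "resistance_params")
}

#' Poiseuille resistance of a plasma-filled vessel
#'
#' `128 mu L / (pi D^4)` for a circular cross-section. All arguments SI.
#'
#' @param l_m length (m)
#' @param d_m diameter (m)
#' @param mu_pas dynamic viscosity (Pa s)
#' @return resistance (Pa s / m^3); vectorized
#' @export
plasma_resistance <- function(l_m, d_m, mu_pas = 1.2e-3) {
  if (any(l_m <= 0) || any(d_m <= 0) || any(mu_pas <= 0))
    stop("value error: plasma_resistance needs positive L, D, mu")
  128 * mu_pas * l_m / (pi * d_m^4)
}

#' Relative apparent viscosity of blood (Fahraeus-Lindqvist effect)
#'
#' Evaluates the in vitro empirical viscosity law (see [resistance_params()]).
#' Equals 1 at zero hematocrit for every diameter and is minimal near
#' D = 7 um at physiological hematocrit.
#'
#' @param d_um diameter (um)
#' @param h_d discharge hematocrit in `[0, 1)`
#' @param params a [resistance_params()]
#' @return dimensionless viscosity ratio; vectorized
#' @export
relative_apparent_viscosity <- function(d_um, h_d, params = resistance_params()) {
  if (any(d_um <= 0)) stop("value error: diameter must be positive")
  if (any(h_d < 0 | h_d >= 1)) stop("value error: discharge hematocrit must be in [0, 1)")
  eta45 <- 220 * exp(-1.3 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
  cc <- (0.8 + exp(-0.075 * d_um)) * (-1 + 1 / (1 + 1e-11 * d_um^12)) +
    1 / (1 + 1e-11 * d_um^12)
  out <- 1 + (eta45 - 1) * (((1 - h_d)^cc - 1) / ((1 - 0.45)^cc - 1))
  out[h_d == 0] <- 1 # exact plasma limit
  out
}

#' Effective vessel resistance
#'
#' Plasma Poiseuille resistance multiplied by the relative apparent viscosity
#' at the vessel's discharge hematocrit. Pass `h_d = 0` for the
#' passive-particle model variant.
#'
#' @inheritParams plasma_resistance
#' @param h_d discharge hematocrit
#' @param params a [resistance_params()]
#' @return resistance (Pa s / m^3); vectorized
#' @export
effective_resistance <- function(l_m, d_m, h_d, params = resistance_params()) {
  plasma_resistance(l_m, d_m, params$mu_plasma_pas) *
    relative_apparent_viscosity(d_m / UM_M, h_d, params)
}

# Fahraeus ratio x(D) such that H_t/H_d = H_d + (1 - H_d) * x(D)
# (Pries et al. 1990). The fit exceeds 1 below D ~ 2.58 um; clamped there so
# tube hematocrit never exceeds discharge hematocrit.
fahraeus_x <- function(d_um) {
  pmin(1, 1 + 1.7 * exp(-0.415 * d_um) - 0.6 * exp(-0.011 * d_um))
}

#' Tube hematocrit from discharge hematocrit (Fahraeus effect)
#'
#' RBCs travel faster than the bulk flow, so the instantaneous (tube)
#' hematocrit is below the discharge hematocrit, most strongly in small
#' vessels. Uses the Pries et al. (1990) empirical relation
#' `H_t/H_d = H_d + (1 - H_d) x(D)`.
#'
#' @param d_um diameter (um)
#' @param h_d discharge hematocrit in `[0, 1]`
#' @return tube hematocrit; vectorized
#' @export
tube_from_discharge <- function(d_um, h_d) {
  if (any(h_d < 0 | h_d > 1)) stop("value error: hematocrit must be in [0, 1]")
  if (any(d_um <= 0)) stop("value error: diameter must be positive")
  x <- fahraeus_x(d_um)
  h_d * (h_d + (1 - h_d) * x)
}

#' Discharge hematocrit from tube hematocrit
#'
#' Exact inverse of [tube_from_discharge()]: the forward relation is quadratic
#' in the discharge hematocrit, `H_t = (1 - x) H_d^2 + x H_d`, whose relevant
#' root is returned in closed form.
#'
#' @param d_um diameter (um)
#' @param h_t tube hematocrit in `[0, 1]`
#' @return discharge hematocrit; vectorized
#' @export
discharge_from_tube <- function(d_um, h_t) {
  if (any(h_t < 0 | h_t > 1)) stop("value error: hematocrit must be in [0, 1]")
  if (any(d_um <= 0)) stop("value error: diameter must be positive")
  x <- fahraeus_x(rep_len(d_um, length(h_t)))
  h_t <- rep_len(h_t, length(x))
  out <- numeric(length(h_t))
  deg <- abs(1 - x) < 1e-12 # D below the clamp point: H_t = H_d
  out[deg] <- h_t[deg]
  a <- 1 - x[!deg]; b <- x[!deg]
  out[!deg] <- (-b + sqrt(b^2 + 4 * a * h_t[!deg])) / (2 * a)
  pmin(pmax(out, 0), 1)
}

# --- nodal pressure solve -----------------------------------------------

# Precomputed solver context: fixed sparsity pattern + cached Cholesky
# factorization; per-step only the conductance values change.
make_solver <- function(gi) {
  int_idx <- which(!gi$is_boundary)
  if (length(int_idx) == 0) stop("no interior nodes")
  nb <- sum(gi$is_boundary)
  if (nb < 2) stop("need at least two boundary nodes with pressures")
  int_of <- rep(NA_integer_, gi$n_nodes)
  int_of[int_idx] <- seq_along(int_idx)
  fi <- int_of[gi$ifrom]; ti <- int_of[gi$ito]
  nE <- gi$n_vessels
  ni <- length(int_idx)
  # triplets (upper triangle only) of the interior Laplacian:
  # diagonal +g for each interior endpoint, off-diagonal -g per interior vessel
  both <- which(!is.na(fi) & !is.na(ti))
  one_f <- which(!is.na(fi) & is.na(ti)) # to-node is boundary
  one_t <- which(is.na(fi) & !is.na(ti))
  rows <- c(fi[both], ti[both], pmin(fi[both], ti[both]), fi[one_f], ti[one_t])
  cols <- c(fi[both], ti[both], pmax(fi[both], ti[both]), fi[one_f], ti[one_t])
  vals_v <- c(both, both, both, one_f, one_t)
  sgn <- c(rep(1, 2 * length(both)), rep(-1, length(both)),
           rep(1, length(one_f) + length(one_t)))
  skel <- Matrix::sparseMatrix(i = rows, j = cols, x = rep(1, length(rows)),
                               dims = c(ni, ni), symmetric = TRUE)
  # dsCMatrix stores unique upper-triangle cells column-major; map conductances
  # onto that slot order: A@x = Tmap %*% g
  ord <- order(cols, rows)
  cell <- paste(rows[ord], cols[ord])
  uc <- !duplicated(cell)
  slot_of <- cumsum(uc)
  stopifnot(sum(uc) == length(skel@x))
  Tmap <- Matrix::sparseMatrix(i = slot_of, j = vals_v[ord], x = sgn[ord],
                               dims = c(sum(uc), nE))
  # rhs map: for boundary-adjacent vessels, rhs[interior] += g * p_bound
  r_rows <- c(fi[one_f], ti[one_t])
  r_ves <- c(one_f, one_t)
  r_p <- gi$p_bound[c(gi$ito[one_f], gi$ifrom[one_t])]
  Rmap <- Matrix::sparseMatrix(i = r_rows, j = r_ves, x = r_p, dims = c(ni, nE))
  list(int_idx = int_idx, skel = skel, Tmap = Tmap, Rmap = Rmap, chol = NULL)
}

solve_interior <- function(solver, g_cond) {
  A <- solver$skel
  A@x <- as.numeric(solver$Tmap %*% g_cond)
  b <- as.numeric(solver$Rmap %*% g_cond)
  if (is.null(solver$chol)) {
    solver$chol <- Matrix::Cholesky(A, LDL = FALSE, super = FALSE)
  } else {
    solver$chol <- Matrix::update(solver$chol, A)
  }
  p_int <- as.numeric(Matrix::solve(solver$chol, b))
  list(solver = solver, p_int = p_int)
}

#' Solve nodal pressures and vessel flows
#'
#' Imposes mass balance at every interior node with the given effective
#' resistances and Dirichlet pressures at boundary nodes, and solves the
#' resulting symmetric positive-definite sparse system (Cholesky after
#' eliminating the Dirichlet rows). Every connected component must contain a
#' boundary node, otherwise the system is singular and an error names the
#' offending component.
#'
#' @param g a `vascular_graph`
#' @param r_eff per-vessel effective resistance (Pa s / m^3), in
#'   `g$vessels` order
#' @param h_d optional per-vessel discharge hematocrit to report (default 0)
#' @return a `capflow_flow` list: `p_pa` (per node), `q` (m^3/s, signed with
#'   respect to the storage orientation `node_from -> node_to`), `v` (m/s),
#'   `r_eff`, `h_d`
#' @export
solve_pressures <- function(g, r_eff, h_d = NULL) {
  gi <- graph_index(g)
  if (length(r_eff) != gi$n_vessels) stop("r_eff must have one value per vessel")
  if (any(!is.finite(r_eff) | r_eff <= 0)) stop("value error: resistances must be finite positive")
  comp <- igraph::components(igraph::graph_from_edgelist(
    cbind(gi$ifrom, gi$ito), directed = FALSE))
  has_b <- tapply(gi$is_boundary, comp$membership[seq_len(gi$n_nodes)], any)
  if (any(!has_b))
    stop("topology error: component ", names(has_b)[!has_b][1],
         " has no boundary node; system singular")
  solver <- make_solver(gi)
  res <- solve_interior(solver, 1 / r_eff)
  p <- gi$p_bound
  p[solver$int_idx] <- res$p_int
  q <- (p[gi$ifrom] - p[gi$ito]) / r_eff
  v <- q / (gi$area * UM_M^2)
  structure(list(p_pa = p, q = q, v = v, r_eff = r_eff,
                 h_d = if (is.null(h_d)) rep(0, gi$n_vessels) else h_d),
            class = "capflow_flow")
}

#' Export a flow state as a per-vessel data frame
#'
#' @param g a `vascular_graph`
#' @param flow a `capflow_flow` from [solve_pressures()]
#' @param h_t optional per-vessel tube hematocrit
#' @return data frame `vessel_id, q, v, He_d, Ht, Re`
#' @export
flow_state_table <- function(g, flow, h_t = NULL) {
  data.frame(vessel_id = g$vessels$vessel_id, q = flow$q, v = flow$v,
             He_d = flow$h_d,
             Ht = if (is.null(h_t)) rep(NA_real_, length(flow$q)) else h_t,
             Re = flow$r_eff)
}
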