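# Transition-rate construction: every directed group transition gets
#   k_AB(x, t, l) = exp(-(dG_site(x) + drive)/2) * h_AB * f_pair(x) * p_pair(l)
# with the time-dependent Ca factor C_AB(t) applied separately in the
# reaction equations. Ratios k_AB/k_BA then equal exp(-dG_transition),
# guaranteeing microscopic reversibility.

# Directed per-site pairs receiving the tropomyosin factor h != 1.
H_DIRECTIONS <- c("WCa->T", "S1Ca->WCa", "S2Ca->S1Ca",
                  "WCa->S2Ca", "S2Ca->S2", "T->S2")

# Directed per-site pairs whose rate is multiplied by the Ca transient.
CA_DIRECTIONS <- c("T->WCa", "S2->S2Ca")

#' Calcium transient
#'
#' Intracellular Ca2+ concentration over one beat (arbitrary units): a
#' quartic rise to the peak at `T_p` followed by a Gaussian decay with
#' characteristic duration `T_d`. Continuous at `t = T_p`.
#'
#' @param t Time (ms), >= 0; vectorized.
#' @param T_p Time to peak (ms).
#' @param T_d Characteristic decay duration (ms).
#' @param amplitude Peak concentration (arbitrary units).
#' @return Concentration, same length as `t`.
#' @export
#' @examples
#' ca_transient(c(15, 30, 120), T_p = 30, T_d = 90)
ca_transient <- function(t, T_p = 30, T_d = 90, amplitude = 1) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  stopifnot(T_p > 0, T_d > 0)
  ifelse(t < T_p, amplitude * (t / T_p)^4,
         amplitude * exp(-((t - T_p) / T_d)^2))
}

#' Calcium factor of a directed per-site reaction
#'
#' The Ca-association directions `T -> W_Ca` and `S2 -> S2_Ca` are
#' multiplied by the Ca transient; every other direction of the six
#' reversible reactions has factor 1; non-adjacent pairs have factor 0
#' (no reaction).
#'
#' @param alpha,beta Per-site state labels of the directed pair.
#' @param ca Ca concentration (arbitrary units) at the evaluation time.
#' @return The multiplier (`ca`, 1, or 0).
#' @export
ca_factor <- function(alpha, beta, ca) {
  key <- paste0(alpha, "->", beta)
  if (key %in% CA_DIRECTIONS) return(ca)
  adj <- xb_adjacency()
  if (beta %in% adj[[alpha]]) 1 else 0
}

#' Tropomyosin factor of a group transition
#'
#' The tropomyosin segment-energy change of a transition is loaded onto one
#' direction of each reaction (the directions `W_Ca -> T`, `S1_Ca -> W_Ca`,
#' `S2_Ca -> S1_Ca`, `W_Ca -> S2_Ca`, `S2_Ca -> S2`, `T -> S2`), as
#' `exp(-dU_tm)`; the opposite directions have `h = 1`. The sign convention
#' is fixed by the detailed-balance requirement, which is asserted in the
#' test suite rather than re-derived.
#'
#' @param sites_A,sites_B Per-site state index vectors differing at one site.
#' @param tm A [tropomyosin_model()].
#' @param states Per-site state labels.
#' @return The (position-independent) multiplier.
#' @export
h_factor <- function(sites_A, sites_B, tm, states = XB_STATES) {
  j <- which(sites_A != sites_B)
  if (length(j) != 1L) {
    stop("states must differ at exactly one site", call. = FALSE)
  }
  alpha <- states[sites_A[j]]
  beta <- states[sites_B[j]]
  key <- paste0(alpha, "->", beta)
  if (!(key %in% H_DIRECTIONS)) return(1)
  dU <- tm_delta_U(sites_A, j, sites_B[j], tm, states)
  exp(-dU)
}

#' Nodal x-locations of the piecewise-linear rate factors
#'
#' The position-dependence `f(x)` of the four non-constant reactions is
#' continuous piecewise linear with nodes at geometrically defined
#' locations (recomputed from the current free-energy profiles): the domain
#' boundaries, the strong-state free-energy minima, the T/S1_Ca
#' free-energy intersections, the W_Ca/S2-class intersections, and (for the
#' detachment reaction) the S1_Ca minimum shifted by the positive
#' W_Ca/S2-class intersection. Node *values* are free model parameters.
#'
#' @param profiles An [energy_profiles()].
#' @param d Regulatory-unit length (nm).
#' @return Named list of sorted node x-vectors for the reactions
#'   `WCa.S1Ca`, `S1Ca.S2Ca`, `WCa.S2Ca`, `T.S2`.
#' @export
build_nodal_positions <- function(profiles, d = 36) {
  half <- d / 2
  if (profiles$G_S1_min >= 0) {
    stop("configuration error for reaction WCa.S1Ca: free energies of T and ",
         "S1Ca do not intersect (G_S1_min >= 0)", call. = FALSE)
  }
  r <- sqrt(-2 * profiles$G_S1_min / profiles$K_S1)
  ts1 <- profiles$x_S1_min + c(-r, r)
  if (profiles$G_W <= profiles$G_S2_min) {
    stop("configuration error for reaction T.S2: free energies of WCa and ",
         "the S2 states do not intersect (G_W <= G_S2_min)", call. = FALSE)
  }
  w <- sqrt(2 * (profiles$G_W - profiles$G_S2_min) / profiles$K_S2)
  nodes <- list(
    WCa.S1Ca  = c(-half, ts1[1], profiles$x_S1_min, ts1[2], half),
    S1Ca.S2Ca = c(-half, 0, ts1[2], half),
    WCa.S2Ca  = c(-half, 0, ts1[2], half),
    T.S2      = c(-half, -w, 0, w, profiles$x_S1_min + w, half)
  )
  for (nm in names(nodes)) {
    xs <- nodes[[nm]]
    if (any(xs < -half - 1e-9) || any(xs > half + 1e-9) ||
        any(diff(xs) <= 0)) {
      stop("configuration error for reaction ", nm,
           ": nodal points not strictly increasing inside [-d/2, d/2]",
           call. = FALSE)
    }
  }
  nodes
}

#' Piecewise-linear position factor
#'
#' Linear interpolation of the nodal values at `x`; outside the outermost
#' nodes the boundary node value is used (the nodes always include the
#' domain boundaries, so this only guards rounding). Direction-symmetric by
#' construction.
#'
#' @param x Position(s), nm, within `[-d/2, d/2]`.
#' @param nodes Sorted node x-locations.
#' @param values Non-negative node values (same length).
#' @return Interpolated factor, vectorized over `x`.
#' @export
f_value <- function(x, nodes, values) {
  stopifnot(length(nodes) == length(values), all(values >= 0))
  lo <- min(nodes); hi <- max(nodes)
  if (any(x < lo - 1e-6) || any(x > hi + 1e-6)) {
    stop("x outside [-d/2, d/2]", call. = FALSE)
  }
  approx(nodes, values, pmin(pmax(x, lo), hi), rule = 2)$y
}

#' Sarcomere-length factor
#'
#' Length dependence of selected reactions: kind `"L1"` (Ca association and
#' dissociation) diverges as the half-sarcomere approaches `l_min`;
#' kind `"L2"` (myosin attachment) grows as the fourth power of the relative
#' length. Both are direction-symmetric. Kind `"none"` returns 1.
#'
#' @param l Half-sarcomere length (micrometers).
#' @param kind `"none"`, `"L1"`, or `"L2"`.
#' @param p Dimensionless parameter of the chosen form.
#' @param l_min,l_max Length range (micrometers).
#' @return The multiplier.
#' @export
p_value <- function(l, kind = c("none", "L1", "L2"), p = 0,
                    l_min = 0.8, l_max = 1.1) {
  kind <- match.arg(kind)
  switch(kind,
    none = rep(1, length(l)),
    L1 = {
      if (any(l <= l_min)) {
        stop("L1 length factor is singular at l <= l_min", call. = FALSE)
      }
      1 + p * (l_max - l) / (l - l_min)
    },
    L2 = exp(p * ((l - l_min) / (l_max - l_min))^4) + 1
  )
}

# Reaction id (unordered pair key) of a directed per-site pair.
pair_key <- function(alpha, beta) {
  fwd <- vapply(XB_REACTIONS, function(r) paste(r, collapse = "."), "")
  k1 <- paste(alpha, beta, sep = ".")
  k2 <- paste(beta, alpha, sep = ".")
  out <- ifelse(k1 %in% fwd, k1, k2)
  if (any(!(out %in% fwd))) stop("not a reaction: ", k1, call. = FALSE)
  out
}

# f factor of a directed edge at positions x, given params.
edge_f <- function(alpha, beta, x, params) {
  key <- pair_key(alpha, beta)
  if (key %in% c("T.WCa", "S2.S2Ca")) {
    rep(params$rates$f_ca, length(x))
  } else {
    nodes <- params$nodal_positions[[node_key(key)]]
    f_value(x, nodes, params$rates[[paste0("f_", gsub("\\.", "_", node_key(key)))]])
  }
}

node_key <- function(key) {
  # unify the stored orientation of pair keys with nodal-position names
  switch(key,
    "WCa.S1Ca" = "WCa.S1Ca", "S1Ca.S2Ca" = "S1Ca.S2Ca",
    "WCa.S2Ca" = "WCa.S2Ca", "T.S2" = "T.S2",
    stop("no nodal positions for reaction ", key, call. = FALSE)
  )
}

# p kind and shared parameter of a reaction pair key.
pair_p <- function(key, params) {
  if (key %in% c("T.WCa", "S2.S2Ca")) {
    list(kind = "L1", p = params$rates$p_L1)
  } else if (key == "WCa.S1Ca") {
    list(kind = "L2", p = params$rates$p_L2)
  } else {
    list(kind = "none", p = 0)
  }
}

#' Directed rate constant of a group transition
#'
#' Product of the symmetric per-site free-energy factor
#' `exp(-(G_beta(x) - G_alpha(x) + drive)/2)`, the tropomyosin factor `h`,
#' the position factor `f(x)` and the length factor `p(l)`. The Ca factor is
#' not included (it multiplies the rate in the reaction equations).
#'
#' @param sites_A,sites_B Per-site state index vectors differing at one
#'   allowed site change.
#' @param x Position(s), nm.
#' @param l Half-sarcomere length (micrometers).
#' @param params An `xb_params` object (see [default_params()]).
#' @return Rate constant (1/ms), vectorized over `x`.
#' @export
rate_constant <- function(sites_A, sites_B, x, l, params) {
  j <- which(sites_A != sites_B)
  if (length(j) != 1L) {
    stop("states must differ at exactly one site", call. = FALSE)
  }
  alpha <- XB_STATES[sites_A[j]]
  beta <- XB_STATES[sites_B[j]]
  profiles <- xb_profiles(params)
  tm <- xb_tm(params)
  dG_site <- state_free_energy(beta, x, profiles) -
    state_free_energy(alpha, x, profiles) +
    drive_term(alpha, beta, params$drive)
  key <- pair_key(alpha, beta)
  pp <- pair_p(key, params)
  exp(-dG_site / 2) * h_factor(sites_A, sites_B, tm) *
    edge_f(alpha, beta, x, params) *
    p_value(l, pp$kind, pp$p, params$l_min, params$l_max)
}
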