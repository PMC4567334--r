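# Free energies: tropomyosin segment elasticity, cross-bridge state
# profiles, group free energies, and per-state forces.
#
# Internal energy unit is RT (dimensionless after division by RT at the
# model temperature); positions are in nm. SI conversions happen in the
# observables only.

# Boltzmann constant (J/K) and Avogadro constant (1/mol)
.kB <- 1.380649e-23
.NA_const <- 6.02214076e23
.R_gas <- 8.31446261815324

#' Tropomyosin elasticity model
#'
#' Segment elastic energies of the tropomyosin string between neighboring
#' cross-bridge sites, over the three tropomyosin position classes
#' (`T` blocked, `W` Ca-open, `S` myosin-shifted). Energies are stored
#' relative to the relaxed (straight) tropomyosin baseline `U_tr`, which
#' cancels in every transition difference and therefore never enters the
#' kinetics; it is computed and reported for reference.
#'
#' @param U_TW Elastic energy of a segment spanning a T|W position change
#'   (RT units, >= 0).
#' @param U_WS Elastic energy of a segment spanning a W|S position change
#'   (RT units, >= 0).
#' @param K_tr Stiffness of a single tropomyosin (pN/nm).
#' @param d Regulatory-unit length (nm).
#' @param temperature Absolute temperature (K).
#' @return An object of class `xb_tm` with the inputs, the derived relaxed
#'   energy `U_tr` (RT), and the symmetric 3x3 segment energy table.
#' @export
#' @examples
#' tm <- tropomyosin_model()
#' tm$U_tr          # ~3270 RT at 310 K
#' segment_energy("T", "S", tm)
tropomyosin_model <- function(U_TW = 0.1, U_WS = 0.05, K_tr = 21.6,
                              d = 36, temperature = 310) {
  stopifnot(U_TW >= 0, U_WS >= 0, K_tr > 0, d > 0, temperature > 0)
  # Relaxed elastic energy per mole: N_A * K_tr * d^2 / 2, divided by RT.
  # K_tr pN/nm = 1e-3 N/m; d nm = 1e-9 m.
  U_tr_J <- (K_tr * 1e-3) * (d * 1e-9)^2 / 2
  U_tr <- .NA_const * U_tr_J / (.R_gas * temperature)
  U_TS <- (U_TW^0.25 + U_WS^0.25)^4
  tab <- matrix(0, 3, 3, dimnames = list(c("T", "W", "S"), c("T", "W", "S")))
  tab["T", "W"] <- tab["W", "T"] <- U_TW
  tab["W", "S"] <- tab["S", "W"] <- U_WS
  tab["T", "S"] <- tab["S", "T"] <- U_TS
  structure(list(U_TW = U_TW, U_WS = U_WS, K_tr = K_tr, d = d,
                 temperature = temperature, U_tr = U_tr, table = tab),
            class = "xb_tm")
}

#' Tropomyosin segment energy
#'
#' Elastic energy (above the relaxed baseline) of a tropomyosin fragment
#' whose endpoints sit at position classes `pos_a` and `pos_b`. Equal
#' positions cost nothing; `U(T,S)` follows from the fragment geometry: the
#' elongation energy scales as displacement^4 in the small-displacement
#' limit and the T-to-S displacement is the sum of the T-to-W and W-to-S
#' displacements, giving the fourth-root addition rule.
#'
#' @param pos_a,pos_b Position class labels, each one of `"T"`, `"W"`, `"S"`.
#' @param tm A [tropomyosin_model()].
#' @return Energy in RT units.
#' @export
segment_energy <- function(pos_a, pos_b, tm) {
  if (!all(c(pos_a, pos_b) %in% c("T", "W", "S"))) {
    stop("tropomyosin position labels must be in {T, W, S}", call. = FALSE)
  }
  tm$table[pos_a, pos_b]
}

# Exact segment energy for the T|S fragment from the fragment geometry
# (elongation l = d(1 + sqrt(U/U_tr)); displacement^2 = l^2 - d^2;
# displacements add for T->S). Used as the oracle for the fourth-root
# approximation.
segment_energy_TS_exact <- function(U_TW, U_WS, U_tr) {
  s <- sqrt(U_TW / U_tr + 2 * sqrt(U_TW / U_tr)) +
       sqrt(U_WS / U_tr + 2 * sqrt(U_WS / U_tr))
  U_tr * (sqrt(1 + s^2) - 1)^2
}

#' Group tropomyosin energy
#'
#' Sum of the segment energies of the `q + 1` tropomyosin fragments spanned
#' by a cross-bridge group, including the two fragments to the permanently
#' unbound (`T`) boundary sites. Independent of cross-bridge position.
#'
#' @param sites Integer vector of per-site state indices.
#' @param tm A [tropomyosin_model()].
#' @param states Per-site state labels.
#' @return Energy in RT units.
#' @export
group_tm_energy <- function(sites, tm, states = XB_STATES) {
  pos <- tm_positions(states)[sites]
  seq_pos <- c("T", pos, "T")
  tot <- 0
  for (i in seq_len(length(seq_pos) - 1L)) {
    tot <- tot + tm$table[seq_pos[i], seq_pos[i + 1L]]
  }
  tot
}

tm_positions <- function(states = XB_STATES) {
  if (identical(states, c("T", "W", "S"))) {
    c("T", "W", "S")
  } else {
    unname(XB_TM_POS[states])
  }
}

#' Cross-bridge free-energy profiles
#'
#' Basic free energies of the five per-site states as functions of
#' cross-bridge position `x` (nm). `T` is the reference (`G = 0`), `W_Ca` is
#' constant, and the strong-binding states have quadratic profiles (linear
#' force): `G_S1(x) = G_S1_min + K_S1/2 (x - x_S1_min)^2` and, shared by
#' `S2_Ca` and `S2`, `G_S2(x) = G_S2_min + K_S2/2 x^2` with its minimum at
#' the model origin.
#'
#' @param G_W Free energy of `W_Ca` (RT).
#' @param G_S1_min,x_S1_min Value (RT) and location (nm, relative to the S2
#'   minimum) of the `S1_Ca` minimum.
#' @param K_S1 Quadratic stiffness of `S1_Ca` (RT/nm^2).
#' @param G_S2_min Minimum free energy of the S2-class states (RT).
#' @param K_S2 Quadratic stiffness of the S2-class states (RT/nm^2).
#' @return An object of class `xb_profiles`.
#' @export
energy_profiles <- function(G_W = 1, G_S1_min = -2, x_S1_min = 4,
                            K_S1 = 1, G_S2_min = -4, K_S2 = 0.5) {
  stopifnot(K_S1 > 0, K_S2 > 0)
  structure(list(G_W = G_W, G_S1_min = G_S1_min, x_S1_min = x_S1_min,
                 K_S1 = K_S1, G_S2_min = G_S2_min, K_S2 = K_S2),
            class = "xb_profiles")
}

#' Per-site state free energy
#'
#' @param state State label (or vector of labels).
#' @param x Cross-bridge position(s), nm.
#' @param profiles An [energy_profiles()].
#' @return Free energy in RT; vectorized over `x` (for scalar `state`) or
#'   over `state` (for scalar `x`).
#' @export
state_free_energy <- function(state, x, profiles) {
  g1 <- function(s) {
    switch(s,
      "T" = rep(0, length(x)),
      "WCa" = rep(profiles$G_W, length(x)),
      "W" = rep(profiles$G_W, length(x)),
      "S1Ca" = profiles$G_S1_min +
        profiles$K_S1 / 2 * (x - profiles$x_S1_min)^2,
      "S2Ca" = profiles$G_S2_min + profiles$K_S2 / 2 * x^2,
      "S2" = profiles$G_S2_min + profiles$K_S2 / 2 * x^2,
      "S" = profiles$G_S2_min + profiles$K_S2 / 2 * x^2,
      stop("unknown state label: ", s, call. = FALSE)
    )
  }
  if (length(state) == 1L) g1(state) else vapply(state, function(s) g1(s)[1], 0)
}

#' Per-site state force
#'
#' Force is the position derivative of the free-energy profile:
#' zero for `T` and `W_Ca`, linear in `x` for the strong states.
#'
#' @inheritParams state_free_energy
#' @param units `"RT/nm"` (default) or `"pN"`.
#' @param temperature Temperature (K), used for the pN conversion.
#' @return Force, vectorized over `x`.
#' @export
state_force <- function(state, x, profiles, units = c("RT/nm", "pN"),
                        temperature = 310) {
  units <- match.arg(units)
  f <- switch(state,
    "T" = rep(0, length(x)),
    "WCa" = rep(0, length(x)),
    "W" = rep(0, length(x)),
    "S1Ca" = profiles$K_S1 * (x - profiles$x_S1_min),
    "S2Ca" = profiles$K_S2 * x,
    "S2" = profiles$K_S2 * x,
    "S" = profiles$K_S2 * x,
    stop("unknown state label: ", state, call. = FALSE)
  )
  if (units == "pN") f * pN_per_RT_nm(temperature) else f
}

# 1 RT/nm expressed in pN at temperature T.
pN_per_RT_nm <- function(temperature) {
  .kB * temperature / 1e-9 * 1e12
}

#' Group free energy
#'
#' Conformational free energy of a group state at common cross-bridge
#' position `x`: the tropomyosin energy of the state plus the sum of the
#' per-site profiles. The ATP chemical drive is not part of this quantity;
#' it enters only the transition free-energy differences of the
#' hydrolysis-counted reactions (see [transition_delta_G()]).
#'
#' @param sites Integer vector of per-site state indices.
#' @param x Position (nm), within `[-d/2, d/2]`.
#' @param profiles An [energy_profiles()].
#' @param tm A [tropomyosin_model()].
#' @param states Per-site state labels.
#' @return Free energy in RT, vectorized over `x`.
#' @export
group_free_energy <- function(sites, x, profiles, tm, states = XB_STATES) {
  if (any(x < -tm$d / 2 - 1e-9) || any(x > tm$d / 2 + 1e-9)) {
    stop("x out of range [-d/2, d/2]", call. = FALSE)
  }
  g <- rep(group_tm_energy(sites, tm, states), length(x))
  for (j in seq_along(sites)) {
    g <- g + state_free_energy(states[sites[j]], x, profiles)
  }
  g
}

# Directed per-site reactions counted as ATP hydrolysis (detachment
# direction): completing one of these consumes one ATP.
HYDROLYSIS_DIR <- c("S2->T", "S2Ca->WCa")

# Chemical drive (RT) carried by a directed per-site reaction: -drive for
# the hydrolysis (detachment) direction, +drive for its reverse, 0 otherwise.
drive_term <- function(alpha, beta, drive) {
  key <- paste0(alpha, "->", beta)
  rev_key <- paste0(beta, "->", alpha)
  if (key %in% HYDROLYSIS_DIR) -drive
  else if (rev_key %in% HYDROLYSIS_DIR) drive
  else 0
}

#' Transition free-energy difference
#'
#' Free-energy change of a single-site group transition at position `x`:
#' the per-site profile difference, plus the tropomyosin segment-energy
#' change of the two fragments adjacent to the reacting site, plus (for the
#' two hydrolysis-counted reactions `S2 -> T` and `S2_Ca -> W_Ca`) the ATP
#' chemical drive `-delta_drive` in the detachment direction. Rate-constant
#' ratios equal `exp(-delta G)` for every reaction (microscopic
#' reversibility); with `delta_drive = 0` the value equals
#' `group_free_energy(B) - group_free_energy(A)` exactly.
#'
#' @param sites_A,sites_B Per-site state index vectors of the source and
#'   destination group states (must differ at exactly one site by an
#'   allowed reaction).
#' @param x Position (nm).
#' @param profiles An [energy_profiles()].
#' @param tm A [tropomyosin_model()].
#' @param delta_drive ATP chemical drive in RT (>= 0). Default 0.
#' @param states Per-site state labels.
#' @return Delta G in RT, vectorized over `x`.
#' @export
transition_delta_G <- function(sites_A, sites_B, x, profiles, tm,
                               delta_drive = 0, states = XB_STATES) {
  j <- which(sites_A != sites_B)
  if (length(j) != 1L) {
    stop("states must differ at exactly one site", call. = FALSE)
  }
  alpha <- states[sites_A[j]]
  beta <- states[sites_B[j]]
  adj <- xb_adjacency(states)
  if (!(beta %in% adj[[alpha]])) {
    stop("(", alpha, " -> ", beta, ") is not an allowed reaction",
         call. = FALSE)
  }
  dU <- tm_delta_U(sites_A, j, match(beta, states), tm, states)
  state_free_energy(beta, x, profiles) -
    state_free_energy(alpha, x, profiles) +
    dU + drive_term(alpha, beta, delta_drive)
}

# Tropomyosin segment-energy change for flipping site j of `sites` to
# per-site state index `beta_idx`; boundary neighbors are T.
tm_delta_U <- function(sites, j, beta_idx, tm, states = XB_STATES) {
  pos <- tm_positions(states)
  q <- length(sites)
  left <- if (j == 1L) "T" else pos[sites[j - 1L]]
  right <- if (j == q) "T" else pos[sites[j + 1L]]
  pa <- pos[sites[j]]
  pb <- pos[beta_idx]
  tm$table[left, pb] + tm$table[pb, right] -
    tm$table[left, pa] - tm$table[pa, right]
}
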