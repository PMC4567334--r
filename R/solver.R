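# Advection-reaction solver for the group-state fractions n_A(x, t).
#
# The reaction part is linear in n with two time/length-dependent scalar
# multipliers (the Ca transient on the two Ca-association directions and
# the length factors p_L1/p_L2 on their reactions), so the generator is
# assembled once as four sparse flow matrices over the stacked index
# (group state, grid point) and combined at evaluation time:
#   dn/dt = [ L0 + pL1(l) L1r + pL2(l) L2 + Ca(t) pL1(l) L1ca ] n
# Advection by filament sliding is applied as a first-order upwind shift in
# an operator-split step (Lie splitting at the 1 ms output cadence).

#' Cross-bridge position grid
#'
#' Uniform grid over one regulatory-unit period `[-d/2, d/2)`; the domain is
#' periodic (the nearest-site parameterization wraps as the filaments
#' slide).
#'
#' @param n_points Number of grid points (>= 16).
#' @param d Regulatory-unit length (nm).
#' @return List with `x` (nm), `dx` (nm), `n_points`, `d`.
#' @export
x_grid <- function(n_points = 72, d = 36) {
  stopifnot(n_points >= 16)
  dx <- d / n_points
  list(x = -d / 2 + dx * (seq_len(n_points) - 1L), dx = dx,
       n_points = as.integer(n_points), d = d)
}

#' Assemble the rate system
#'
#' Precomputes, for a parameter set and position grid, the group-state
#' enumeration, the directed transition table, the per-edge rate constants
#' on the grid, the sparse reaction flow matrices, the per-state force
#' table, and the ATP-flux extraction vector.
#'
#' @param params An `xb_params` object.
#' @param n_points Grid resolution (default 72, i.e. 0.5 nm spacing).
#' @param x Optional explicit position vector (nm) overriding the uniform
#'   grid (used for point-wise verification and the stochastic oracle).
#' @return An object of class `xb_rate_system`.
#' @export
build_rate_system <- function(params, n_points = 72, x = NULL) {
  grid <- if (is.null(x)) {
    x_grid(n_points, params$d)
  } else {
    list(x = x, dx = params$d / length(x), n_points = length(x),
         d = params$d)
  }
  n_points <- grid$n_points
  q <- params$q
  ns <- 5L^q
  gs <- enumerate_group_states(q)
  trans <- group_transition_table(q)
  ne <- nrow(trans)
  profiles <- xb_profiles(params)
  tm <- xb_tm(params)

  # per-state free energies and forces on the grid
  G_site <- vapply(XB_STATES,
                   function(s) state_free_energy(s, grid$x, profiles),
                   numeric(n_points))              # nx x 5
  F_site <- vapply(XB_STATES,
                   function(s) state_force(s, grid$x, profiles),
                   numeric(n_points))              # nx x 5, RT/nm
  if (!is.matrix(G_site)) G_site <- matrix(G_site, nrow = 1L)
  if (!is.matrix(F_site)) F_site <- matrix(F_site, nrow = 1L)

  # per-edge static pieces
  h <- numeric(ne)
  drv <- numeric(ne)
  grp <- integer(ne)   # 1 = Ca&L1, 2 = 1&L1, 3 = 1&L2, 4 = rest
  fmat <- matrix(0, ne, n_points)
  for (e in seq_len(ne)) {
    A <- gs[trans$from[e], ]
    B <- gs[trans$to[e], ]
    h[e] <- h_factor(A, B, tm)
    drv[e] <- drive_term(trans$alpha[e], trans$beta[e], params$drive)
    key <- paste0(trans$alpha[e], "->", trans$beta[e])
    pk <- pair_p(pair_key(trans$alpha[e], trans$beta[e]), params)
    grp[e] <- if (key %in% CA_DIRECTIONS) 1L
              else if (pk$kind == "L1") 2L
              else if (pk$kind == "L2") 3L else 4L
    fmat[e, ] <- edge_f(trans$alpha[e], trans$beta[e], grid$x, params)
  }
  ai <- match(trans$alpha, XB_STATES)
  bi <- match(trans$beta, XB_STATES)
  # k0[e, i]: rate constant without C and p factors
  dG <- t(G_site)[bi, , drop = FALSE] - t(G_site)[ai, , drop = FALSE] + drv
  k0 <- exp(-dG / 2) * h * fmat

  # Pairwise rate cap: the symmetric factor exp(-dG/2) grows without bound
  # at extreme strain where the quadratic profiles are tens of RT. Both
  # directions of a reaction are scaled by the same factor so every rate
  # stays below `rate_cap` (1/ms) while the forward/backward ratio -- and
  # hence every equilibrium and the detailed-balance property -- is
  # preserved exactly. The cap only bites where occupancancy is negligible.
  rate_cap <- if (is.null(params$rate_cap)) 1e3 else params$rate_cap
  if (is.finite(rate_cap)) {
    rev_idx <- match(paste(trans$to, trans$from, trans$site),
                     paste(trans$from, trans$to, trans$site))
    scale <- pmin(1, rate_cap / pmax(k0, k0[rev_idx, , drop = FALSE]))
    k0 <- k0 * scale
  }

  # sparse flow matrices over stacked index (state A, grid i)
  n_tot <- ns * n_points
  flow <- function(sel) {
    if (!any(sel)) {
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(n_tot, n_tot)))
    }
    es <- which(sel)
    i_idx <- integer(0); j_idx <- integer(0); vals <- numeric(0)
    for (e in es) {
      cols <- (seq_len(n_points) - 1L) * ns + trans$from[e]
      rows <- (seq_len(n_points) - 1L) * ns + trans$to[e]
      i_idx <- c(i_idx, rows, cols)
      j_idx <- c(j_idx, cols, cols)
      vals <- c(vals, k0[e, ], -k0[e, ])
    }
    Matrix::sparseMatrix(i = i_idx, j = j_idx, x = vals, dims = c(n_tot, n_tot))
  }
  L1ca <- flow(grp == 1L)
  L1r <- flow(grp == 2L)
  L2 <- flow(grp == 3L)
  L0 <- flow(grp == 4L)

  # per-group-state force on the grid (sum over sites), RT/nm: ns x nx
  Fg <- matrix(0, ns, n_points)
  for (j in seq_len(q)) Fg <- Fg + t(F_site)[gs[, j], , drop = FALSE]

  # ATP flux extraction vector: hydrolysis-direction edges positive.
  # Those reactions carry neither Ca nor length factors, so the flux
  # weights are time- and length-independent.
  watp <- numeric(n_tot)
  hyd <- paste0(trans$alpha, "->", trans$beta) %in% HYDROLYSIS_DIR
  rev_hyd <- paste0(trans$beta, "->", trans$alpha) %in% HYDROLYSIS_DIR
  for (e in which(hyd)) {
    idx <- (seq_len(n_points) - 1L) * ns + trans$from[e]
    watp[idx] <- watp[idx] + k0[e, ]
  }
  for (e in which(rev_hyd)) {
    idx <- (seq_len(n_points) - 1L) * ns + trans$from[e]
    watp[idx] <- watp[idx] - k0[e, ]
  }

  structure(list(
    params = params, grid = grid, ns = ns, q = q, states = gs, trans = trans,
    k0 = k0, grp = grp, L1ca = L1ca, L1r = L1r, L2 = L2, L0 = L0,
    force = Fg, watp = watp
  ), class = "xb_rate_system")
}

#' Diastolic initial density
#'
#' All groups fully unbound: `n_(T,...,T)(x) = 1` for every grid point.
#'
#' @param rs An [build_rate_system()] object.
#' @return Matrix `ns` x `n_points`.
#' @export
init_density <- function(rs) {
  n <- matrix(0, rs$ns, rs$grid$n_points)
  n[1L, ] <- 1
  n
}

# Length factors of a rate system at half-sarcomere length l.
length_factors <- function(rs, l) {
  p <- rs$params
  list(p1 = p_value(l, "L1", p$rates$p_L1, p$l_min, p$l_max),
       p2 = p_value(l, "L2", p$rates$p_L2, p$l_min, p$l_max))
}

#' Reaction time-derivative
#'
#' Right-hand side of the reaction part at clamped Ca and length; column
#' sums are zero to machine precision (pairwise flux cancellation).
#'
#' @param n Density matrix (`ns` x `n_points`).
#' @param rs Rate system.
#' @param ca Ca concentration (arbitrary units).
#' @param l Half-sarcomere length (um).
#' @return Derivative matrix, same shape as `n`.
#' @export
reaction_deriv <- function(n, rs, ca, l) {
  pf <- length_factors(rs, l)
  y <- as.vector(n)
  dy <- as.vector(rs$L0 %*% y) + pf$p1 * as.vector(rs$L1r %*% y) +
    pf$p2 * as.vector(rs$L2 %*% y) + ca * pf$p1 * as.vector(rs$L1ca %*% y)
  matrix(dy, rs$ns, rs$grid$n_points)
}

# Integrate the reaction part over [t0, t1] at frozen length l, with Ca
# given by ca_fun(t) (or a constant). Returns densities at `times_out`
# (including t1); matrix list. Uses the sparse stiff integrator.
integrate_reaction <- function(rs, n0, t0, t1, l, ca_fun,
                               times_out = NULL, rtol = 1e-8, atol = 1e-10) {
  if (any(!is.finite(n0))) {
    stop("non-finite entries in the initial density", call. = FALSE)
  }
  if (is.numeric(ca_fun)) {
    ca_val <- ca_fun
    ca_fun <- function(t) ca_val
  }
  pf <- length_factors(rs, l)
  Lfix <- rs$L0 + pf$p1 * rs$L1r + pf$p2 * rs$L2
  Lca <- pf$p1 * rs$L1ca
  func <- function(t, y, parms) {
    list(as.vector(Lfix %*% y) + ca_fun(t) * as.vector(Lca %*% y))
  }
  times <- unique(sort(c(t0, times_out, t1)))
  out <- deSolve::lsodes(y = as.vector(n0), times = times, func = func,
                         parms = NULL, rtol = rtol, atol = atol,
                         maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0) {
    stop("reaction integrator failed at t = ", utils::tail(out[, 1], 1),
         ", state norm ", signif(max(abs(utils::tail(out, 1)[-1])), 4),
         call. = FALSE)
  }
  # renormalize column sums (drift guard; drift is ~integrator tolerance)
  drift <- 0
  res <- lapply(seq_len(nrow(out)), function(i) {
    m <- matrix(out[i, -1], rs$ns, rs$grid$n_points)
    sums <- colSums(m)
    drift <<- max(drift, max(abs(sums - 1)))
    sweep(m, 2L, sums, "/")
  })
  names(res) <- format(out[, 1])
  attr(res, "times") <- out[, 1]
  attr(res, "max_drift") <- drift
  res
}

# Backward-Euler reaction advance over one short interval (the isotonic
# solve's inner step). The reaction system is linear, so each substep is a
# sparse solve against a cached LU factor; backward Euler with a generator
# matrix conserves column sums exactly (1' A = 0) and preserves positivity
# ((I - hA) is an M-matrix). Ca is frozen at the interval midpoint, which
# for 1 ms intervals is far below the transient's timescale.
reaction_step_implicit <- function(rs, n, t0, dt, l, ca_fun, nsub = 4) {
  pf <- length_factors(rs, l)
  A <- rs$L0 + pf$p1 * rs$L1r + pf$p2 * rs$L2 +
    (ca_fun(t0 + dt / 2) * pf$p1) * rs$L1ca
  h <- dt / nsub
  M <- Matrix::Diagonal(nrow(A)) - h * A
  fac <- Matrix::lu(M)
  y <- as.vector(n)
  # Backward-Euler-consistent quadrature of the hydrolysis flux: h * w * y
  # evaluated at the end of each substep equals exactly the mass the step
  # removes through a fast edge, so stiff detachment bursts (freshly
  # advected mass in ~10^2/ms bins) are counted once, not oversampled.
  atp <- 0
  for (s in seq_len(nsub)) {
    y <- as.vector(Matrix::solve(fac, y))
    atp <- atp + h * sum(rs$watp * y)
  }
  out <- matrix(y, rs$ns, rs$grid$n_points)
  attr(out, "atp_step") <- atp * rs$grid$dx / rs$grid$d / rs$q
  out
}

#' Upwind advection step
#'
#' Shifts every state's position profile by `v * dt` using first-order
#' upwind differencing on the periodic grid, sub-stepping internally so the
#' CFL number of each sub-step is at most 1 (at CFL exactly 1 the shift is
#' exact). Total mass per state is conserved exactly.
#'
#' @param n Density matrix (`ns` x `n_points`).
#' @param v Lengthening rate (nm/ms); positive v moves cross-bridge
#'   positions towards larger x.
#' @param dt Time step (ms).
#' @param grid An [x_grid()].
#' @return Advected density matrix.
#' @export
advect <- function(n, v, dt, grid) {
  if (v == 0 || dt == 0) return(n)
  shift <- v * dt / grid$dx          # cells moved
  nsub <- max(1L, ceiling(abs(shift)))
  c_sub <- shift / nsub              # |c_sub| <= 1
  nx <- grid$n_points
  if (c_sub > 0) {
    prev <- c(nx, seq_len(nx - 1L))
    for (s in seq_len(nsub)) n <- n - c_sub * (n - n[, prev, drop = FALSE])
  } else {
    nxt <- c(seq_len(nx)[-1L], 1L)
    for (s in seq_len(nsub)) n <- n + c_sub * (n - n[, nxt, drop = FALSE])
  }
  n
}

#' Steady-state density at clamped calcium
#'
#' Solves, independently at each grid point, the linear balance of the
#' group-state chain at constant Ca and length (v = 0), replacing one
#' balance row by the normalization constraint. For a reducible chain
#' (e.g. Ca = 0) the unique stationary distribution of the recurrent set is
#' still returned by the linear solve; if the solve is singular the all-T
#' diastolic solution is returned with a warning.
#'
#' @param rs Rate system.
#' @param ca Clamped Ca concentration (>= 0, arbitrary units).
#' @param l Half-sarcomere length (um).
#' @return Density matrix (`ns` x `n_points`).
#' @export
steady_state <- function(rs, ca, l) {
  stopifnot(ca >= 0)
  ns <- rs$ns
  nx <- rs$grid$n_points
  pf <- length_factors(rs, l)
  mult <- c(ca * pf$p1, pf$p1, pf$p2, 1)[rs$grp]
  out <- matrix(0, ns, nx)
  tr <- rs$trans
  for (i in seq_len(nx)) {
    k <- rs$k0[, i] * mult
    M <- matrix(0, ns, ns)
    for (e in seq_len(nrow(tr))) {
      M[tr$to[e], tr$from[e]] <- M[tr$to[e], tr$from[e]] + k[e]
      M[tr$from[e], tr$from[e]] <- M[tr$from[e], tr$from[e]] - k[e]
    }
    M[ns, ] <- 1
    b <- c(rep(0, ns - 1L), 1)
    sol <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol))) {
      warning("singular group-state chain at ca = ", ca,
              "; returning the all-T solution", call. = FALSE)
      sol <- c(1, rep(0, ns - 1L))
    }
    out[, i] <- sol
  }
  out
}

#' Detailed-balance check of an assembled rate system
#'
#' Maximum over all directed transition pairs and all grid positions of
#' `|ln(k_AB / k_BA) + delta G_{A->B}|`, where delta G is the transition
#' free-energy difference (tropomyosin terms and ATP drive included).
#' Microscopic reversibility requires this to vanish; the assembled system
#' satisfies it to machine precision by construction, including under the
#' pairwise rate cap.
#'
#' @param rs Rate system.
#' @return Maximum absolute violation (dimensionless, RT units).
#' @export
detailed_balance_error <- function(rs) {
  tr <- rs$trans
  params <- rs$params
  profiles <- xb_profiles(params)
  tm <- xb_tm(params)
  rev_idx <- match(paste(tr$to, tr$from, tr$site),
                   paste(tr$from, tr$to, tr$site))
  worst <- 0
  gs <- rs$states
  for (e in seq_len(nrow(tr))) {
    dG <- transition_delta_G(gs[tr$from[e], ], gs[tr$to[e], ], rs$grid$x,
                             profiles, tm, delta_drive = params$drive)
    viol <- max(abs(log(rs$k0[e, ] / rs$k0[rev_idx[e], ]) + dG))
    worst <- max(worst, viol)
  }
  worst
}

# Dense per-x generator (with Ca and length factors applied), used by the
# stochastic oracle and by small verification utilities.
# Returns ns x ns matrix M with M[to, from] the directed rate (1/ms).
rate_matrix_at <- function(rs, ix, ca, l) {
  pf <- length_factors(rs, l)
  mult <- c(ca * pf$p1, pf$p1, pf$p2, 1)[rs$grp]
  k <- rs$k0[, ix] * mult
  M <- matrix(0, rs$ns, rs$ns)
  tr <- rs$trans
  for (e in seq_len(nrow(tr))) {
    M[tr$to[e], tr$from[e]] <- M[tr$to[e], tr$from[e]] + k[e]
  }
  M
}
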