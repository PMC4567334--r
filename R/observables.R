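# Mechanical and energetic observables: Cauchy stress, ATP turnover,
# twitch protocols, stress-strain area, force-Ca curves and Hill slopes.

#' Cauchy stress of a density
#'
#' Active stress developed by the cross-bridge population:
#' `sigma = pref * (1/d) * sum_A integral n_A(x) F_A(x) dx`, with the
#' prefactor `m l / 2` (default, `eq45` mode) or `m l` (`eq28` mode), where
#' `m = c_myosin * N_A` is the cross-bridge number density and `l` the
#' half-sarcomere length. Group force integrals are divided by `q` so the
#' reported stress is per cross-bridge and directly comparable across group
#' sizes.
#'
#' @param n Density matrix (`ns` x `n_points`).
#' @param l Half-sarcomere length (um).
#' @param rs Rate system.
#' @return Stress in kPa.
#' @export
cauchy_stress <- function(n, l, rs) {
  p <- rs$params
  m <- p$c_myosin * .NA_const                    # 1/m^3
  pref <- switch(p$stress_prefactor_mode,
                 eq45 = m * (l * 1e-6) / 2,
                 eq28 = m * (l * 1e-6))
  f_pN <- rs$force * pN_per_RT_nm(p$temperature) # ns x nx, pN
  integral <- sum(n * f_pN) * 1e-12 * (rs$grid$dx * 1e-9)  # N m
  pref / (p$d * 1e-9) * integral / rs$q / 1000   # kPa
}

#' Per-cross-bridge ATP consumption rate
#'
#' Net flux through the two hydrolysis-counted reactions (`S2 -> T` and
#' `S2_Ca -> W_Ca`, detachment positive), integrated over position and
#' divided by the regulatory-unit length and by `q` (rate per cross-bridge).
#' Those reactions carry neither Ca nor length factors, so the rate depends
#' only on the current density.
#'
#' @param n Density matrix.
#' @param rs Rate system.
#' @return ATP consumption rate (1/ms per cross-bridge).
#' @export
atp_rate <- function(n, rs) {
  sum(rs$watp * as.vector(n)) * rs$grid$dx / rs$grid$d / rs$q
}

#' ATP consumed per beat
#'
#' Trapezoidal time integral of the per-cross-bridge ATP rate over the
#' beat.
#'
#' @param t Time base (ms).
#' @param v_atp ATP rate series (1/ms).
#' @return ATP molecules per myosin head per beat.
#' @export
atp_per_beat <- function(t, v_atp) {
  if (length(t) < 2L) stop("incomplete beat", call. = FALSE)
  sum(diff(t) * (head(v_atp, -1) + tail(v_atp, -1)) / 2)
}

new_twitch <- function(t, sigma, l, v, v_atp, params) {
  structure(list(t = t, sigma = sigma, l = l, v = v, v_atp = v_atp,
                 atp_per_beat = atp_per_beat(t, v_atp),
                 peak_stress = max(sigma), params = params),
            class = "xb_twitch")
}

#' @export
print.xb_twitch <- function(x, ...) {
  cat("<xb_twitch>", length(x$t), "samples over", max(x$t), "ms\n")
  cat("  peak stress", signif(x$peak_stress, 4), "kPa;",
      "min length", signif(min(x$l), 4), "um;",
      "ATP/beat", signif(x$atp_per_beat, 4), "\n")
  invisible(x)
}

#' Isometric twitch
#'
#' Integrates one beat at fixed half-sarcomere length with the Ca
#' transient; the lengthening rate is identically zero.
#'
#' @param params An `xb_params` object.
#' @param l Half-sarcomere length (um); defaults to `params$l_ed`.
#' @param n_points Grid resolution.
#' @param dt_out Output cadence (ms).
#' @param rs Optional pre-built rate system (must match `params`).
#' @param rtol,atol Integration tolerances.
#' @return An `xb_twitch` object.
#' @export
run_isometric <- function(params, l = params$l_ed, n_points = 72,
                          dt_out = 1, rs = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  if (is.null(rs)) rs <- build_rate_system(params, n_points)
  ca_fun <- function(t) ca_transient(t, params$ca$T_p, params$ca$T_d,
                                     params$ca$amplitude)
  times <- seq(0, params$beat_period, by = dt_out)
  traj <- integrate_reaction(rs, init_density(rs), 0, params$beat_period,
                             l, ca_fun, times_out = times,
                             rtol = rtol, atol = atol)
  sigma <- vapply(traj, cauchy_stress, 0, l = l, rs = rs)
  vatp <- vapply(traj, atp_rate, 0, rs = rs)
  tw <- new_twitch(attr(traj, "times"), sigma, rep(l, length(traj)),
                   rep(0, length(traj)), vatp, params)
  tw$final_density <- traj[[length(traj)]]
  tw
}

#' Afterloaded (physiologic) twitch
#'
#' Three phases, mirroring the phases of the cardiac pressure-volume loop:
#' (i) isometric stress development at the end-diastolic length until the
#' afterload is reached (isovolumic contraction); (ii) isotonic
#' shortening, where for each output interval a constant lengthening rate
#' `v` is solved (by root finding) such that the end-of-interval stress
#' equals the afterload, the interval being recursively quartered (down to
#' 1/64 ms) if the solve fails; (iii) once the solved rate first turns
#' non-negative the end-systolic point is reached, the length is clamped
#' there, and the twitch relaxes isometrically (the analog of isovolumic
#' relaxation at end-systolic volume). The end-systolic point is the point
#' of minimum half-sarcomere length.
#'
#' @param params An `xb_params` object.
#' @param afterload Stress (kPa), > 0.
#' @param l_ed End-diastolic half-sarcomere length (um).
#' @param n_points,dt_out,rs,rtol,atol As in [run_isometric()].
#' @return An `xb_twitch` with an `es_point` element (`l`, `sigma`, `t`).
#' @export
run_afterloaded <- function(params, afterload, l_ed = params$l_ed,
                            n_points = 72, dt_out = 1, rs = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  if (afterload <= 0) stop("`afterload` must be > 0", call. = FALSE)
  if (is.null(rs)) rs <- build_rate_system(params, n_points)
  ca_fun <- function(t) ca_transient(t, params$ca$T_p, params$ca$T_d,
                                     params$ca$amplitude)
  times <- seq(0, params$beat_period, by = dt_out)
  nt <- length(times)
  # phase (i): isometric until the afterload is reached
  traj <- integrate_reaction(rs, init_density(rs), 0, params$beat_period,
                             l_ed, ca_fun, times_out = times,
                             rtol = rtol, atol = atol)
  sigma_iso <- vapply(traj, cauchy_stress, 0, l = l_ed, rs = rs)
  cross <- which(sigma_iso >= afterload)
  if (length(cross) == 0L) {
    # afterload above peak isometric stress: the twitch stays isometric
    vatp <- vapply(traj, atp_rate, 0, rs = rs)
    tw <- new_twitch(times, sigma_iso, rep(l_ed, nt), rep(0, nt),
                     vatp, params)
    tw$es_point <- list(l = l_ed, sigma = max(sigma_iso),
                        t = times[which.max(sigma_iso)])
    tw$afterload <- afterload
    return(tw)
  }
  k <- cross[1L]
  sigma <- sigma_iso
  lvec <- rep(l_ed, nt)
  vvec <- rep(0, nt)
  vatp <- rep(NA_real_, nt)
  vatp[seq_len(k)] <- vapply(traj[seq_len(k)], atp_rate, 0, rs = rs)
  n <- traj[[k]]

  # Solve v for one sub-interval; the reaction advance is independent of v
  # (length frozen over the interval), so it is computed once and the root
  # solve iterates only over the cheap advection + stress evaluation.
  # Recursive quartering of the interval on root-bracketing failure.
  solve_interval <- function(n, t0, dt, l0, depth = 0) {
    n_react <- reaction_step_implicit(rs, n, t0, dt, l0, ca_fun)
    atp_step <- attr(n_react, "atp_step")
    g <- function(v) {
      l1 <- l0 + v * 1e-3 * dt
      if (l1 <= params$l_min + 0.005) return(1e6)  # guard the l_min pole
      cauchy_stress(advect(n_react, v, dt, rs$grid), l1, rs) - afterload
    }
    # bound the advection shift |v * dt| well below half the grid period
    # (larger shifts wrap the attached population around the periodic domain)
    v_lo <- -8 / dt; v_hi <- 8 / dt
    g_lo <- g(v_lo); g_hi <- g(v_hi)
    if (g_lo * g_hi > 0) {
      if (dt > 1 / 64 && depth < 4) {
        # quarter the interval and chain the solves
        vs <- numeric(0); nn <- n; ll <- l0; tt <- t0; acc <- 0
        for (s in 1:4) {
          res <- solve_interval(nn, tt, dt / 4, ll, depth + 1)
          if (res$bracket_failed) return(res)
          nn <- res$n; ll <- res$l; tt <- tt + dt / 4
          vs <- c(vs, res$v); acc <- acc + res$atp
        }
        return(list(n = nn, l = ll, v = mean(vs), atp = acc,
                    bracket_failed = FALSE))
      }
      # no root: stress cannot match the afterload in this interval
      return(list(n = n, l = l0, v = 0, atp = 0, bracket_failed = TRUE,
                  g_sign = sign(g_lo)))
    }
    root <- uniroot(g, c(v_lo, v_hi), tol = 1e-4)
    v <- root$root
    l1 <- l0 + v * 1e-3 * dt
    list(n = advect(n_react, v, dt, rs$grid), l = l1, v = v,
         atp = atp_step, bracket_failed = FALSE)
  }

  l_cur <- l_ed
  es <- list(l = l_ed, sigma = afterload, t = times[k])
  # ATP bookkeeping: trapezoid over the smooth isometric phases, exact
  # backward-Euler quadrature over the isotonic steps (snapshot rates
  # right after an advection step oversample the stiff detachment bursts)
  atp_total <- atp_per_beat(times[seq_len(k)], vatp[seq_len(k)])
  atp_phases <- c(develop = atp_total, isotonic = 0, relax = 0)
  i <- k + 1L
  while (i <= nt) {
    t0 <- times[i - 1L]; dt <- times[i] - t0
    res <- solve_interval(n, t0, dt, l_cur)
    done <- FALSE
    if (res$bracket_failed) {
      # stress cannot match the afterload at any admissible v (late
      # relaxation): finish the beat isometrically at the current length
      done <- TRUE
    } else if (res$v >= 0) {
      # the solve asks for re-lengthening: end systole; clamp the length
      # at its minimum and relax isometrically
      done <- TRUE
    } else {
      n <- res$n
      l_cur <- res$l
      vvec[i] <- res$v
      lvec[i] <- l_cur
      sigma[i] <- cauchy_stress(n, l_cur, rs)
      vatp[i] <- atp_rate(n, rs)
      atp_total <- atp_total + res$atp
      atp_phases["isotonic"] <- atp_phases["isotonic"] + res$atp
      if (l_cur < es$l) es <- list(l = l_cur, sigma = sigma[i], t = times[i])
      i <- i + 1L
    }
    if (done && i <= nt) {
      # isometric remainder of the beat in one integrator call
      tr <- integrate_reaction(rs, n, times[i - 1L], params$beat_period,
                               l_cur, ca_fun, times_out = times[i:nt],
                               rtol = rtol, atol = atol)
      tt <- attr(tr, "times")
      for (jj in i:nt) {
        nj <- tr[[match(times[jj], tt)]]
        lvec[jj] <- l_cur
        vvec[jj] <- 0
        sigma[jj] <- cauchy_stress(nj, l_cur, rs)
        vatp[jj] <- atp_rate(nj, rs)
      }
      n <- tr[[length(tr)]]
      tail_atp <- atp_per_beat(times[(i - 1L):nt], vatp[(i - 1L):nt])
      atp_total <- atp_total + tail_atp
      atp_phases["relax"] <- tail_atp
      break
    }
  }
  tw <- new_twitch(times, sigma, lvec, vvec, vatp, params)
  tw$atp_per_beat <- atp_total
  tw$atp_phases <- atp_phases
  tw$es_point <- es
  tw$afterload <- afterload
  tw$final_density <- n
  tw
}

#' End-systolic stress-length relation from isometric twitches
#'
#' Runs isometric twitches at the given lengths and returns the peak
#' (end-systolic) stress per length together with a monotone interpolator.
#'
#' @param params An `xb_params` object.
#' @param lengths Half-sarcomere lengths (um).
#' @param ... Passed to [run_isometric()].
#' @return List with `points` (data.frame `l`, `sigma`), `fun` (stress as a
#'   function of length, linearly extrapolated to zero), `l0` (zero-stress
#'   intercept) and the twitches.
#' @export
es_line <- function(params, lengths, ...) {
  tws <- lapply(lengths, function(l) run_isometric(params, l = l, ...))
  pts <- data.frame(l = lengths,
                    sigma = vapply(tws, function(x) x$peak_stress, 0))
  o <- order(pts$l)
  pts <- pts[o, ]
  # zero-stress intercept by linear extrapolation of the lowest segment;
  # with a single length the line is anchored at l_min
  l0 <- if (nrow(pts) >= 2L) {
    sl <- (pts$sigma[2] - pts$sigma[1]) / (pts$l[2] - pts$l[1])
    max(params$l_min, pts$l[1] - pts$sigma[1] / sl)
  } else {
    params$l_min
  }
  fun <- function(l) {
    ifelse(l <= l0, 0,
           approx(c(l0, pts$l), c(0, pts$sigma), xout = l, rule = 2)$y)
  }
  list(points = pts, fun = fun, l0 = l0, twitches = tws)
}

#' Stress-strain area of a twitch
#'
#' Area in the stress-strain plane bounded by the end-systolic line, the
#' end-diastolic line and the systolic segment of the twitch trajectory,
#' computed by polygon (shoelace) integration. The model develops no
#' passive stress, so the end-diastolic line is the zero-stress axis.
#' Strain is referenced to the end-diastolic length, making the area a
#' volumetric energy density (kPa = kJ/m^3).
#'
#' @param twitch An `xb_twitch` (isometric or afterloaded).
#' @param es An [es_line()] object.
#' @param l_ed End-diastolic length (um); default from the twitch.
#' @return SSA in kJ/m^3.
#' @export
compute_ssa <- function(twitch, es, l_ed = max(twitch$l)) {
  l_es <- min(twitch$l)
  sigma_es <- if (l_es < l_ed) {
    twitch$sigma[which.min(twitch$l)]
  } else {
    twitch$peak_stress
  }
  l0 <- min(es$l0, l_es)
  if (l_es > l0) {
    # include the ES polyline kinks so piecewise-linear ES lines are exact
    ls <- sort(unique(c(seq(l0, l_es, length.out = 64),
                        es$points$l[es$points$l > l0 &
                                      es$points$l < l_es])))
    poly_l <- c(ls, l_es, l_ed, l_ed)
    poly_s <- c(es$fun(ls), sigma_es, sigma_es, 0)
  } else {
    poly_l <- c(l_es, l_es, l_ed, l_ed)
    poly_s <- c(0, sigma_es, sigma_es, 0)
  }
  shoelace(poly_l / l_ed, poly_s)
}

# Absolute polygon area (shoelace formula); vertices in order.
shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Contraction efficiency
#'
#' Ratio of the stress-strain area to the free energy made available by
#' ATP hydrolysis: `ssa / (atp_per_beat * c_myosin * dG_ATP)`.
#'
#' @param ssa Stress-strain area (kJ/m^3).
#' @param atp ATP molecules per myosin head per beat (> 0).
#' @param c_myosin Myosin ATPase concentration (mol/m^3).
#' @param dG_ATP ATP hydrolysis free energy (kJ/mol).
#' @return Efficiency (fraction).
#' @export
xb_efficiency <- function(ssa, atp, c_myosin = 0.18, dG_ATP = 60) {
  if (atp <= 0) stop("efficiency undefined for atp_per_beat <= 0", call. = FALSE)
  ssa / (atp * c_myosin * dG_ATP)
}

#' Steady-state force-Ca relation
#'
#' Stress of the clamped-Ca steady state over a Ca grid, normalized by the
#' maximum over the grid.
#'
#' @param params An `xb_params` object.
#' @param ca_grid Positive Ca concentrations (arbitrary units), typically
#'   log-spaced.
#' @param l Half-sarcomere length (um).
#' @param n_points Grid resolution.
#' @param rs Optional pre-built rate system.
#' @return data.frame with `ca`, `stress` (kPa), `f_norm`.
#' @export
force_ca_curve <- function(params, ca_grid = 10^seq(-3, 0, length.out = 13),
                           l = params$l_ed, n_points = 36, rs = NULL) {
  stopifnot(all(ca_grid > 0))
  if (is.null(rs)) rs <- build_rate_system(params, n_points)
  stress <- vapply(ca_grid, function(ca) {
    cauchy_stress(steady_state(rs, ca, l), l, rs)
  }, 0)
  data.frame(ca = ca_grid, stress = stress,
             f_norm = stress / max(stress))
}

#' Hill slope of a force-Ca curve
#'
#' Slope of `logit(F_norm)` versus `log(Ca)`: centered finite differences
#' at interior points, one-sided at the ends; points with `F_norm` at 0 or
#' 1 are excluded.
#'
#' @param curve Output of [force_ca_curve()] (or any data.frame with `ca`
#'   and `f_norm`).
#' @return data.frame with `ca` and `slope`.
#' @export
hill_slope <- function(curve) {
  ok <- curve$f_norm > 0 & curve$f_norm < 1
  ca <- curve$ca[ok]
  f <- curve$f_norm[ok]
  if (length(ca) < 3L) stop("fewer than 3 usable points", call. = FALSE)
  u <- log(ca)
  y <- log(f / (1 - f))
  n <- length(u)
  slope <- numeric(n)
  slope[1] <- (y[2] - y[1]) / (u[2] - u[1])
  slope[n] <- (y[n] - y[n - 1]) / (u[n] - u[n - 1])
  if (n > 2L) {
    slope[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (u[3:n] - u[1:(n - 2)])
  }
  data.frame(ca = ca, slope = slope)
}
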