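# Least-squares fitting: three weighted residual blocks (isometric stress
# traces, end-systolic consistency, SSA/ATP energetic consistency) and a
# two-tier optimization scheme (outer exhaustive grid over free-energy
# parameters, inner damped least squares over rate parameters).

#' Energetic conversion constant
#'
#' The target ATP-per-SSA ratio used by the third residual block: the
#' reciprocal of (efficiency x myosin ATPase concentration x ATP free
#' energy).
#'
#' @param efficiency Assumed contraction efficiency (default 0.65).
#' @param c_myosin Myosin ATPase concentration (mol/m^3).
#' @param dG_ATP ATP hydrolysis free energy (kJ/mol).
#' @return eta in 1/(kJ/m^3) units.
#' @export
#' @examples
#' eta_const()  # 0.1425
eta_const <- function(efficiency = 0.65, c_myosin = 0.18, dG_ATP = 60) {
  1 / (efficiency * c_myosin * dG_ATP)
}

#' Isometric trace residuals
#'
#' Per-record weighted residuals comparing computed to measured isometric
#' stress: `(P_co - P_ex) / ((P_max - P_co) * N_isom / 10)`. `P_max` is the
#' maximum measured stress over the whole dataset; the weight denominator
#' `(P_max - P_co)` is floored at `0.05 * P_max` to avoid blow-up near peak
#' stress.
#'
#' @param P_co Computed stress at the dataset's `(l, t)` records (kPa).
#' @param P_ex Measured stress records (kPa).
#' @param P_max Maximum measured stress (default: `max(P_ex)`).
#' @return Residual vector; its sum of squares is the scalar `R_I`.
#' @export
residual_isometric <- function(P_co, P_ex, P_max = max(P_ex)) {
  stopifnot(length(P_co) == length(P_ex))
  N <- length(P_ex)
  denom <- pmax(P_max - P_co, 0.05 * P_max)
  if (any(denom <= 0)) stop("non-positive residual weight", call. = FALSE)
  (P_co - P_ex) / (denom * N / 10)
}

#' End-systolic consistency residuals
#'
#' Compares, per afterload, the end-systolic half-sarcomere length of the
#' physiologic (afterloaded) contraction with the length at which the
#' isometric end-systolic relation reaches the same stress:
#' `(l_es_isom - l_es_phy) / ((l_phy - l_min) * N_isot / 5)`.
#'
#' @param l_es_isom Isometric ES lengths interpolated at the afterloaded ES
#'   stresses (um).
#' @param l_es_phy Afterloaded ES lengths (um).
#' @param l_phy End-diastolic length of the physiologic runs (um).
#' @param l_min Minimum half-sarcomere length (um).
#' @return Residual vector; its sum of squares is `R_II`.
#' @export
residual_es <- function(l_es_isom, l_es_phy, l_phy = 1.05, l_min = 0.8) {
  stopifnot(length(l_es_isom) == length(l_es_phy))
  N <- length(l_es_phy)
  (l_es_isom - l_es_phy) / ((l_phy - l_min) * N / 5)
}

#' Energetic consistency residuals
#'
#' Compares the ATP-per-SSA ratio of each run with the target `eta`:
#' `(V_beat/SSA - eta) / (eta * N_SSA)`. Runs with non-positive SSA are
#' excluded with a warning.
#'
#' @param atp ATP consumed per beat per run (molecules per head).
#' @param ssa Stress-strain area per run (kJ/m^3).
#' @param eta Target ratio, default [eta_const()].
#' @return Residual vector; its sum of squares is `R_III`.
#' @export
residual_ssa <- function(atp, ssa, eta = eta_const()) {
  stopifnot(length(atp) == length(ssa))
  ok <- ssa > 0
  if (!all(ok)) warning("excluding ", sum(!ok), " run(s) with ssa <= 0")
  N <- sum(ok)
  (atp[ok] / ssa[ok] - eta) / (eta * N)
}

# --- parameter packing -------------------------------------------------

# Free parameters are addressed by name: "f_ca", "p_L1", "p_L2", or
# "<rate vector>[i]" such as "f_WCa_S1Ca[3]".
free_get <- function(params, free) {
  vapply(free, function(nm) {
    m <- regmatches(nm, regexec("^([A-Za-z0-9_.]+)\\[(\\d+)\\]$", nm))[[1]]
    if (length(m)) params$rates[[m[2]]][as.integer(m[3])]
    else if (nm %in% names(params$rates)) params$rates[[nm]]
    else params[[nm]]
  }, 0)
}

free_set <- function(params, free, values) {
  for (i in seq_along(free)) {
    nm <- free[i]
    m <- regmatches(nm, regexec("^([A-Za-z0-9_.]+)\\[(\\d+)\\]$", nm))[[1]]
    if (length(m)) {
      params$rates[[m[2]]][as.integer(m[3])] <- values[i]
    } else if (nm %in% names(params$rates)) {
      params$rates[[nm]] <- values[i]
    } else {
      params[[nm]] <- values[i]
    }
  }
  as_xb_params(unclass(params))
}

#' Model residual vector against a dataset
#'
#' Runs the forward model at the dataset's conditions and assembles the
#' requested residual blocks into one vector (the inner optimizer's
#' objective).
#'
#' @param params An `xb_params` object.
#' @param dataset An `xb_dataset` (see [generate_twitch_dataset()]).
#' @param parts Which blocks to include: subset of
#'   `c("isometric", "es", "ssa")`.
#' @param n_points Grid resolution for the forward runs.
#' @param rs Optional pre-built rate system.
#' @return Numeric residual vector with a `blocks` attribute.
#' @export
model_residuals <- function(params, dataset,
                            parts = c("isometric", "es", "ssa"),
                            n_points = 24, rs = NULL) {
  parts <- match.arg(parts, several.ok = TRUE)
  if (is.null(rs)) rs <- build_rate_system(params, n_points)
  lens <- sort(unique(dataset$isometric$l))
  need_iso <- "isometric" %in% parts
  need_run_aft <- any(c("es", "ssa") %in% parts)
  tws <- lapply(lens, function(l) run_isometric(params, l = l, rs = rs))
  out <- numeric(0)
  blocks <- character(0)
  if (need_iso) {
    P_co <- unlist(lapply(seq_len(nrow(dataset$isometric)), function(i) {
      tw <- tws[[match(dataset$isometric$l[i], lens)]]
      approx(tw$t, tw$sigma, dataset$isometric$t[i], rule = 2)$y
    }))
    r1 <- residual_isometric(P_co, dataset$isometric$P_ex)
    out <- c(out, r1)
    blocks <- c(blocks, rep("isometric", length(r1)))
  }
  if (need_run_aft) {
    es <- list(points = data.frame(
      l = lens, sigma = vapply(tws, function(t) t$peak_stress, 0)))
    o <- order(es$points$l)
    es$points <- es$points[o, ]
    sl <- diff(es$points$sigma[1:2]) / diff(es$points$l[1:2])
    es$l0 <- max(params$l_min, es$points$l[1] - es$points$sigma[1] / sl)
    es$fun <- function(l) ifelse(l <= es$l0, 0,
      approx(c(es$l0, es$points$l), c(0, es$points$sigma), xout = l,
             rule = 2)$y)
    afts <- lapply(dataset$es_phy$afterload, function(af) {
      run_afterloaded(params, af, rs = rs)
    })
    if ("es" %in% parts) {
      # isometric ES length at the afterloaded ES stress, by monotone
      # interpolation of the (stress -> length) inverse relation
      inv <- function(s) approx(c(0, es$points$sigma), c(es$l0, es$points$l),
                                xout = s, rule = 2)$y
      l_es_phy <- vapply(afts, function(tw) tw$es_point$l, 0)
      s_es_phy <- vapply(afts, function(tw) tw$es_point$sigma, 0)
      r2 <- residual_es(inv(s_es_phy), l_es_phy,
                        l_phy = params$l_ed, l_min = params$l_min)
      out <- c(out, r2)
      blocks <- c(blocks, rep("es", length(r2)))
    }
    if ("ssa" %in% parts) {
      ssa <- c(vapply(seq_along(lens), function(i) {
        compute_ssa(tws[[i]], es, l_ed = lens[i])
      }, 0), vapply(afts, compute_ssa, 0, es = es, l_ed = params$l_ed))
      atp <- c(vapply(tws, function(t) t$atp_per_beat, 0),
               vapply(afts, function(t) t$atp_per_beat, 0))
      r3 <- residual_ssa(atp, ssa)
      out <- c(out, r3)
      blocks <- c(blocks, rep("ssa", length(r3)))
    }
  }
  attr(out, "blocks") <- blocks
  out
}

#' Fit model parameters to a dataset
#'
#' Two-tier scheme: an outer exhaustive grid over combinations of the
#' `grid` parameters (free-energy profile and tropomyosin values), and for
#' each combination an inner Levenberg-Marquardt damped least squares over
#' the `free` rate parameters, minimizing the total weighted residual.
#' Deterministic given the starting values.
#'
#' @param dataset An `xb_dataset`.
#' @param params Starting parameter object.
#' @param free Character vector naming the inner free parameters (see
#'   [model_residuals()] for the forward model); e.g.
#'   `c("f_ca", "f_WCa_S1Ca[3]", "p_L2")`.
#' @param grid Named list of value vectors for the outer grid (fields of
#'   `params`, e.g. `list(G_S1_min = c(-6, -5))`); `NULL` for inner-only.
#' @param parts Residual blocks to use.
#' @param n_points Grid resolution for forward runs.
#' @param lower Lower bounds for the free parameters (default 0: rates are
#'   non-negative).
#' @param maxiter Inner iteration cap.
#' @param epsfcn Relative step used for the numerical Jacobian; the default
#'   1e-6 keeps finite-difference steps well above the forward model's
#'   integration noise.
#' @return List with `params` (best fit), `free_values`, `residual` (best
#'   total sum of squares), `report` (one row per outer grid point), and
#'   `fit` (the `nls.lm` object of the winning inner fit).
#' @export
fit_xb <- function(dataset, params, free, grid = NULL,
                   parts = c("isometric"), n_points = 24,
                   lower = NULL, maxiter = 25, epsfcn = 1e-6) {
  combos <- if (is.null(grid) || length(grid) == 0L) {
    data.frame(.dummy = 1)
  } else {
    do.call(expand.grid, grid)
  }
  if (is.null(lower)) lower <- rep(0, length(free))
  best <- NULL
  report <- NULL
  for (ci in seq_len(nrow(combos))) {
    p_outer <- params
    for (nm in setdiff(names(combos), ".dummy")) {
      p_outer[[nm]] <- combos[ci, nm]
    }
    p_outer <- tryCatch(as_xb_params(unclass(p_outer)), error = function(e) NULL)
    if (is.null(p_outer)) {
      report <- rbind(report, cbind(combos[ci, , drop = FALSE],
                                    residual = NA_real_))
      next
    }
    start <- free_get(p_outer, free)
    fn <- function(v) {
      p <- tryCatch(free_set(p_outer, free, v), error = function(e) NULL)
      if (is.null(p)) return(rep(1e3, 8))
      r <- tryCatch(model_residuals(p, dataset, parts, n_points),
                    error = function(e) NULL)
      if (is.null(r) || any(!is.finite(r))) return(rep(1e3, 8))
      as.numeric(r)
    }
    fit <- minpack.lm::nls.lm(par = start, fn = fn, lower = lower,
                              control = minpack.lm::nls.lm.control(
                                maxiter = maxiter, ptol = 1e-10,
                                epsfcn = epsfcn))
    rss <- sum(fit$fvec^2)
    report <- rbind(report, cbind(combos[ci, , drop = FALSE],
                                  residual = rss))
    if (is.null(best) || rss < best$residual) {
      best <- list(params = free_set(p_outer, free, fit$par),
                   free_values = setNames(fit$par, free),
                   residual = rss, fit = fit)
    }
  }
  best$report <- report
  best
}
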