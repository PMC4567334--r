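# Stress and ATP observables, SSA geometry, force-Ca analysis, protocols.

test_that("Cauchy stress of a point mass matches first-principles
          arithmetic and vanishes for symmetric or unbound densities", {
  p <- fix_params(q = 1)
  rs <- build_rate_system(p, n_points = 24)
  expect_equal(cauchy_stress(init_density(rs), 1.05, rs), 0)
  # point mass in S2 at one grid position
  ix <- which.min(abs(rs$grid$x - 2))
  x_val <- rs$grid$x[ix]
  n <- matrix(0, rs$ns, 24)
  n[5L, ix] <- 1   # q = 1, state S2
  # independent arithmetic: sigma = m l/(2d) * K_S2 x kT/nm * dx
  kT <- 1.380649e-23 * p$temperature
  F_N <- p$K_S2 * x_val * kT / 1e-9
  m <- p$c_myosin * 6.02214076e23
  expected_kPa <- m * 1.05e-6 / (2 * 36e-9) * F_N * (rs$grid$dx * 1e-9) / 1e3
  expect_equal(cauchy_stress(n, 1.05, rs), expected_kPa, tolerance = 1e-12)
  # eq28 prefactor mode doubles the stress
  p2 <- fix_params(q = 1, stress_prefactor_mode = "eq28")
  rs2 <- build_rate_system(p2, n_points = 24)
  expect_equal(cauchy_stress(n, 1.05, rs2),
               2 * cauchy_stress(n, 1.05, rs), tolerance = 1e-12)
  # occupancy symmetric about the S2 minimum: linear force integrates to 0
  nsym <- matrix(0, rs$ns, 24)
  i_lo <- which.min(abs(rs$grid$x + 3))
  i_hi <- which.min(abs(rs$grid$x - 3))
  nsym[5L, c(i_lo, i_hi)] <- 0.5
  expect_equal(cauchy_stress(nsym, 1.05, rs), 0, tolerance = 1e-12)
})

test_that("ATP rate vanishes at chemical equilibrium (zero drive) and is
          positive over an active fixture beat", {
  # zero ATP drive: the clamped-Ca steady state is a true equilibrium
  p0 <- fix_params(q = 1, dG_ATP = 0)
  rs0 <- build_rate_system(p0, n_points = 16)
  ss <- steady_state(rs0, ca = 0.5, l = 1.05)
  expect_equal(atp_rate(ss, rs0), 0, tolerance = 1e-12)
  # driven fixture: net hydrolysis over the beat is positive
  tw <- run_isometric(fix_params(q = 1), n_points = 16)
  expect_gt(tw$atp_per_beat, 0)
  # ... and equals an independent Riemann-sum oracle within 0.1%
  riemann <- sum(tw$v_atp[-1] * diff(tw$t))
  expect_equal(tw$atp_per_beat, riemann, tolerance = 1e-3)
})

test_that("ATP per beat integrates the rate series", {
  tt <- seq(0, 500, by = 1)
  expect_equal(atp_per_beat(tt, rep(0.002, length(tt))), 1)
  expect_equal(atp_per_beat(tt, rep(0, length(tt))), 0)
  expect_error(atp_per_beat(0, 1), "incomplete")
})

test_that("steady cycling at constant Ca balances the hydrolysis cut
          against the attachment cut", {
  # flux conservation on the state graph: at steady state the net flux
  # through the counted detachment reactions equals the net attachment
  # flux through the {WCa,S1Ca} edge (the only other strong<->weak cut)
  p <- fix_params(q = 1)
  rs <- build_rate_system(p, n_points = 16)
  ss <- steady_state(rs, ca = 0.8, l = 1.05)
  tr <- rs$trans
  pf <- xbgroup:::length_factors(rs, 1.05)
  mult <- c(0.8 * pf$p1, pf$p1, pf$p2, 1)[rs$grp]
  flux_edge <- function(a, b) {
    e_f <- which(tr$alpha == a & tr$beta == b)
    e_r <- which(tr$alpha == b & tr$beta == a)
    sum((rs$k0[e_f, ] * mult[e_f]) * ss[tr$from[e_f], ] -
          (rs$k0[e_r, ] * mult[e_r]) * ss[tr$from[e_r], ])
  }
  # cut balance: net flux into the strong states through {WCa,S1Ca} must
  # equal the net hydrolysis flux out through {T,S2} and {WCa,S2Ca}
  net_hydrolysis <- flux_edge("S2", "T") + flux_edge("S2Ca", "WCa")
  net_attach <- flux_edge("WCa", "S1Ca")
  expect_equal(net_hydrolysis, net_attach, tolerance = 1e-10)
  expect_equal(atp_rate(ss, rs),
               net_hydrolysis * rs$grid$dx / 36, tolerance = 1e-10)
})

test_that("stress-strain area geometry: degenerate and rectangular loops", {
  # coincident ES and ED lines: zero area
  es0 <- list(points = data.frame(l = c(1, 1.1), sigma = c(0, 0)),
              l0 = 1, fun = function(l) rep(0, length(l)))
  tw_flat <- structure(list(t = 0:10, sigma = rep(0, 11), l = rep(1.05, 11),
                            peak_stress = 0), class = "xb_twitch")
  expect_equal(compute_ssa(tw_flat, es0, l_ed = 1.05), 0)
  # rectangular synthetic loop: width x height
  es_r <- list(points = data.frame(l = c(0.9, 1.1), sigma = c(40, 40)),
               l0 = 0.9,
               fun = function(l) ifelse(l <= 0.9, 0, 40))
  tw_rect <- structure(list(t = 0:3, sigma = c(0, 40, 40, 40),
                            l = c(1.05, 1.05, 0.95, 0.95),
                            peak_stress = 40), class = "xb_twitch")
  # polygon: ES segment at 40 from 0.9 to 0.95, isotonic at 40 to 1.05,
  # down; area = 40 * (1.05 - 0.9) strain units... computed by shoelace
  got <- compute_ssa(tw_rect, es_r, l_ed = 1.05)
  # the step in the synthetic ES line is resolved to sampling accuracy
  expect_equal(got, 40 * (1.05 - 0.9) / 1.05, tolerance = 5e-3)
})

test_that("isometric SSA equals the area under the ES line left of l_ed
          (brute-force quadrature oracle)", {
  lens <- c(0.95, 1.0, 1.05, 1.1)
  pks <- c(30, 45, 60, 75)   # synthetic ES points
  sl <- (pks[2] - pks[1]) / 0.05
  l0 <- 0.95 - pks[1] / sl
  esf <- function(l) ifelse(l <= l0, 0,
                            approx(c(l0, lens), c(0, pks), xout = l,
                                   rule = 2)$y)
  es <- list(points = data.frame(l = lens, sigma = pks), l0 = l0, fun = esf)
  tw_iso <- structure(list(t = 0:2, sigma = c(0, 60, 0), l = rep(1.05, 3),
                           peak_stress = 60), class = "xb_twitch")
  got <- compute_ssa(tw_iso, es, l_ed = 1.05)
  oracle <- integrate(esf, l0, 1.05, subdivisions = 1000L)$value / 1.05
  expect_equal(got, oracle, tolerance = 1e-3)
})

test_that("efficiency follows the SSA / ATP relation", {
  # the eta relation: atp/ssa = 0.142 -> efficiency 0.65
  expect_equal(xb_efficiency(1 / 0.142, 1), 0.65, tolerance = 0.01)
  expect_equal(xb_efficiency(0, 1), 0)
  expect_error(xb_efficiency(1, 0), "undefined")
  expect_lt(xb_efficiency(10, 1.42), 1)
})

test_that("Hill slope of an exact Hill function recovers its coefficient", {
  ca <- 10^seq(-2, 2, length.out = 17)
  for (nh in c(1, 2, 3.5)) {
    f <- ca^nh / (1 + ca^nh)
    curve <- data.frame(ca = ca, f_norm = f)
    hs <- hill_slope(curve)
    expect_equal(hs$slope, rep(nh, nrow(hs)), tolerance = 1e-6)
  }
  expect_error(hill_slope(data.frame(ca = c(1, 2), f_norm = c(0.2, 0.8))),
               "fewer than 3")
  # saturated points are excluded
  curve2 <- data.frame(ca = ca, f_norm = pmin(ca / 10, 1))
  expect_true(all(is.finite(hill_slope(curve2)$slope)))
})

test_that("force-Ca curve is normalized, non-decreasing, and vanishes at
          low Ca", {
  p <- fix_params(q = 1)
  rs <- build_rate_system(p, n_points = 16)
  curve <- force_ca_curve(p, ca_grid = 10^seq(-3, 0, length.out = 9),
                          rs = rs)
  expect_equal(max(curve$f_norm), 1)
  expect_lt(curve$f_norm[1], 0.05)
  expect_true(all(diff(curve$f_norm) > -1e-6))
})

test_that("zero Ca amplitude leaves the twitch at resting stress", {
  p <- fix_params(q = 1)
  p$ca$amplitude <- 0
  p <- as_xb_params(unclass(p))
  tw <- run_isometric(p, n_points = 16)
  expect_lt(max(abs(tw$sigma)), 0.1)   # kPa; resting stress is negligible
  expect_equal(tw$v, rep(0, length(tw$t)))
})

test_that("an afterload above peak isometric stress reproduces the
          isometric twitch", {
  p <- fix_params(q = 1)
  rs <- build_rate_system(p, n_points = 16)
  iso <- run_isometric(p, n_points = 16, rs = rs)
  aft <- run_afterloaded(p, afterload = 10 * iso$peak_stress,
                         n_points = 16, rs = rs)
  expect_equal(aft$sigma, iso$sigma, tolerance = 1e-10)
  expect_equal(aft$l, iso$l)
  expect_equal(aft$es_point$l, p$l_ed)
  expect_error(run_afterloaded(p, afterload = -5), "afterload")
})

test_that("the isotonic phase holds stress at the afterload and records
          the minimum-length end-systolic point", {
  p <- fix_params(q = 3)
  rs <- fix_rs(q = 3, n_points = 16)
  af <- 0.5 * run_isometric(p, n_points = 16, rs = rs)$peak_stress
  tw <- run_afterloaded(p, af, n_points = 16, rs = rs)
  shortening <- which(tw$v < 0)
  expect_gt(length(shortening), 3)
  # stress pinned to the afterload at the end of each isotonic interval
  iso_phase <- shortening[-1]
  expect_lt(max(abs(tw$sigma[iso_phase] - af)), 0.1)
  expect_equal(tw$es_point$l, min(tw$l))
  expect_lt(min(tw$l), p$l_ed)
})
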