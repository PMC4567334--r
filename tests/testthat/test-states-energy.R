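# State enumeration, tropomyosin energetics, free-energy profiles, forces.

test_that("per-site state table has the five-state structure", {
  st <- xb_states()
  expect_equal(nrow(st), 5L)
  expect_equal(st$ca_bound, st$label %in% c("WCa", "S1Ca", "S2Ca"))
  expect_equal(st$force_bearing, st$label %in% c("S1Ca", "S2Ca", "S2"))
  expect_equal(st$tm_position,
               c(T = "T", WCa = "W", S1Ca = "S", S2Ca = "S", S2 = "S")[st$label],
               ignore_attr = TRUE)
})

test_that("group-state enumeration gives K^q states in a stable order", {
  expect_equal(nrow(enumerate_group_states(1)), 5L)
  expect_equal(nrow(enumerate_group_states(3)), 125L)
  expect_equal(nrow(enumerate_group_states(3, c("T", "W", "S"))), 27L)
  gs <- enumerate_group_states(2)
  # stable lexicographic order, site 1 fastest
  expect_equal(gs[1, ], c(1L, 1L))
  expect_equal(gs[2, ], c(2L, 1L))
  expect_equal(gs[6, ], c(1L, 2L))
  # index round trip
  for (A in c(1L, 7L, 25L)) {
    expect_equal(xbgroup:::group_state_index(gs[A, ], 5L), A)
  }
  expect_error(enumerate_group_states(0), "positive integer")
})

test_that("allowed transitions follow the five-state reaction graph", {
  # q = 1: T connects to WCa and S2; WCa to T, S1Ca, S2Ca
  trT <- allowed_transitions(1L)
  expect_setequal(trT$to, c("WCa", "S2"))
  trW <- allowed_transitions(2L)
  expect_setequal(trW$to, c("T", "S1Ca", "S2Ca"))
  # q = 3 all-T: two transitions per site
  tr3 <- allowed_transitions(c(1L, 1L, 1L))
  expect_equal(nrow(tr3), 6L)
  expect_equal(unname(table(tr3$site)), rep(2L, 3L), ignore_attr = TRUE)
  # every transition changes exactly one site
  tab <- xbgroup:::group_transition_table(2)
  gs <- enumerate_group_states(2)
  for (e in seq_len(nrow(tab))) {
    expect_equal(sum(gs[tab$from[e], ] != gs[tab$to[e], ]), 1L)
  }
})

test_that("segment energies are symmetric, zero on the diagonal, with the
          fourth-root T;S value", {
  tm <- tropomyosin_model(U_TW = 0.1, U_WS = 0.05)
  for (a in c("T", "W", "S")) expect_equal(segment_energy(a, a, tm), 0)
  for (a in c("T", "W", "S")) for (b in c("T", "W", "S")) {
    expect_equal(segment_energy(a, b, tm), segment_energy(b, a, tm))
  }
  expect_equal(segment_energy("T", "W", tm), 0.1)
  expect_equal(segment_energy("W", "S", tm), 0.05)
  expect_equal(segment_energy("T", "S", tm), (0.1^0.25 + 0.05^0.25)^4,
               tolerance = 1e-12)
  expect_error(segment_energy("T", "Q", tm), "position labels")
})

test_that("relaxed tropomyosin energy is ~3300 RT and dominates the
          segment energies", {
  tm <- tropomyosin_model(temperature = 310)
  expect_gt(tm$U_tr, 3200)
  expect_lt(tm$U_tr, 3500)
  expect_gt(tm$U_tr, 1000 * max(tm$U_TW, tm$U_WS))
  # 25 C value is ~3400
  tm25 <- tropomyosin_model(temperature = 298.15)
  expect_equal(tm25$U_tr, 3400, tolerance = 0.01)
})

test_that("fourth-root approximation tracks the exact fragment geometry", {
  tm <- tropomyosin_model()
  exact <- xbgroup:::segment_energy_TS_exact(0.1, 0.05, tm$U_tr)
  approx_v <- segment_energy("T", "S", tm)
  # leading correction is ~ -s^2/2 of the exact value; < 2% here
  expect_lt(abs(approx_v - exact) / exact, 0.02)
  # error shrinks with smaller energies ...
  for (u in c(0.02, 0.005)) {
    ex <- xbgroup:::segment_energy_TS_exact(u, u / 2, tm$U_tr)
    ap <- (u^0.25 + (u / 2)^0.25)^4
    expect_lt(abs(ap - ex) / ex, 0.01)
  }
  # ... and with stiffer tropomyosin (larger U_tr), over a grid of pairs
  for (u1 in c(0.05, 0.5, 1)) for (u2 in c(0.05, 0.5, 1)) {
    e1 <- abs((u1^0.25 + u2^0.25)^4 -
                xbgroup:::segment_energy_TS_exact(u1, u2, 3000)) /
      xbgroup:::segment_energy_TS_exact(u1, u2, 3000)
    e2 <- abs((u1^0.25 + u2^0.25)^4 -
                xbgroup:::segment_energy_TS_exact(u1, u2, 30000)) /
      xbgroup:::segment_energy_TS_exact(u1, u2, 30000)
    expect_lt(e2, e1)
    expect_lt(e1, 0.06)
  }
})

test_that("group tropomyosin energy sums q+1 segments with T boundaries", {
  tm <- tropomyosin_model(U_TW = 0.1, U_WS = 0.05)
  # all-T group: relaxed
  expect_equal(group_tm_energy(c(1L, 1L, 1L), tm), 0)
  # q = 1 single WCa: two T|W boundary fragments
  expect_equal(group_tm_energy(2L, tm), 0.2)
  # q = 3 all-S1Ca: only the two boundary T|S fragments count
  uts <- segment_energy("T", "S", tm)
  expect_equal(group_tm_energy(c(3L, 3L, 3L), tm), 2 * uts)
  # invariant under site-order reversal (boundary symmetry)
  set.seed(42)
  for (i in 1:20) {
    sites <- sample(5L, 4L, replace = TRUE)
    expect_equal(group_tm_energy(sites, tm), group_tm_energy(rev(sites), tm))
  }
})

test_that("group free energy is tropomyosin energy plus per-site profiles", {
  tm <- tropomyosin_model(U_TW = 0.1, U_WS = 0.05)
  pr <- energy_profiles(G_W = 1, G_S1_min = -2, x_S1_min = 4, K_S1 = 1,
                        G_S2_min = -4, K_S2 = 0.5)
  x <- seq(-17, 17, by = 1)
  expect_equal(group_free_energy(c(1L, 1L, 1L), x, pr, tm), rep(0, length(x)))
  # q = 1 S2 at x = 0: G_S2_min plus two T|S boundary fragments
  uts <- segment_energy("T", "S", tm)
  expect_equal(group_free_energy(5L, 0, pr, tm), -4 + 2 * uts)
  # q = 1 WCa anywhere: constant
  expect_equal(group_free_energy(2L, x, pr, tm), rep(1 + 0.2, length(x)))
  expect_error(group_free_energy(2L, 30, pr, tm), "out of range")
})

test_that("transition delta G matches the group free-energy difference and
          carries the neighbor terms", {
  tm <- tropomyosin_model(U_TW = 0.1, U_WS = 0.05)
  pr <- energy_profiles()
  x <- seq(-17.5, 17.5, by = 0.5)
  # central T -> WCa with T neighbors: +2 U_TW
  dG <- transition_delta_G(c(1L, 1L, 1L), c(1L, 2L, 1L), x, pr, tm)
  expect_equal(dG, pr$G_W + 0.2 + 0 * x)
  # central T -> WCa with WCa neighbors: -2 U_TW (facilitated attachment)
  dG2 <- transition_delta_G(c(2L, 1L, 2L), c(2L, 2L, 2L), x, pr, tm)
  expect_equal(dG2, pr$G_W - 0.2 + 0 * x)
  expect_error(transition_delta_G(c(1L, 1L), c(2L, 2L), 0, pr, tm),
               "exactly one site")
  expect_error(transition_delta_G(1L, 3L, 0, pr, tm), "not an allowed")
})

test_that("delta G equals group free-energy difference exactly for every
          reachable pair on the grid (zero drive)", {
  tm <- tropomyosin_model()
  pr <- energy_profiles()
  tab <- xbgroup:::group_transition_table(2)
  gs <- enumerate_group_states(2)
  x <- seq(-18, 17, by = 2.5)
  for (e in seq_len(nrow(tab))) {
    dG <- transition_delta_G(gs[tab$from[e], ], gs[tab$to[e], ], x, pr, tm)
    diff <- group_free_energy(gs[tab$to[e], ], x, pr, tm) -
      group_free_energy(gs[tab$from[e], ], x, pr, tm)
    # absolute machine-precision agreement on the RT energy scale (the
    # two routes cancel ~1 RT segment energies down to ~1e-3 RT)
    expect_lt(max(abs(dG - diff)), 1e-12)
  }
})

test_that("state forces are the derivatives of the free-energy profiles", {
  pr <- energy_profiles(G_W = 1, G_S1_min = -2, x_S1_min = 4, K_S1 = 1,
                        G_S2_min = -4, K_S2 = 0.5)
  x <- seq(-15, 15, by = 0.5)
  expect_equal(state_force("T", x, pr), rep(0, length(x)))
  expect_equal(state_force("WCa", x, pr), rep(0, length(x)))
  expect_equal(state_force("S1Ca", 4, pr), 0)
  expect_equal(state_force("S2Ca", 2, pr, ), 0.5 * 2)
  # numerical derivative check to 1e-6 relative
  h <- 1e-5
  for (s in c("S1Ca", "S2Ca", "S2")) {
    num <- (state_free_energy(s, x + h, pr) -
              state_free_energy(s, x - h, pr)) / (2 * h)
    expect_equal(state_force(s, x, pr), num, tolerance = 1e-6)
  }
  # pN conversion: 1 RT/nm at 310 K is ~4.28 pN
  expect_equal(state_force("S2", 2, pr, units = "pN") /
                 state_force("S2", 2, pr), 4.28, tolerance = 0.01)
})
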