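# Stochastic verification oracle and synthetic dataset generator.

#' Stochastic simulation of a single cross-bridge group
#'
#' Event-driven continuous-time Markov chain simulation of one group at a
#' fixed cross-bridge position, clamped Ca and fixed length (no advection):
#' exponential waiting times and categorical next-state choice proportional
#' to the directed rates (including Ca and length factors). Serves as an
#' independent oracle for the deterministic kinetics: its time-weighted
#' occupancy converges to [steady_state()] at the same conditions.
#'
#' @param params An `xb_params` object.
#' @param x Cross-bridge position (nm).
#' @param ca Clamped Ca concentration (arbitrary units).
#' @param l Half-sarcomere length (um).
#' @param n_events Number of transition events to simulate.
#' @param seed RNG seed (integer); same seed gives a bit-identical result.
#' @param n_batches Number of batches for the batch-means standard errors.
#' @return An object of class `xb_ctmc`: `occupancy` (time-weighted fraction
#'   per group state), `se` (batch-means standard errors), `counts`
#'   (directed transition counts), `n_events`, `total_time` (ms), `seed`.
#' @export
ctmc_simulate <- function(params, x, ca, l, n_events = 1e5, seed = 1,
                          n_batches = 20) {
  stopifnot(ca >= 0, n_events >= n_batches)
  set.seed(seed)
  # single-position rate system holding exactly x
  rs <- build_rate_system(params, x = x)
  M <- rate_matrix_at(rs, 1L, ca, l)   # M[to, from]
  ns <- rs$ns
  out_rates <- colSums(M)
  # per-state outgoing targets and rates
  targets <- lapply(seq_len(ns), function(s) which(M[, s] > 0))
  rates <- lapply(seq_len(ns), function(s) M[targets[[s]], s])
  state <- 1L  # all-T
  occ_time <- numeric(ns)
  counts <- matrix(0L, ns, ns)
  batch <- matrix(0, ns, n_batches)
  per_batch <- ceiling(n_events / n_batches)
  total_time <- 0
  for (ev in seq_len(n_events)) {
    r0 <- out_rates[state]
    if (r0 <= 0) {
      # absorbing state: assign all remaining weight to it
      occ_time[state] <- occ_time[state] + 1e9
      batch[state, ] <- batch[state, ] + 1e9 / n_batches
      total_time <- total_time + 1e9
      break
    }
    dt <- stats::rexp(1, r0)
    occ_time[state] <- occ_time[state] + dt
    b <- min(n_batches, 1L + (ev - 1L) %/% per_batch)
    batch[state, b] <- batch[state, b] + dt
    total_time <- total_time + dt
    tg <- targets[[state]]
    nxt <- if (length(tg) == 1L) tg else {
      tg[sample.int(length(tg), 1L, prob = rates[[state]])]
    }
    counts[state, nxt] <- counts[state, nxt] + 1L
    state <- nxt
  }
  occ <- occ_time / total_time
  bt <- colSums(batch)
  bfrac <- sweep(batch, 2L, bt, "/")
  se <- apply(bfrac, 1L, stats::sd) / sqrt(n_batches)
  structure(list(occupancy = occ, se = se, counts = counts,
                 n_events = n_events, total_time = total_time,
                 seed = seed, x = x, ca = ca, l = l),
            class = "xb_ctmc")
}

#' Generate a synthetic twitch dataset
#'
#' Emulates the experimental fitting targets: per-length isometric stress
#' time series over one beat (sampled at a fixed cadence, with additive
#' Gaussian noise), end-systolic stress-length points, and SSA/ATP pairs
#' for isometric and afterloaded beats.
#'
#' @param params Generating (`true`) parameters.
#' @param lengths Half-sarcomere lengths for the isometric family (um).
#' @param afterloads Afterloads for the physiologic family (kPa).
#' @param noise_sd Gaussian noise standard deviation on stresses (kPa).
#' @param seed RNG seed.
#' @param cadence Sampling cadence of the stress traces (ms).
#' @param n_points Grid resolution used for the forward runs.
#' @return An object of class `xb_dataset`: `isometric` (data.frame `l`,
#'   `t`, `P_ex`), `es_isometric` (`l`, `sigma`), `es_phy` (`afterload`,
#'   `l_es`, `sigma_es`), `energetics` (`kind`, `id`, `ssa`, `atp`), counts
#'   `N_isom`, `N_isot`, `N_SSA`, and `provenance`.
#' @export
generate_twitch_dataset <- function(params, lengths = c(0.95, 1.0, 1.05, 1.1),
                                    afterloads = c(20, 40, 60, 80),
                                    noise_sd = 0, seed = 1, cadence = 5,
                                    n_points = 24) {
  set.seed(seed)
  rs <- build_rate_system(params, n_points)
  es <- es_line(params, lengths, rs = rs)
  iso <- NULL
  energ <- NULL
  for (i in seq_along(lengths)) {
    tw <- es$twitches[[i]]
    sel <- which(tw$t %% cadence == 0)
    iso <- rbind(iso, data.frame(l = lengths[i], t = tw$t[sel],
                                 P_ex = tw$sigma[sel] +
                                   rnorm(length(sel), 0, noise_sd)))
    energ <- rbind(energ, data.frame(kind = "isometric", id = lengths[i],
                                     ssa = compute_ssa(tw, es, lengths[i]),
                                     atp = tw$atp_per_beat))
  }
  es_phy <- NULL
  for (af in afterloads) {
    tw <- run_afterloaded(params, af, rs = rs)
    es_phy <- rbind(es_phy, data.frame(afterload = af, l_es = tw$es_point$l,
                                       sigma_es = tw$es_point$sigma))
    energ <- rbind(energ, data.frame(kind = "afterloaded", id = af,
                                     ssa = compute_ssa(tw, es,
                                                       params$l_ed),
                                     atp = tw$atp_per_beat))
  }
  structure(list(
    isometric = iso,
    es_isometric = es$points,
    es_phy = es_phy,
    energetics = energ,
    N_isom = nrow(iso), N_isot = nrow(es_phy), N_SSA = nrow(energ),
    provenance = list(noise_sd = noise_sd, seed = seed, cadence = cadence,
                      n_points = n_points, q = params$q)
  ), class = "xb_dataset")
}

#' @export
print.xb_dataset <- function(x, ...) {
  cat("<xb_dataset>", x$N_isom, "isometric stress samples at",
      length(unique(x$isometric$l)), "lengths;", x$N_isot,
      "afterloaded ES points;", x$N_SSA, "SSA/ATP pairs\n")
  invisible(x)
}
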