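#' @importFrom stats approx optimize rnorm runif setNames uniroot coef lm
#' @importFrom utils head tail modifyList
NULL

#' Per-site cross-bridge state labels
#'
#' The five biochemical states of one cross-bridge site: `T` (unbound,
#' tropomyosin blocking the site), `WCa` (unbound active, Ca bound to
#' troponin-C), `S1Ca` (strongly bound pre-powerstroke, Ca bound), `S2Ca`
#' (strongly bound post-powerstroke, Ca bound), `S2` (strongly bound
#' post-powerstroke, Ca dissociated).
#'
#' @format Character vector of length 5.
#' @export
XB_STATES <- c("T", "WCa", "S1Ca", "S2Ca", "S2")

# Tropomyosin azimuthal position class per state (blocked/weak/shifted).
XB_TM_POS <- c(T = "T", WCa = "W", S1Ca = "S", S2Ca = "S", S2 = "S")

# The six reversible per-site reactions (Fig-7-type adjacency), listed in the
# direction that carries the Ca factor or, for Ca-independent reactions, the
# "forward" (towards force generation / detachment) direction.
XB_REACTIONS <- list(
  c("T", "WCa"),     # Ca association to troponin-C (unbound site)
  c("WCa", "S1Ca"),  # myosin attachment
  c("S1Ca", "S2Ca"), # powerstroke
  c("WCa", "S2Ca"),  # attachment directly into the post-stroke state
  c("S2", "S2Ca"),   # Ca association with the cross-bridge strongly bound
  c("T", "S2")       # attachment/detachment of the Ca-free strong state
)

#' Per-site cross-bridge states
#'
#' Metadata for the five per-site states: whether Ca2+ is bound, whether the
#' state bears force, and the tropomyosin position class (`T`, `W`, `S`)
#' occupied at that site.
#'
#' @return A data.frame with one row per state and columns `label`,
#'   `ca_bound`, `force_bearing`, `tm_position`.
#' @export
#' @examples
#' xb_states()
xb_states <- function() {
  data.frame(
    label = XB_STATES,
    ca_bound = XB_STATES %in% c("WCa", "S1Ca", "S2Ca"),
    force_bearing = XB_STATES %in% c("S1Ca", "S2Ca", "S2"),
    tm_position = unname(XB_TM_POS[XB_STATES]),
    stringsAsFactors = FALSE
  )
}

#' Enumerate all group states
#'
#' A group state is the joint state of `q` consecutive cross-bridges coupled
#' by one tropomyosin; the flanking boundary sites are permanently in state
#' `T`. States are enumerated in a stable lexicographic order (site 1 varies
#' fastest), giving `K^q` states for `K` per-site states.
#'
#' @param q Number of cross-bridges in the group (>= 1).
#' @param states Character vector of per-site state labels. Defaults to the
#'   five-state scheme; the three-state scheme `c("T","W","S")` is accepted as
#'   a reduced fixture.
#' @return Integer matrix of dimension `K^q` by `q`; entry `[A, j]` is the
#'   index into `states` of site `j` in group state `A`.
#' @export
#' @examples
#' nrow(enumerate_group_states(3)) # 125
enumerate_group_states <- function(q, states = XB_STATES) {
  if (length(q) != 1L || !is.finite(q) || q < 1 || q != round(q)) {
    stop("`q` must be a positive integer", call. = FALSE)
  }
  K <- length(states)
  if (K < 1L) stop("`states` must be non-empty", call. = FALSE)
  idx <- seq_len(K)
  m <- as.matrix(do.call(expand.grid, rep(list(idx), q)))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  attr(m, "states") <- states
  m
}

# Stable index of a group state row (site 1 fastest), 1-based.
group_state_index <- function(sites, K) {
  1L + as.integer(sum((sites - 1L) * K^(seq_along(sites) - 1L)))
}

group_state_label <- function(sites, states = XB_STATES) {
  paste(states[sites], collapse = ".")
}

# Directed per-site adjacency of the reaction scheme: list mapping
# "alpha->beta" for the 12 directed reactions.
xb_adjacency <- function(states = XB_STATES) {
  if (identical(states, c("T", "W", "S"))) {
    reactions <- list(c("T", "W"), c("W", "S"))
  } else {
    reactions <- XB_REACTIONS
  }
  adj <- vector("list", length(states))
  names(adj) <- states
  for (r in reactions) {
    adj[[r[1]]] <- c(adj[[r[1]]], r[2])
    adj[[r[2]]] <- c(adj[[r[2]]], r[1])
  }
  adj
}

#' Allowed transitions from a group state
#'
#' Only transitions changing the state of exactly one cross-bridge in the
#' group are allowed, and the per-site change must be one of the six
#' reversible reactions of the five-state scheme.
#'
#' @param sites Integer vector of per-site state indices (a row of
#'   [enumerate_group_states()]).
#' @param states Character vector of per-site state labels.
#' @return A data.frame with columns `site`, `from`, `to` (labels) and
#'   `to_index` (index of the destination group state in the stable order).
#' @export
allowed_transitions <- function(sites, states = XB_STATES) {
  adj <- xb_adjacency(states)
  K <- length(states)
  out <- list()
  for (j in seq_along(sites)) {
    a <- states[sites[j]]
    for (b in adj[[a]]) {
      new_sites <- sites
      new_sites[j] <- match(b, states)
      out[[length(out) + 1L]] <- data.frame(
        site = j, from = a, to = b,
        to_index = group_state_index(new_sites, K),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(site = integer(), from = character(),
                      to = character(), to_index = integer()))
  }
  do.call(rbind, out)
}

# Full directed transition table for all K^q group states.
# Columns: from (group index), to (group index), site, alpha, beta (labels).
group_transition_table <- function(q, states = XB_STATES) {
  gs <- enumerate_group_states(q, states)
  adj <- xb_adjacency(states)
  K <- length(states)
  from <- integer(0); to <- integer(0); site <- integer(0)
  alpha <- character(0); beta <- character(0)
  for (A in seq_len(nrow(gs))) {
    sites <- gs[A, ]
    for (j in seq_len(q)) {
      a <- states[sites[j]]
      for (b in adj[[a]]) {
        new_sites <- sites
        new_sites[j] <- match(b, states)
        from <- c(from, A)
        to <- c(to, group_state_index(new_sites, K))
        site <- c(site, j)
        alpha <- c(alpha, a)
        beta <- c(beta, b)
      }
    }
  }
  data.frame(from = from, to = to, site = site,
             alpha = alpha, beta = beta, stringsAsFactors = FALSE)
}
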