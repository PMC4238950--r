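# Shared fixtures and independent oracles for the test suite.

# Small fully-specified connectome: explicit matrices, no generators.
tiny_connectome <- function() {
  acp <- matrix(c(1.0, 0.5, 0.0,
                  0.5, 1.0, 0.8,
                  0.0, 0.8, 1.0), 3, 3, byrow = TRUE)
  len <- matrix(c(0, 30, 0,
                  30, 0, 50,
                  0, 50, 0), 3, 3, byrow = TRUE)
  connectome(acp, len)
}

# Random valid connectome for property tests (dense enough to be connected).
random_connectome <- function(n, seed, density = 0.6) {
  set.seed(seed)
  repeat {
    acp <- matrix(0, n, n)
    sel <- upper.tri(acp) & matrix(runif(n * n) < density, n, n)
    acp[sel] <- runif(sum(sel), 0.1, 1)
    acp <- acp + t(acp)
    diag(acp) <- 1
    len <- matrix(0, n, n)
    len[sel] <- runif(sum(sel), 10, 150)
    len <- len + t(len)
    offdiag <- acp
    diag(offdiag) <- 0
    g <- igraph::graph_from_adjacency_matrix((offdiag > 0) * 1,
                                             mode = "undirected")
    if (igraph::is_connected(g)) return(connectome(acp, len))
  }
}

# Brute-force shortest path over all simple paths (exponential; tiny n only).
brute_force_distance <- function(conn, sources, transform = "log") {
  n <- n_regions(conn)
  w <- matrix(Inf, n, n)
  offdiag <- conn$acp
  diag(offdiag) <- 0
  pos <- offdiag > 0
  w[pos] <- acp_edge_length(offdiag[pos], transform)
  best <- rep(Inf, n)
  best[sources] <- 0
  recurse <- function(node, visited, len) {
    if (len < best[node]) best[node] <<- len
    for (nb in seq_len(n)) {
      if (!visited[nb] && is.finite(w[node, nb])) {
        v <- visited
        v[nb] <- TRUE
        recurse(nb, v, len + w[node, nb])
      }
    }
  }
  for (s in sources) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    recurse(s, visited, 0)
  }
  best
}

# O(n^2) double-loop Gini oracle, straight from the definition.
gini_oracle <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Pure-R reference integrator following the update equations step by step,
# independent of the compiled path (same discretization, explicit loops).
r_reference_esm <- function(conn, params, seeds, n_steps) {
  n <- n_regions(conn)
  delay <- transmission_delays(conn, params)
  p <- matrix(0, n_steps + 1, n)
  p[1, seeds] <- params$p_seed_init
  dt <- params$dt
  for (t in seq_len(n_steps)) {
    cur <- p[t, ]
    g <- gini_coefficient(cur)
    btot_cur <- infection_rate(cur, params$beta0, params$sigmoid_slope,
                               params$sigmoid_mid)
    deltas <- clearance_rate(cur, params$delta0, params$clearance_decay)
    for (i in seq_len(n)) {
      prod_term <- 1
      for (j in seq_len(n)) {
        if (j == i || conn$acp[j, i] <= 0) next
        td <- (t - 1) - delay[j, i]
        if (td < 0) next # clean pre-outbreak history
        bj <- infection_rate(p[td + 1, j], params$beta0,
                             params$sigmoid_slope, params$sigmoid_mid)
        prod_term <- prod_term * (1 - conn$acp[j, i] * g * bj)
      }
      bint <- (1 - g) * btot_cur[i]
      R <- 1 - (1 - bint) * prod_term
      np <- cur[i] + dt * ((1 - cur[i]) * R - cur[i] * deltas[i]) +
        params$noise_mean * dt
      p[t + 1, i] <- min(max(np, 0), 1)
    }
  }
  p
}

# Cheap config for search-heavy tests: grid-only scoring.
cheap_cfg <- function(grid_n = 6, params = esm_params(0.5, 0.3)) {
  fit_config(grid_n = grid_n, refine = FALSE, sweep = FALSE, params = params)
}
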