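# Shared helpers for building small deterministic test objects.

random_mu <- function() stats::setNames(stats::runif(8, -1, 1), edge_names())

# A small standard configuration for engine tests; pi is an arbitrary but
# fixed moderate replication rate.
tiny_config <- function(n = 30, generations = 10, seed = 1, theta = 1,
                        alpha = 2, beta = 1, phi = 0, MH = 0.001,
                        MP = 2 * MH, mu_overrides = NULL, ...) {
  evolution_config(
    dynamics = dynamics_params(phi = phi, pi = 0.2),
    alpha = alpha, beta = beta, n = n, generations = generations,
    theta = theta, MH = MH, MP = MP, mu_overrides = mu_overrides,
    seed = seed, ...
  )
}

# Independent per-edge oracle: recompute every coefficient directly from raw
# bits, bypassing compute_interactions' internals.
brute_force_mu <- function(host, pathogen, L = 10L) {
  topo <- signaling_topology()
  vapply(seq_len(nrow(topo)), function(k) {
    g_src <- if (topo$source[k] == "P") pathogen else host
    g_tgt <- if (topo$target[k] == "P") pathogen else host
    s <- gene_domain(g_src, topo$source[k], "sender")
    r <- gene_domain(g_tgt, topo$target[k], "receiver")
    1 - 2 * sum(abs(s - r)) / L
  }, numeric(1))
}
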