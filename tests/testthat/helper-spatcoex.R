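# Shared fixtures: all built in code, no files.

# Reduced habitat (20 grid points) and shortened protocol for unit tests of
# the mechanics; acceptance-level checks use the full default configuration.
tiny_cfg <- function(...) {
  sim_config(Z = 0.1, n_gen = 10, ...)
}

# Hand-built network with explicit matrices, for arithmetic checks.
make_network <- function(rho, beta, alpha, r0, seed = 0L) {
  rho <- as.matrix(rho); beta <- as.matrix(beta); alpha <- as.matrix(alpha)
  structure(list(n_species = nrow(rho), n_mediators = ncol(rho),
                 rho = rho, beta = beta, alpha = alpha, r0 = r0,
                 seed = as.integer(seed),
                 params = list(qp = NA, qc = NA, fac_ratio = NA,
                               beta0 = NA, alpha0 = NA, rint0 = NA,
                               r0_range = range(r0))),
            class = "interaction_network")
}

# A single non-interacting species with exactly known basal rate.
lone_species_network <- function(r0 = 0.2) {
  make_network(rho = matrix(0, 1, 1), beta = matrix(0, 1, 1),
               alpha = matrix(0, 1, 1), r0 = r0)
}
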