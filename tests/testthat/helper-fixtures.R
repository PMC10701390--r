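# shared in-code fixtures; everything is generated at test time

# small NAM population: 9 families (4/3/2) x rils_per_family RILs
tiny_sim_config <- function(seed = 11, n_env = 6, rils_per_family = 30,
                            n_markers = 600, ...) {
  sim_config(n_families_g1 = 4, n_families_g2 = 3, n_families_g3 = 2,
             rils_per_family = rils_per_family, n_markers = n_markers,
             n_chromosomes = 6, n_env = n_env, seed = seed, ...)
}

tiny_pop <- function(seed = 11, ...) simulate_nam(tiny_sim_config(seed, ...))

# unit-variance component map used by several oracles
unit_vc <- c(E = 1, L = 0.5, F = 0.5, g = 1, gE = 0.5, FE = 0.5, resid = 1)

# deterministic {0,2} dosage matrix with rownames
rand_dosages <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(sample(c(0L, 2L), n * p, replace = TRUE), nrow = n)
  rownames(X) <- sprintf("R%04d", seq_len(n))
  colnames(X) <- sprintf("M%05d", seq_len(p))
  X
}

# independent brute-force E(S2): explicit p x p similarity matrix
es2_bruteforce <- function(X0, variant = "trace") {
  S <- t(X0) %*% X0
  S2 <- S %*% S
  if (variant == "trace") return(sum(diag(S2)))
  sum(S^2) - sum(diag(S)^2)
}
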