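test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(recomb_prob = 0.6), "recomb_prob")
  expect_error(sim_config(founder_divergence = c(g1 = -0.1, g2 = 0.2, g3 = 0.3)),
               "divergences")
  expect_error(sim_config(var_components = c(E = 1, L = 1, F = 1, g = 1,
                                             gE = 1, FE = 1, resid = -1)),
               "variance")
  expect_error(sim_config(var_components = c(E = 1)), "var_components")
  expect_error(sim_config(rils_per_family = 0), "rils_per_family")
})

test_that("simulate_founders: degenerate sizes and zero divergence", {
  cfg0 <- tiny_sim_config(n_markers = 0)
  f0 <- simulate_founders(cfg0)
  expect_equal(length(f0$hub), 0)
  expect_equal(dim(f0$founders), c(9, 0))

  cfg <- tiny_sim_config(n_markers = 200,
                         founder_divergence = c(g1 = 0, g2 = 0, g3 = 0))
  f <- simulate_founders(cfg)
  expect_true(all(f$founders == matrix(f$hub, nrow(f$founders),
                                       ncol(f$founders), byrow = TRUE)))
})

test_that("founder divergence ordering matches the per-marker flip model", {
  # MC oracle: flips are iid Bernoulli(divergence), so the mismatch rate
  # is divergence +- 3 binomial SEs over n_founders * p draws
  cfg <- sim_config(n_families_g1 = 5, n_families_g2 = 5, n_families_g3 = 5,
                    rils_per_family = 1, n_markers = 10000,
                    founder_divergence = c(g1 = 0.1, g2 = 0.2, g3 = 0.4),
                    seed = 42)
  f <- simulate_founders(cfg)
  mism <- rowMeans(f$founders != matrix(f$hub, nrow(f$founders), 10000,
                                        byrow = TRUE))
  rate <- tapply(mism, f$group, mean)
  for (g in c("G1", "G2", "G3")) {
    div <- cfg$founder_divergence[tolower(g)]
    se <- sqrt(div * (1 - div) / (5 * 10000))
    expect_lt(abs(rate[[g]] - div), 3 * se)
  }
  expect_gt(rate[["G3"]], rate[["G1"]])
})

test_that("simulate_ril_family: trivial modes", {
  map <- marker_map(50, 1)
  hub <- rep(0L, 50); fnd <- rep(1L, 50)
  # no recombination: each RIL is entirely hub or entirely founder
  g <- simulate_ril_family(hub, fnd, 40, map, recomb_prob = 0, seed = 3)
  expect_true(all(g %in% c(0L, 2L)))
  expect_true(all(apply(g, 1, function(r) all(r == 0) || all(r == 2))))
  # markers where the parents agree are fixed in every RIL
  hub2 <- rep(1L, 50)
  g2 <- simulate_ril_family(hub2, rep(1L, 50), 25, map, 0.3, seed = 4)
  expect_true(all(g2 == 2L))
  expect_error(simulate_ril_family(hub, fnd, 5, map, 0.7), "recomb_prob")
  expect_error(simulate_ril_family(hub, fnd[-1], 5, map, 0.1), "every marker")
})

test_that("RIL mosaics match a brute-force Markov-chain oracle", {
  # distinguishable parents so the mosaic state is readable off dosages
  p <- 101; r <- 0.1; n <- 2000
  map <- marker_map(p, 1)
  g <- simulate_ril_family(rep(0L, p), rep(1L, p), n, map, r, seed = 99)
  states <- g / 2
  hub_frac <- mean(states == 0)
  switches <- rowSums(abs(states[, -1] - states[, -p]))

  # independent brute-force chain simulation
  set.seed(1234)
  orc_frac <- orc_sw <- numeric(n)
  for (i in seq_len(n)) {
    s <- numeric(p)
    s[1] <- rbinom(1, 1, 0.5)
    for (j in 2:p) s[j] <- if (runif(1) < r) 1 - s[j - 1] else s[j - 1]
    orc_frac[i] <- mean(s == 0)
    orc_sw[i] <- sum(abs(diff(s)))
  }
  se_frac <- sd(orc_frac) / sqrt(n)
  se_sw <- sd(orc_sw) / sqrt(n)
  expect_lt(abs(hub_frac - mean(orc_frac)), 3 * sqrt(2) * se_frac)
  expect_lt(abs(mean(switches) - mean(orc_sw)), 3 * sqrt(2) * se_sw)
  # and against the analytic chain expectations
  expect_lt(abs(hub_frac - 0.5), 3 * se_frac * sqrt(2))
  expect_lt(abs(mean(switches) - (p - 1) * r), 3 * se_sw * sqrt(2))
})

test_that("simulate_nam is reproducible and fully inbred", {
  pop1 <- tiny_pop(seed = 21, n_markers = 200, rils_per_family = 5)
  pop2 <- tiny_pop(seed = 21, n_markers = 200, rils_per_family = 5)
  expect_identical(pop1$genotypes, pop2$genotypes)
  expect_identical(levels(pop1$family_ids), rownames(pop1$founders$founders))
  expect_equal(mean(pop1$genotypes == 1), 0)  # heterozygosity exactly 0
  expect_true(all(pop1$genotypes %in% c(0L, 2L)))
  expect_equal(nrow(pop1$genotypes), 9 * 5)
  # every RIL belongs to exactly one family
  expect_equal(length(pop1$ril_ids), length(unique(pop1$ril_ids)))
  pop3 <- tiny_pop(seed = 22, n_markers = 200, rils_per_family = 5)
  expect_false(identical(pop1$genotypes, pop3$genotypes))
})

test_that("simulate_phenotypes: degenerate variance maps", {
  pop <- tiny_pop(seed = 5, n_markers = 100, rils_per_family = 10, n_env = 4)
  vc0 <- c(E = 0, L = 0, F = 0, g = 0, gE = 0, FE = 0, resid = 1)
  cfg <- tiny_sim_config(seed = 5, n_env = 4, rils_per_family = 10,
                         n_markers = 100, mu = 50, var_components = vc0)
  ph <- simulate_phenotypes(pop, cfg, seed = 7)
  ym <- tapply(ph$phenotypes$value, ph$phenotypes$env_id, mean)
  expect_lt(abs(mean(ph$phenotypes$value) - 50), 3 / sqrt(nrow(ph$phenotypes)) * 3)
  expect_lt(max(ym) - min(ym), 4 * 3 / sqrt(90))
  # only E nonzero: within-environment variance exactly 0
  vcE <- c(E = 4, L = 0, F = 0, g = 0, gE = 0, FE = 0, resid = 0)
  cfgE <- tiny_sim_config(seed = 5, n_env = 4, rils_per_family = 10,
                          n_markers = 100, var_components = vcE)
  phE <- simulate_phenotypes(pop, cfgE, seed = 8)
  wv <- tapply(phE$phenotypes$value, phE$phenotypes$env_id, var)
  expect_equal(unname(max(wv)), 0)
  expect_equal(nrow(ph$phenotypes), 90 * 4)  # one record per cell
})

test_that("phenotype model decomposes into the configured variances", {
  # ANOVA-style MC oracle at 1,000 RILs x 6 environments: realized
  # component variances vs configuration, with a chi-square-aware band
  # (15% where the component has enough draws; 3 sampling SDs where the
  # level count itself is the limit, e.g. 6 environment draws)
  cfg <- sim_config(n_families_g1 = 9, n_families_g2 = 8, n_families_g3 = 8,
                    rils_per_family = 40, n_markers = 400, n_chromosomes = 5,
                    n_env = 6, mu = 0, var_components = unit_vc, seed = 77)
  pop <- simulate_nam(cfg)
  ph <- simulate_phenotypes(pop, cfg, seed = 78)
  ef <- ph$effects
  n <- length(pop$ril_ids); J <- cfg$n_env; m <- nlevels(pop$family_ids)
  realized <- c(E = mean(ef$E^2), L = mean(ef$L^2), F = mean(ef$F^2),
                g = mean(ef$g^2), gE = mean(ef$gE^2), FE = mean(ef$FE^2))
  draws <- c(E = J, L = n, F = m, g = n, gE = n * J, FE = m * J)
  for (comp in names(realized)) {
    tol <- max(0.15, 3 * sqrt(2 / draws[[comp]]))
    expect_lt(abs(realized[[comp]] - unit_vc[[comp]]) / unit_vc[[comp]], tol)
  }
  # assembly is exact: y == mu + sum of stored components
  fam <- as.integer(pop$family_ids)
  y_rebuilt <- cfg$mu + rep(ef$E, each = n) + ef$L[ph$phenotypes$ril_id] +
    ef$F[fam] + ef$g[ph$phenotypes$ril_id] + as.vector(ef$gE) +
    as.vector(ef$FE[fam, ])
  eps <- ph$phenotypes$value - y_rebuilt
  expect_lt(abs(mean(eps^2) - unit_vc[["resid"]]) / unit_vc[["resid"]], 0.15)
  expect_lt(abs(cor(eps, y_rebuilt)), 0.05)  # residual independent of signal
  # total variance and broad-sense signal fraction
  tot <- var(ph$phenotypes$value)
  expect_lt(abs(tot - sum(unit_vc)) / sum(unit_vc), 0.15)
  signal <- 1 - mean(eps^2) / tot
  expect_lt(abs(signal - (1 - unit_vc[["resid"]] / sum(unit_vc))), 0.1)
})

test_that("same seed gives bit-identical phenotypes", {
  pop <- tiny_pop(seed = 31, n_markers = 120, rils_per_family = 6, n_env = 3)
  a <- simulate_phenotypes(pop, seed = 9)
  b <- simulate_phenotypes(pop, seed = 9)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$effects$gE, b$effects$gE)
})
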