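test_that("qc_filter applies the hand-enumerated thresholds", {
  # 4 RILs x 5 markers: missingness {0, 25, 0, 50, 0}%,
  # MAF {0.5, *, 0, 0.5, 0.25}; survivors are markers 1 and 5
  raw <- cbind(M1 = c(0, 0, 2, 2),
               M2 = c(0, 2, 2, NA),
               M3 = c(0, 0, 0, 0),
               M4 = c(NA, NA, 0, 2),
               M5 = c(0, 0, 0, 2))
  qc <- qc_filter(raw, max_missing = 0.20, min_maf = 0.03)
  expect_equal(colnames(qc$X), c("M1", "M5"))
  expect_equal(sort(qc$dropped$marker), c("M2", "M3", "M4"))
  expect_equal(qc$dropped$reason[qc$dropped$marker == "M3"], "maf")
  expect_equal(qc$dropped$reason[qc$dropped$marker == "M4"], "missingness")
  # retained columns have mean 0 and divisor-n variance 1
  expect_equal(unname(colMeans(qc$X)), c(0, 0))
  expect_equal(unname(colMeans(qc$X^2)), c(1, 1))
  expect_error(qc_filter(cbind(c(0, 0), c(0, 0))), "survive")
  expect_error(qc_filter(cbind(c(0, 3))), "dosages")
})

test_that("clean panels pass through qc untouched", {
  X <- rand_dosages(30, 40, seed = 2)
  qc <- qc_filter(X)
  mono <- apply(X, 2, function(c) length(unique(c)) == 1)
  expect_equal(qc$p, sum(!mono))
  expect_lt(max(abs(colMeans(qc$X))), 1e-12)
})

test_that("build_grm matches hand linear algebra and trace identity", {
  # 3 RILs x 2 markers, dosages rows (0,2),(2,0),(2,2)
  X <- rbind(a = c(0, 2), b = c(2, 0), c = c(2, 2))
  Xs <- sparsegp:::standardize_dosages(X)
  G <- build_grm(Xs)
  G_hand <- matrix(c(1.25, -1, -0.25,
                     -1, 1.25, -0.25,
                     -0.25, -0.25, 0.5), nrow = 3, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(G, G_hand)
  expect_equal(sum(diag(G)) / nrow(G), 1)
  # duplicated rows give off-diagonal equal to the shared diagonal
  X2 <- rbind(X, a2 = c(0, 2))
  G2 <- build_grm(sparsegp:::standardize_dosages(X2))
  expect_equal(G2["a", "a2"], G2["a", "a"])
  expect_error(build_grm(matrix(numeric(0), 3, 0)), "markers")
})

test_that("kernels match the brute-force double-loop definition", {
  set.seed(3)
  rils <- sprintf("r%d", 1:10)
  fams <- rep(c("f1", "f2"), each = 5)
  X <- rand_dosages(10, 30, seed = 4)
  rownames(X) <- rils
  G <- build_grm(qc_filter(X)$X)
  rec <- grid_records(rils, c("E1", "E2", "E3"), fams)
  ks <- build_kernels("M3", rec, G)
  expect_length(ks$terms, 6)
  expect_length(build_kernels("M1", rec, G)$terms, 3)
  N <- nrow(rec)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    same_env <- rec$env_id[a] == rec$env_id[b]
    expect_identical(ks$terms$E$K[a, b], as.numeric(same_env))
    gexp <- if (same_env) G[rec$ril_id[a], rec$ril_id[b]] else 0
    expect_equal(ks$terms$GE$K[a, b], gexp)
    fexp <- as.numeric(rec$family_id[a] == rec$family_id[b] && same_env)
    expect_equal(ks$terms$FE$K[a, b], fexp)
  }
  expect_error(build_kernels("M3", transform(rec, family_id = NA), G),
               "family_id")
  expect_error(build_kernels("M1", transform(rec, ril_id = "zz"), G),
               "absent")
})

test_that("analytic grid eigendecompositions reproduce the kernels", {
  rils <- sprintf("r%d", 1:8)
  fams <- rep(c("f1", "f2", "f3"), c(3, 3, 2))
  X <- rand_dosages(8, 25, seed = 6)
  rownames(X) <- rils
  G <- build_grm(qc_filter(X)$X)
  rec <- grid_records(rils, c("E1", "E2"), fams)
  ks <- build_kernels("M3", rec, G)
  for (t in names(ks$terms)) {
    e <- ks$terms[[t]]$eig
    expect_false(is.null(e))
    K_rebuilt <- e$vectors %*% (e$values * t(e$vectors))
    expect_equal(unname(K_rebuilt), unname(ks$terms[[t]]$K), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # orthonormal eigenvectors
    expect_equal(crossprod(e$vectors), diag(ncol(e$vectors)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("fit_gibbs handles degenerate constant data", {
  rils <- sprintf("r%d", 1:6)
  X <- rand_dosages(6, 20, seed = 8)
  rownames(X) <- rils
  G <- build_grm(qc_filter(X)$X)
  rec <- grid_records(rils, c("E1", "E2"), rep("f1", 6))
  ks <- build_kernels("M1", rec, G)
  y <- rep(5, nrow(rec))
  fit <- fit_gibbs(y, ks, mcmc_config(n_iter = 600, burn_in = 100, thin = 1,
                                      seed = 1))
  expect_lt(abs(fit$mu - 5), 1e-2)
  expect_lt(max(abs(unlist(fit$effects))), 1e-2)
  expect_lt(max(fit$var_components), 1e-3)
  expect_error(fit_gibbs(rep(NA_real_, nrow(rec)), ks), "observed")
  expect_error(fit_gibbs(y, ks, mcmc_config(n_iter = 10, burn_in = 20)),
               "burn_in")
})

test_that("gibbs chains are reproducible and shift-equivariant", {
  rils <- sprintf("r%d", 1:12)
  X <- rand_dosages(12, 40, seed = 10)
  rownames(X) <- rils
  G <- build_grm(qc_filter(X)$X)
  rec <- grid_records(rils, c("E1", "E2", "E3"), rep(c("f1", "f2"), 6))
  ks <- build_kernels("M2", rec, G)
  set.seed(77)
  y <- rnorm(nrow(rec), 10)
  y[sample.int(length(y), 6)] <- NA
  mc <- mcmc_config(n_iter = 500, burn_in = 100, thin = 1, seed = 42)
  f1 <- fit_gibbs(y, ks, mc)
  f2 <- fit_gibbs(y, ks, mc)
  expect_identical(f1$chains$var, f2$chains$var)
  expect_identical(f1$yhat, f2$yhat)
  # adding a constant shifts predictions by that constant
  f3 <- fit_gibbs(y + 100, ks, mc)
  expect_equal(f3$yhat, f1$yhat + 100, tolerance = 1e-8)
})

test_that("predictions are consistent and order-invariant", {
  rils <- sprintf("r%d", 1:10)
  X <- rand_dosages(10, 30, seed = 12)
  rownames(X) <- rils
  G <- build_grm(qc_filter(X)$X)
  rec <- grid_records(rils, c("E1", "E2"), rep(c("f1", "f2"), 5))
  ks <- build_kernels("M1", rec, G)
  set.seed(5)
  y <- rnorm(nrow(rec))
  y[c(3, 18)] <- NA
  fit <- fit_gibbs(y, ks, mcmc_config(n_iter = 400, burn_in = 100, thin = 1,
                                      seed = 9))
  # observed cells: prediction equals the fitted value
  pr <- predict_missing(fit, data.frame(ril_id = rec$ril_id[1],
                                        env_id = rec$env_id[1]))
  expect_equal(pr$y_pred, fit$yhat[1])
  # permuting the request order permutes the output identically
  cells <- rec[c(3, 18, 7), c("ril_id", "env_id")]
  p1 <- predict_missing(fit, cells)
  p2 <- predict_missing(fit, cells[c(3, 1, 2), ])
  expect_equal(p1$y_pred[match(paste(p2$ril_id, p2$env_id),
                               paste(p1$ril_id, p1$env_id))], p2$y_pred)
  expect_error(predict_missing(fit, data.frame(ril_id = "nope",
                                               env_id = "E1")),
               "record index")
})

test_that("fixed-variance gibbs matches conditional-mean prediction on a tiny instance", {
  # joint-Gaussian oracle: with known variances the posterior mean of the
  # genetic effect is K (K + lambda I)^{-1} (y - mu)
  n <- 12
  X <- rand_dosages(n, 50, seed = 14)
  G <- build_grm(qc_filter(X)$X)
  rec <- data.frame(ril_id = rownames(X), env_id = "E1",
                    family_id = NA_character_)
  ks <- structure(list(terms = list(G = list(label = "G", K = G, eig = NULL)),
                       records = rec, model = "single"),
                  class = "kernel_set")
  set.seed(15)
  sg <- 2; se <- 1
  y <- 3 + drop(chol(G + diag(1e-6, n)) %*% rnorm(n)) * sqrt(sg) +
    rnorm(n, 0, sqrt(se))
  mc <- mcmc_config(n_iter = 6000, burn_in = 1000, thin = 1, seed = 16,
                    fixed_variances = list(G = sg, resid = se),
                    store_effect_chains = TRUE)
  fit <- fit_gibbs(y, ks, mc)
  u_closed <- drop(sg * G %*% solve(sg * G + diag(se, n)) %*% (y - fit$mu))
  ch <- fit$chains$effects[[1]]
  nb <- 25
  bm <- apply(ch, 2, function(col) {
    means <- colMeans(matrix(col[seq_len(nb * (length(col) %/% nb))],
                             ncol = nb))
    sd(means) / sqrt(nb)
  })
  expect_true(all(abs(fit$effects$G - u_closed) < 3 * bm + 1e-3 * sd(y)))
})
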