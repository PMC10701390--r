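#' Simulation configuration for a NAM population
#'
#' Collects every tunable of the synthetic nested-association-mapping
#' (NAM) world: family counts per founder ancestry group, RILs per
#' family, marker panel layout, recombination intensity, founder
#' divergence from the hub parent, number of environments, and the
#' variance components of the phenotype model
#' \deqn{y_{ij} = \mu + E_j + L_i + F_k + g_i + gE_{ij} + FE_{kj} + \epsilon_{ij}.}
#'
#' Defaults emulate the SoyNAM-like structure the package targets:
#' 39 bi-parental families (16 elite, 15 diverse, 8 exotic founders) each
#' contributing 45 fully inbred RILs (1,755 total), a panel of 4,100
#' biallelic SNPs on 20 chromosomes, and 9 environments. Variance
#' components are on the grain-yield scale (kg ha^-1)^2; see the methods
#' vignette for the rationale behind each default.
#'
#' @param n_families_g1,n_families_g2,n_families_g3 number of founder
#'   families in ancestry groups G1 (elite), G2 (diverse), G3 (exotic).
#' @param rils_per_family RILs derived from each cross (>= 1).
#' @param n_markers total biallelic SNPs (>= 0).
#' @param n_chromosomes chromosomes the markers are spread over.
#' @param recomb_prob per-adjacent-marker switch probability of the
#'   hub/founder mosaic, in \[0, 0.5\].
#' @param founder_divergence named numeric `c(g1=, g2=, g3=)`; per-marker
#'   probability that a founder allele differs from the hub allele, in
#'   \[0, 1\]. Must be ordered so exotic founders diverge most if the
#'   G1 < G2 < G3 diversity ordering is wanted (not enforced).
#' @param n_env number of environments J (>= 1).
#' @param mu grand mean, kg ha^-1.
#' @param var_components named nonnegative numeric with entries
#'   `E`, `L`, `F`, `g`, `gE`, `FE`, `resid` ((kg ha^-1)^2).
#' @param seed integer master seed for the population draw.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_nam()], [simulate_phenotypes()]
#' @export
sim_config <- function(n_families_g1 = 16, n_families_g2 = 15,
                       n_families_g3 = 8, rils_per_family = 45,
                       n_markers = 4100, n_chromosomes = 20,
                       recomb_prob = 0.01,
                       founder_divergence = c(g1 = 0.10, g2 = 0.20, g3 = 0.35),
                       n_env = 9, mu = 3560,
                       var_components = c(E = 202500, L = 30625, F = 40000,
                                          g = 75625, gE = 50625, FE = 40000,
                                          resid = 122500),
                       seed = 1L) {
  vc_keys <- c("E", "L", "F", "g", "gE", "FE", "resid")
  var_components <- unlist(var_components)
  if (!all(vc_keys %in% names(var_components))) {
    stop("var_components must contain: ",
         paste(setdiff(vc_keys, names(var_components)), collapse = ", "),
         call. = FALSE)
  }
  var_components <- var_components[vc_keys]
  if (any(var_components < 0)) stop("all variance components must be >= 0",
                                    call. = FALSE)
  fd <- unlist(founder_divergence)
  if (!all(c("g1", "g2", "g3") %in% names(fd))) {
    stop("founder_divergence needs named entries g1, g2, g3", call. = FALSE)
  }
  fd <- fd[c("g1", "g2", "g3")]
  if (any(fd < 0 | fd > 1)) stop("founder divergences must lie in [0, 1]",
                                 call. = FALSE)
  if (recomb_prob < 0 || recomb_prob > 0.5) {
    stop("recomb_prob must lie in [0, 0.5]", call. = FALSE)
  }
  if (rils_per_family < 1) stop("rils_per_family must be >= 1", call. = FALSE)
  if (n_markers < 0) stop("n_markers must be >= 0", call. = FALSE)
  if (n_env < 1) stop("n_env must be >= 1", call. = FALSE)
  structure(list(
    n_families_g1 = as.integer(n_families_g1),
    n_families_g2 = as.integer(n_families_g2),
    n_families_g3 = as.integer(n_families_g3),
    rils_per_family = as.integer(rils_per_family),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(max(1, n_chromosomes)),
    recomb_prob = recomb_prob,
    founder_divergence = fd,
    n_env = as.integer(n_env),
    mu = mu,
    var_components = var_components,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Marker map for a simulated panel
#'
#' Spreads `n_markers` as evenly as possible over `n_chromosomes`,
#' assigning a within-chromosome order to each marker.
#'
#' @param n_markers,n_chromosomes panel layout.
#' @return data.frame with columns `marker`, `chromosome`, `order`.
#' @export
marker_map <- function(n_markers, n_chromosomes) {
  if (n_markers == 0) {
    return(data.frame(marker = character(0), chromosome = integer(0),
                      order = integer(0)))
  }
  bounds <- floor(seq(0, n_markers, length.out = n_chromosomes + 1))
  sizes <- diff(bounds)
  data.frame(
    marker = sprintf("M%05d", seq_len(n_markers)),
    chromosome = rep(seq_len(n_chromosomes), sizes),
    order = unlist(lapply(sizes, seq_len), use.names = FALSE)
  )
}

#' Simulate hub and founder haplotypes
#'
#' The hub parent haplotype is drawn with allele frequency 0.5 at every
#' marker; each founder's haplotype is the hub's with a per-marker allele
#' flip at its group's divergence probability. Higher divergence yields a
#' higher expected hub-founder mismatch rate, reproducing the
#' elite < diverse < exotic ancestry ordering.
#'
#' @param config a [sim_config()].
#' @param seed optional seed (defaults to `config$seed`).
#' @return list with `hub` (0/1 vector of length p), `founders`
#'   (founder x marker 0/1 matrix) and `group` (factor of ancestry
#'   labels G1/G2/G3 per founder).
#' @export
simulate_founders <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .seed_if(seed)
  p <- config$n_markers
  counts <- c(config$n_families_g1, config$n_families_g2, config$n_families_g3)
  m <- sum(counts)
  group <- factor(rep(c("G1", "G2", "G3"), counts), levels = c("G1", "G2", "G3"))
  hub <- rbinom(p, 1L, 0.5)
  div <- config$founder_divergence[c("g1", "g2", "g3")][as.integer(group)]
  founders <- matrix(0L, nrow = m, ncol = p)
  if (p > 0 && m > 0) {
    flip <- matrix(runif(m * p), nrow = m) < div
    founders <- matrix(rep(hub, each = m), nrow = m)
    founders[flip] <- 1L - founders[flip]
  }
  rownames(founders) <- sprintf("F%02d", seq_len(m))
  list(hub = hub, founders = founders, group = group)
}

#' Simulate one bi-parental RIL family
#'
#' Each RIL inherits, chromosome by chromosome, a mosaic of hub- and
#' founder-derived segments produced by a two-state Markov chain whose
#' per-adjacent-marker switch probability is `recomb_prob` (a
#' Haldane-like, no-interference approximation of recombination during
#' repeated selfing). RILs are fully inbred: the mosaic haplotype is
#' doubled, so dosages are 0 or 2.
#'
#' @param hub,founder 0/1 haplotypes defined at every marker.
#' @param n_rils number of RILs to derive.
#' @param map marker map as from [marker_map()] (same marker count).
#' @param recomb_prob switch probability in \[0, 0.5\].
#' @param seed optional RNG seed.
#' @return `n_rils` x p integer dosage matrix with entries in \{0, 2\}.
#' @export
simulate_ril_family <- function(hub, founder, n_rils, map, recomb_prob,
                                seed = NULL) {
  if (recomb_prob < 0 || recomb_prob > 0.5) {
    stop("recomb_prob must lie in [0, 0.5]", call. = FALSE)
  }
  p <- length(hub)
  if (length(founder) != p) stop("hub and founder must be defined at every marker",
                                 call. = FALSE)
  if (nrow(map) != p) stop("marker map does not match marker count", call. = FALSE)
  .seed_if(seed)
  geno <- matrix(0L, nrow = n_rils, ncol = p)
  if (p == 0 || n_rils == 0) return(geno)
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)[order(map$order[map$chromosome == chr])]
    L <- length(idx)
    # state 0 = hub-derived, 1 = founder-derived; cumulative XOR of switches
    init <- rbinom(n_rils, 1L, 0.5)
    if (L > 1) {
      switches <- matrix(runif(n_rils * (L - 1)) < recomb_prob, nrow = n_rils)
      cum <- matrix(0L, nrow = n_rils, ncol = L)
      cum[, -1] <- t(apply(switches, 1, cumsum))
      states <- (init + cum) %% 2L
    } else {
      states <- matrix(init, ncol = 1)
    }
    hapH <- matrix(rep(hub[idx], each = n_rils), nrow = n_rils)
    hapF <- matrix(rep(founder[idx], each = n_rils), nrow = n_rils)
    geno[, idx] <- 2L * ifelse(states == 1L, hapF, hapH)
  }
  storage.mode(geno) <- "integer"
  geno
}

#' Simulate a NAM population
#'
#' Draws founders with [simulate_founders()] and derives every family
#' with [simulate_ril_family()], producing a fully inbred RIL panel in
#' which all families share the hub parent.
#'
#' @param config a [sim_config()].
#' @return object of class `nam_population`: list with `genotypes`
#'   (RIL x marker \{0,2\} matrix with ril ids as rownames), `ril_ids`,
#'   `family_ids` (factor), `ancestry` (factor per RIL), `marker_map`,
#'   `founders` (the [simulate_founders()] output) and `config`.
#' @export
simulate_nam <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fnd <- simulate_founders(config, seed = NULL)  # continue the seeded stream
  map <- marker_map(config$n_markers, config$n_chromosomes)
  m <- nrow(fnd$founders)
  n_r <- config$rils_per_family
  geno <- matrix(0L, nrow = m * n_r, ncol = config$n_markers)
  fam_names <- rownames(fnd$founders)
  ril_ids <- as.vector(t(outer(fam_names, sprintf("R%03d", seq_len(n_r)),
                               paste, sep = "_")))
  for (k in seq_len(m)) {
    rows <- ((k - 1) * n_r + 1):(k * n_r)
    geno[rows, ] <- simulate_ril_family(fnd$hub, fnd$founders[k, ], n_r, map,
                                        config$recomb_prob, seed = NULL)
  }
  rownames(geno) <- ril_ids
  colnames(geno) <- map$marker
  family_ids <- factor(rep(fam_names, each = n_r), levels = fam_names)
  ancestry <- factor(rep(as.character(fnd$group), each = n_r),
                     levels = c("G1", "G2", "G3"))
  structure(list(
    genotypes = geno,
    ril_ids = ril_ids,
    family_ids = family_ids,
    ancestry = ancestry,
    marker_map = map,
    founders = fnd,
    config = config
  ), class = "nam_population")
}

#' @export
print.nam_population <- function(x, ...) {
  cat(sprintf(
    "NAM population: %d RILs, %d families (G1 %d / G2 %d / G3 %d), %d markers on %d chromosomes\n",
    nrow(x$genotypes), nlevels(x$family_ids),
    sum(x$founders$group == "G1"), sum(x$founders$group == "G2"),
    sum(x$founders$group == "G3"),
    ncol(x$genotypes), max(x$marker_map$chromosome, 0)))
  invisible(x)
}

# center and standardize dosages by column, divisor-n variance;
# zero-variance columns are left at 0 so they contribute nothing
standardize_dosages <- function(geno) {
  n <- nrow(geno)
  X <- scale(geno, center = TRUE, scale = FALSE)
  sdn <- sqrt(colMeans(X^2))
  keep <- sdn > 0
  X[, keep] <- sweep(X[, keep, drop = FALSE], 2, sdn[keep], "/")
  X[, !keep] <- 0
  attr(X, "scaled:center") <- NULL
  X
}

#' Simulate phenotypes for a NAM population
#'
#' Generates the fully balanced RIL x environment phenotype table under
#' the variance-component model
#' \deqn{y_{ij} = \mu + E_j + L_i + F_k + g_i + gE_{ij} + FE_{kj} + \epsilon_{ij}}
#' with independent Gaussian components at the configured variances. The
#' genomic value is `g = X beta` with `X` the centered, standardized
#' (divisor n) dosage matrix and i.i.d. marker effects scaled so the
#' marginal variance of `g` equals `var_components["g"]`; the
#' genotype-by-environment term uses independent environment-specific
#' marker-effect deviations scaled the same way.
#'
#' @param pop a [simulate_nam()] population.
#' @param config the [sim_config()] holding `mu`, `n_env` and
#'   `var_components`.
#' @param seed optional seed (default `config$seed + 1` so the phenotype
#'   draw is distinct from, but tied to, the population draw).
#' @return list of class `nam_phenotypes` with elements
#'   `phenotypes` (long data.frame: ril_id, family_id, ancestry_group,
#'   env_id, value, observed) and `effects` (class `true_effects`: the
#'   realized E, L, F, g, gE, FE components and marker effect vectors).
#' @export
simulate_phenotypes <- function(pop, config = pop$config,
                                seed = config$seed + 1L) {
  stopifnot(inherits(pop, "nam_population"))
  n <- nrow(pop$genotypes)
  if (n == 0) stop("population is empty", call. = FALSE)
  J <- config$n_env
  vc <- config$var_components
  .seed_if(seed)
  p <- ncol(pop$genotypes)
  X <- standardize_dosages(pop$genotypes)
  m <- nlevels(pop$family_ids)
  env_ids <- sprintf("E%d", seq_len(J))

  E <- rnorm(J, 0, sqrt(vc["E"]))
  L <- rnorm(n, 0, sqrt(vc["L"]))
  F_ <- rnorm(m, 0, sqrt(vc["F"]))
  if (p > 0) {
    beta <- rnorm(p, 0, sqrt(vc["g"] / p))
    g <- drop(X %*% beta)
    beta_env <- matrix(rnorm(p * J, 0, sqrt(vc["gE"] / p)), nrow = p)
    gE <- X %*% beta_env  # n x J
  } else {
    beta <- numeric(0)
    g <- numeric(n)
    beta_env <- matrix(numeric(0), nrow = 0, ncol = J)
    gE <- matrix(0, nrow = n, ncol = J)
  }
  FE <- matrix(rnorm(m * J, 0, sqrt(vc["FE"])), nrow = m)
  eps <- matrix(rnorm(n * J, 0, sqrt(vc["resid"])), nrow = n)

  fam_idx <- as.integer(pop$family_ids)
  ymat <- config$mu +
    matrix(rep(E, each = n), nrow = n) +
    L + F_[fam_idx] + g +
    gE + FE[fam_idx, , drop = FALSE] + eps

  phen <- data.frame(
    ril_id = rep(pop$ril_ids, times = J),
    family_id = rep(as.character(pop$family_ids), times = J),
    ancestry_group = rep(as.character(pop$ancestry), times = J),
    env_id = rep(env_ids, each = n),
    value = as.vector(ymat),
    observed = TRUE,
    stringsAsFactors = FALSE
  )
  effects <- structure(list(
    E = setNames(E, env_ids),
    L = setNames(L, pop$ril_ids),
    F = setNames(F_, levels(pop$family_ids)),
    g = setNames(g, pop$ril_ids),
    gE = `dimnames<-`(gE, list(pop$ril_ids, env_ids)),
    FE = `dimnames<-`(FE, list(levels(pop$family_ids), env_ids)),
    beta = beta, beta_env = beta_env
  ), class = "true_effects")
  structure(list(phenotypes = phen, effects = effects),
            class = "nam_phenotypes")
}
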