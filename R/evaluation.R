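#' Pearson correlation between predicted and observed values
#'
#' Standard Pearson estimate; returns `NA` (the "undefined" flag) when
#' either vector is constant, and errors on a length mismatch.
#'
#' @param pred,obs numeric vectors of equal length (>= 2).
#' @return correlation coefficient or `NA_real_`.
#' @export
pearson <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (sd(pred) == 0 || sd(obs) == 0) return(NA_real_)
  cor(pred, obs)
}

#' Predictive-ability table
#'
#' Within-environment Pearson correlations between predictions and
#' truth, overall (`stratum = "all"`) and post-stratified by the
#' supplied strata (e.g. ancestry groups or families). For each stratum
#' a `"mean"` row carries the arithmetic mean of that stratum's
#' per-environment correlations (undefined rows excluded and counted).
#'
#' @param pred data.frame `ril_id`, `env_id`, `y_pred`.
#' @param truth data.frame `ril_id`, `env_id`, `value` covering every
#'   predicted cell.
#' @param strata optional; either a data.frame `ril_id`, `stratum` or a
#'   named list of RIL id vectors.
#' @return data.frame of class `results_table` with columns `stratum`,
#'   `env_id` (or `"mean"`), `r`, `n_pairs`, `undefined`.
#' @export
ability_table <- function(pred, truth, strata = NULL) {
  key <- paste(truth$ril_id, truth$env_id, sep = "\r")
  idx <- match(paste(pred$ril_id, pred$env_id, sep = "\r"), key)
  if (anyNA(idx)) stop("every predicted cell needs a truth value",
                       call. = FALSE)
  dat <- data.frame(ril_id = pred$ril_id, env_id = pred$env_id,
                    y_pred = pred$y_pred, value = truth$value[idx],
                    stringsAsFactors = FALSE)
  if (is.data.frame(strata)) {
    strata <- split(strata$ril_id, strata$stratum)
  }
  groups <- c(list(all = unique(dat$ril_id)), strata)
  envs <- unique(dat$env_id)
  rows <- list()
  for (s in names(groups)) {
    rs <- numeric(0)
    for (ev in envs) {
      sub <- dat[dat$env_id == ev & dat$ril_id %in% groups[[s]], ]
      if (nrow(sub) < 2) {
        r <- NA_real_
      } else {
        r <- pearson(sub$y_pred, sub$value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, env_id = ev, r = r, n_pairs = nrow(sub),
        undefined = is.na(r), stringsAsFactors = FALSE)
      rs <- c(rs, r)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, env_id = "mean", r = mean(rs, na.rm = TRUE),
      n_pairs = sum(!is.na(rs)), undefined = all(is.na(rs)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("results_table", class(out))
  out
}

#' Between-environment phenotype correlations
#'
#' Pearson correlation of a RIL sample's phenotypes between every
#' unordered pair of environments — `J(J-1)/2` values, 36 at J = 9 —
#' with median and quartiles as the stability summary.
#'
#' @param phenotypes long data.frame `ril_id`, `env_id`, `value`.
#' @param sample_rils optional RIL subset (must be observed in every
#'   environment).
#' @return list with `pairs` (data.frame `env_a`, `env_b`, `r`),
#'   `n_pairs`, `median`, `q1`, `q3`.
#' @export
env_pair_correlations <- function(phenotypes, sample_rils = NULL) {
  if (!is.null(sample_rils)) {
    phenotypes <- phenotypes[phenotypes$ril_id %in% sample_rils, ]
  }
  envs <- unique(phenotypes$env_id)
  J <- length(envs)
  if (J < 2) stop("need at least 2 environments", call. = FALSE)
  rils <- unique(phenotypes$ril_id)
  wide <- matrix(NA_real_, length(rils), J,
                 dimnames = list(rils, envs))
  wide[cbind(match(phenotypes$ril_id, rils),
             match(phenotypes$env_id, envs))] <- phenotypes$value
  if (anyNA(wide)) stop("sample RILs must be observed in all environments",
                        call. = FALSE)
  pairs <- utils::combn(J, 2)
  r <- apply(pairs, 2, function(ab) pearson(wide[, ab[1]], wide[, ab[2]]))
  list(pairs = data.frame(env_a = envs[pairs[1, ]], env_b = envs[pairs[2, ]],
                          r = r, stringsAsFactors = FALSE),
       n_pairs = ncol(pairs),
       median = median(r, na.rm = TRUE),
       q1 = unname(quantile(r, 0.25, na.rm = TRUE)),
       q3 = unname(quantile(r, 0.75, na.rm = TRUE)))
}

#' Run a sparse-testing prediction experiment
#'
#' Orchestrates the full pipeline for every replicate and every cell of
#' a size x composition grid: simulate (or reuse) a NAM population and
#' phenotypes, build the base allocation, derive the composition, fit
#' each requested model on the observed cells, predict the evaluated
#' prediction sets and score predictive ability. All stage seeds are
#' derived deterministically from `seed` via [derive_seed()].
#'
#' For simulated inputs each replicate draws a fresh population and
#' phenotype realization; with user-supplied `data` only the allocation
#' varies between replicates.
#'
#' @param sim a [sim_config()]; ignored when `data` is given.
#' @param data optional list with elements `pop` (a `nam_population`)
#'   and `phenotypes` (long truth table).
#' @param grid data.frame with `n_per_env`, `n_overlap` (e.g. from
#'   [composition_grid()]).
#' @param models character subset of `c("M1", "M2", "M3")`.
#' @param replicates number of replicates.
#' @param mcmc an [mcmc_config()].
#' @param seed master seed.
#' @param strata `"ancestry"` (default), `"family"`, `"both"` or
#'   `"none"` — the post-stratifications added to the `"all"` rows.
#' @return list with `results` (data.frame: replicate, n_per_env,
#'   n_overlap, model, stratum, env_id, r, n_pairs, undefined, failed)
#'   and `provenance` (seeds, config echo, package version).
#' @export
run_experiment <- function(sim = sim_config(), data = NULL,
                           grid = data.frame(n_per_env = 45, n_overlap = 0),
                           models = c("M1", "M2", "M3"),
                           replicates = 5, mcmc = mcmc_config(),
                           seed = 1L, strata = "ancestry") {
  models <- match.arg(models, c("M1", "M2", "M3"), several.ok = TRUE)
  results <- list()
  for (rep_i in seq_len(replicates)) {
    if (is.null(data)) {
      cfg <- sim
      cfg$seed <- derive_seed(seed, "simulate", rep_i)
      pop <- simulate_nam(cfg)
      phen <- simulate_phenotypes(pop, cfg)$phenotypes
    } else {
      pop <- data$pop
      phen <- data$phenotypes
      cfg <- pop$config
    }
    qc <- qc_filter(pop$genotypes)
    G <- build_grm(qc$X)
    env_ids <- unique(phen$env_id)
    fam_of_ril <- as.character(pop$family_ids)
    records <- grid_records(pop$ril_ids, env_ids, fam_of_ril)
    # superset of kernels shared by all models for this replicate
    kern_all <- build_kernels("M3", records, G)
    truth_key <- paste(phen$ril_id, phen$env_id, sep = "\r")
    y_true <- phen$value[match(paste(records$ril_id, records$env_id,
                                     sep = "\r"), truth_key)]
    base <- allocate_base(pop$ril_ids, length(env_ids),
                          seed = derive_seed(seed, "allocate", rep_i))
    strata_list <- experiment_strata(pop, strata)
    for (gi in seq_len(nrow(grid))) {
      spec <- design_spec(grid$n_per_env[gi], grid$n_overlap[gi],
                          seed = derive_seed(seed, "compose",
                                             rep_i * 10000 + gi))
      alloc <- derive_composition(base, spec)
      tr <- training_sets(alloc)
      obs_key <- unlist(lapply(seq_along(tr), function(j) {
        paste(tr[[j]], names(tr)[j], sep = "\r")
      }), use.names = FALSE)
      y <- y_true
      y[!(paste(records$ril_id, records$env_id, sep = "\r") %in% obs_key)] <- NA
      ev <- evaluated_prediction(alloc)
      cells <- data.frame(
        ril_id = unlist(ev, use.names = FALSE),
        env_id = rep(names(ev), lengths(ev)),
        stringsAsFactors = FALSE)
      for (mod in models) {
        labs <- switch(mod, M1 = c("E", "L", "G"),
                       M2 = c("E", "L", "G", "GE"),
                       M3 = c("E", "L", "G", "GE", "F", "FE"))
        kern <- kern_all
        kern$terms <- kern_all$terms[labs]
        kern$model <- mod
        mc <- mcmc
        mc$seed <- derive_seed(seed, "fit",
                               rep_i * 1000000 + gi * 100 + match(mod, models))
        tab <- tryCatch({
          fit <- fit_gibbs(y, kern, mc)
          pred <- predict_missing(fit, cells)
          ability_table(pred, phen, strata_list)
        }, error = function(err) {
          warning("fit failed (replicate ", rep_i, ", grid ", gi, ", ",
                  mod, "): ", conditionMessage(err), call. = FALSE)
          data.frame(stratum = "all", env_id = "mean", r = NA_real_,
                     n_pairs = 0L, undefined = TRUE,
                     stringsAsFactors = FALSE)
        })
        tab$failed <- is.na(tab$r) & tab$n_pairs == 0
        tab <- cbind(replicate = rep_i, n_per_env = grid$n_per_env[gi],
                     n_overlap = grid$n_overlap[gi], model = mod, tab)
        results[[length(results) + 1L]] <- tab
      }
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  list(results = out,
       provenance = list(seed = seed, replicates = replicates,
                         models = models, grid = grid,
                         strata = strata,
                         mcmc = unclass(mcmc),
                         package_version = as.character(packageVersion("sparsegp")),
                         synthetic = is.null(data)))
}

# strata definitions for run_experiment
experiment_strata <- function(pop, strata) {
  out <- list()
  if (strata %in% c("ancestry", "both")) {
    out <- c(out, split(pop$ril_ids, pop$ancestry))
  }
  if (strata %in% c("family", "both")) {
    fams <- split(pop$ril_ids, pop$family_ids)
    names(fams) <- paste0("family:", names(fams))
    out <- c(out, fams)
  }
  if (length(out) == 0) NULL else out
}
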