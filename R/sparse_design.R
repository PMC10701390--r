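#' Base non-overlapping allocation (selection method S1)
#'
#' Randomly partitions the full RIL panel into `n_env` disjoint
#' equal-size training sets, one per environment; each environment's
#' prediction set is the complement of its training set. At the target
#' scale of 1,755 RILs and 9 environments this yields 195 training and
#' 1,560 prediction RILs per environment.
#'
#' The per-environment assignment order is retained: later size
#' reductions and NO-to-O redistributions mask RILs from the *end* of
#' each environment's assignment order, so designs of decreasing size
#' are nested within one another.
#'
#' @param ril_ids character vector of all RIL ids (the candidate pool).
#' @param n_env number of environments (>= 2).
#' @param seed optional RNG seed.
#' @return object of class `allocation`: list with per-environment
#'   `no_rils` (training, observed in that environment only), empty
#'   `o_rils`, frozen `prediction` sets, plus bookkeeping fields.
#' @export
allocate_base <- function(ril_ids, n_env, seed = NULL) {
  n <- length(ril_ids)
  if (n_env < 2) stop("n_env must be >= 2", call. = FALSE)
  if (anyDuplicated(ril_ids)) stop("duplicate ril_ids", call. = FALSE)
  if (n %% n_env != 0) {
    stop(sprintf("pool of %d RILs is not divisible by %d environments (remainder %d)",
                 n, n_env, n %% n_env), call. = FALSE)
  }
  .seed_if(seed)
  perm <- sample(ril_ids)
  base_n <- n %/% n_env
  env_ids <- sprintf("E%d", seq_len(n_env))
  no_rils <- split(perm, rep(seq_len(n_env), each = base_n))
  names(no_rils) <- env_ids
  prediction <- lapply(no_rils, function(s) setdiff(ril_ids, s))
  structure(list(
    env_ids = env_ids,
    no_rils = no_rils,
    o_rils = character(0),
    prediction = prediction,
    all_rils = ril_ids,
    masked = character(0),
    n_env = n_env,
    base_n = base_n,
    spec = NULL,
    seed = seed
  ), class = "allocation")
}

#' Training-set composition specification
#'
#' One cell of the size x composition grid: `n_per_env` RILs observed in
#' each environment, of which `n_overlap` are O-RILs (common to all
#' environments) and the rest NO-RILs (each observed in exactly one
#' environment).
#'
#' @param n_per_env per-environment training-set size.
#' @param n_overlap O-RILs per environment (multiple of `group_size`).
#' @param group_size masking/redistribution step (10 in the reference
#'   grid).
#' @param seed optional RNG seed for the O-RIL draw.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(n_per_env, n_overlap = 0, group_size = 10,
                        seed = NULL) {
  if (n_overlap >= n_per_env && n_overlap > 0) {
    stop("n_overlap must be smaller than n_per_env", call. = FALSE)
  }
  if (n_overlap < 0 || n_per_env < 1) stop("sizes must be positive", call. = FALSE)
  if (group_size >= 1 && n_overlap %% group_size != 0) {
    stop("n_overlap must be a multiple of group_size", call. = FALSE)
  }
  structure(list(n_per_env = as.integer(n_per_env),
                 n_overlap = as.integer(n_overlap),
                 group_size = as.integer(group_size),
                 seed = seed),
            class = "design_spec")
}

#' Derive a reduced / overlapping composition from a base allocation
#'
#' Implements the systematic NO-to-O redistribution: starting from the
#' base allocation reduced to `n_per_env` NO-RILs per environment, each
#' step masks `group_size` further NO-RILs in every environment and
#' promotes `group_size` RILs, drawn at random from the pooled masked
#' RILs, to O-RILs observed in all environments. Prediction sets stay
#' frozen at the base allocation; use [evaluated_prediction()] to drop
#' RILs currently observed in an environment before scoring.
#'
#' @param base an [allocate_base()] allocation.
#' @param spec a [design_spec()].
#' @return a new `allocation` with `n_per_env - n_overlap` NO-RILs per
#'   environment and a common `o_rils` set of size `n_overlap`.
#' @export
derive_composition <- function(base, spec) {
  stopifnot(inherits(base, "allocation"), inherits(spec, "design_spec"))
  if (spec$n_per_env > base$base_n) {
    stop("n_per_env exceeds the base per-environment size", call. = FALSE)
  }
  gs <- spec$group_size
  t_steps <- if (spec$n_overlap == 0) 0L else spec$n_overlap %/% gs
  .seed_if(spec$seed)
  # size reduction: keep the first n_per_env of each environment's order
  no_sets <- lapply(base$no_rils, function(s) s[seq_len(spec$n_per_env)])
  masked <- unlist(lapply(base$no_rils,
                          function(s) s[-seq_len(spec$n_per_env)]),
                   use.names = FALSE)
  o <- character(0)
  for (step in seq_len(t_steps)) {
    for (j in seq_along(no_sets)) {
      s <- no_sets[[j]]
      take <- s[(length(s) - gs + 1):length(s)]
      no_sets[[j]] <- s[seq_len(length(s) - gs)]
      masked <- c(masked, take)
    }
    pool <- setdiff(masked, o)
    if (length(pool) < gs) stop("masked pool too small for requested O-RILs",
                                call. = FALSE)
    o <- c(o, sample(pool, gs))
  }
  out <- base
  out$no_rils <- no_sets
  out$o_rils <- o
  out$masked <- setdiff(masked, o)
  out$spec <- spec
  out
}

#' Training sets of an allocation
#'
#' @param alloc an `allocation`.
#' @return named list, per environment: NO-RILs plus O-RILs.
#' @export
training_sets <- function(alloc) {
  lapply(alloc$no_rils, function(s) c(s, alloc$o_rils))
}

#' Evaluated prediction sets
#'
#' The frozen base prediction set of each environment minus any RIL
#' currently observed there (O-RILs are observed everywhere, so they are
#' removed from every environment's evaluated set).
#'
#' @param alloc an `allocation`.
#' @return named list of RIL id vectors.
#' @export
evaluated_prediction <- function(alloc) {
  lapply(alloc$prediction, function(s) setdiff(s, alloc$o_rils))
}

#' Validate allocation invariants
#'
#' Checks disjointness of NO sets across environments, NO/O
#' disjointness, identical O sets across environments (by construction),
#' and that no environment's training set intersects its frozen
#' prediction set beyond promoted O-RILs.
#'
#' @param alloc an `allocation`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_allocation <- function(alloc) {
  no_all <- unlist(alloc$no_rils, use.names = FALSE)
  if (anyDuplicated(no_all)) stop("NO-RIL sets are not disjoint", call. = FALSE)
  if (length(intersect(no_all, alloc$o_rils)) > 0) {
    stop("a RIL is both NO and O", call. = FALSE)
  }
  tr <- training_sets(alloc)
  ev <- evaluated_prediction(alloc)
  for (j in seq_along(tr)) {
    if (length(intersect(tr[[j]], ev[[j]])) > 0) {
      stop("training and evaluated prediction sets overlap in ",
           alloc$env_ids[j], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' The size-by-composition grid of training designs
#'
#' Enumerates, for each per-environment size `s` in `sizes`, the
#' compositions `s-0`, `(s-step)-step`, ... down to `min_no` NO-RILs.
#' The reference grid (sizes 195 down to 95 by 10, step 10, min 5 NO)
#' has 20 compositions in its largest row, 10 in its smallest, and 165
#' cells in total.
#'
#' @param sizes per-environment training sizes (grid rows).
#' @param overlap_step O-RIL increment between adjacent columns.
#' @param min_no smallest NO-RIL count allowed per environment.
#' @return data.frame with `n_per_env`, `n_overlap`, `label`
#'   ("NO-O" as printed in the reference table).
#' @export
composition_grid <- function(sizes = seq(195, 95, by = -10),
                             overlap_step = 10, min_no = 5) {
  if (length(sizes) == 0) {
    return(data.frame(n_per_env = integer(0), n_overlap = integer(0),
                      label = character(0)))
  }
  rows <- lapply(sizes, function(s) {
    ov <- seq(0, s - min_no, by = overlap_step)
    data.frame(n_per_env = s, n_overlap = ov,
               label = sprintf("%d-%d", s - ov, ov))
  })
  do.call(rbind, rows)
}

#' Design accounting
#'
#' Exact integer bookkeeping of a sparse design: phenotyped plots,
#' distinct RILs observed anywhere, NO-RILs across environments,
#' coverage fraction of the full RIL x environment grid, and missing
#' cells.
#'
#' @param alloc an `allocation`.
#' @param total_rils total RILs in the panel (defaults to the
#'   allocation's pool).
#' @return object of class `design_accounting`.
#' @export
design_accounting <- function(alloc, total_rils = length(alloc$all_rils)) {
  tr <- training_sets(alloc)
  plots <- sum(lengths(tr))
  cells_total <- total_rils * alloc$n_env
  structure(list(
    plots = plots,
    unique_across = length(unique(unlist(tr, use.names = FALSE))),
    no_across = sum(lengths(alloc$no_rils)),
    cells_total = cells_total,
    missing_cells = cells_total - plots,
    coverage_fraction = plots / cells_total,
    n_env = alloc$n_env
  ), class = "design_accounting")
}

#' @export
print.design_accounting <- function(x, ...) {
  cat(sprintf(
    "plots %d | unique RILs %d | NO across %d | cells %d | missing %d | coverage %.1f%%\n",
    x$plots, x$unique_across, x$no_across, x$cells_total, x$missing_cells,
    100 * x$coverage_fraction))
  invisible(x)
}

#' Phenotyping cost of a design
#'
#' Plot-count arithmetic at a fixed cost per yield plot (default $15):
#' the sparse design's total cost, the cost of phenotyping the full
#' RIL x environment grid, and the savings.
#'
#' @param accounting a [design_accounting()] (or any list with `plots`
#'   and `cells_total`).
#' @param cost_per_plot dollars per phenotyped plot (>= 0).
#' @return list with `total_cost`, `full_design_cost`, `savings`.
#' @export
cost_model <- function(accounting, cost_per_plot = 15) {
  if (cost_per_plot < 0) stop("cost_per_plot must be >= 0", call. = FALSE)
  total <- accounting$plots * cost_per_plot
  full <- accounting$cells_total * cost_per_plot
  list(total_cost = total, full_design_cost = full, savings = full - total)
}
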