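#' E(S2) supersaturated-design criterion
#'
#' For a selected genotype submatrix `X0` (rows = selected individuals,
#' columns = markers centered and standardized on the FULL candidate
#' set), the default criterion is `trace((X0'X0)^2)`, computed through
#' the Gram-matrix identity `trace((X'X)^2) = trace((XX')^2)` as the sum
#' of squared entries of the small n x n matrix `X0 X0'`. The
#' `"offdiag"` variant returns the sum of squared off-diagonal entries
#' of `S = X0'X0` (the classical column-orthogonality form); the two
#' differ by the sum of squared diagonal entries of `S`.
#'
#' Lower values correspond to nearer-orthogonal marker columns, i.e.
#' more genetically diverse samples.
#'
#' @param X0 numeric matrix of selected rows (nonempty).
#' @param variant `"trace"` (default) or `"offdiag"`.
#' @return the criterion value (scalar).
#' @export
es2 <- function(X0, variant = c("trace", "offdiag")) {
  variant <- match.arg(variant)
  X0 <- as.matrix(X0)
  if (nrow(X0) == 0) stop("empty selection", call. = FALSE)
  G <- tcrossprod(X0)
  tr <- sum(G * G)
  if (variant == "trace") return(tr)
  d <- colSums(X0^2)            # diag of S = X0'X0
  tr - sum(d^2)
}

# center/standardize columns on the full candidate matrix (divisor n),
# dropping zero-variance columns
ssd_prepare <- function(X) {
  X <- as.matrix(X)
  Xs <- standardize_dosages(X)
  keep <- colSums(Xs != 0) > 0
  Xs[, keep, drop = FALSE]
}

# precomputations shared by all iterations
ssd_precompute <- function(Xs, variant) {
  K <- tcrossprod(Xs)
  pre <- list(K2 = K * K, dK2 = diag(K)^2 * 0)  # placeholder, set below
  pre$dK2 <- diag(pre$K2)
  if (variant == "offdiag") {
    pre$Xsq <- Xs^2
    pre$M2q <- tcrossprod(pre$Xsq)
  }
  pre
}

#' SSD exchange-search state
#'
#' Builds the initial state of the exchange algorithm: a seeded random
#' split of the candidate rows into a selected set `X0` of size
#' `n_sample` and a pool `X1` of the remainder, plus cached
#' cross-product precomputations that make each candidate swap an O(1)
#' criterion update.
#'
#' @param X candidate genotype matrix (rows = individuals). Standardized
#'   internally on the full matrix when `standardize = TRUE`.
#' @param n_sample selected-set size (1..nrow(X)).
#' @param direction `"max_diversity"` (decrease E(S2)) or
#'   `"min_diversity"` (increase it).
#' @param seed optional RNG seed for the initial split.
#' @param variant criterion variant, see [es2()].
#' @param standardize standardize columns on the full candidate set.
#' @return object of class `ssd_state`.
#' @export
ssd_state <- function(X, n_sample,
                      direction = c("max_diversity", "min_diversity"),
                      seed = NULL, variant = c("trace", "offdiag"),
                      standardize = TRUE) {
  direction <- match.arg(direction)
  variant <- match.arg(variant)
  X <- as.matrix(X)
  N <- nrow(X)
  if (n_sample < 1 || n_sample > N) {
    stop("n_sample must lie in 1..nrow(X)", call. = FALSE)
  }
  Xs <- if (standardize) ssd_prepare(X) else X
  .seed_if(seed)
  sel <- sort(sample.int(N, n_sample))
  pool <- setdiff(seq_len(N), sel)
  pre <- ssd_precompute(Xs, variant)
  crit <- es2(Xs[sel, , drop = FALSE], variant)
  structure(list(
    Xs = Xs, ids = rownames(X), selected = sel, pool = pool,
    criterion = crit, direction = direction, variant = variant,
    pre = pre, history = crit
  ), class = "ssd_state")
}

#' Best single exchange between selected set and pool
#'
#' Evaluates the criterion for every (selected, pool) exchange —
#' `|X0| * |X1|` candidate swaps, 304,200 at the reference scale of
#' (195, 1,560) — and returns the single exchange that most improves the
#' criterion in the state's direction. Ties are broken by the lowest
#' (selected-position, pool-position) pair. Returns a no-swap sentinel
#' (`improved = FALSE`) when the pool is empty or no exchange improves.
#'
#' @param state an [ssd_state()].
#' @param tol strict-improvement tolerance guarding termination.
#' @return list with `improved`, `sel_pos`/`pool_pos` (positions within
#'   the current sets), `sel_idx`/`pool_idx` (row indices in `X`),
#'   `new_criterion`, and `n_evaluated` (the swap-evaluation count).
#' @export
best_swap <- function(state, tol = 1e-9) {
  stopifnot(inherits(state, "ssd_state"))
  sel <- state$selected
  pool <- state$pool
  if (length(pool) == 0) {
    return(list(improved = FALSE, sel_pos = NA_integer_,
                pool_pos = NA_integer_, sel_idx = NA_integer_,
                pool_idx = NA_integer_, new_criterion = state$criterion,
                n_evaluated = 0L))
  }
  K2 <- state$pre$K2
  # trace-variant value of the current selection (needed for both variants)
  Ctr <- sum(K2[sel, sel])
  CS <- colSums(K2[sel, , drop = FALSE])
  A <- Ctr - 2 * CS[sel] + state$pre$dK2[sel]          # after removing m
  B <- 2 * CS[pool] + state$pre$dK2[pool]              # adding l
  vals <- outer(A, B, "+") - 2 * K2[sel, pool, drop = FALSE]
  if (state$variant == "offdiag") {
    Xsq <- state$pre$Xsq
    M2q <- state$pre$M2q
    d <- colSums(state$Xs[sel, , drop = FALSE]^2)
    w <- drop(Xsq %*% d)
    Q <- sum(d^2)
    sd2 <- outer(Q - 2 * w[sel] + diag(M2q)[sel],
                 2 * w[pool] + diag(M2q)[pool], "+") -
      2 * M2q[sel, pool, drop = FALSE]
    vals <- vals - sd2
  }
  minimize <- state$direction == "max_diversity"
  opt <- if (minimize) min(vals) else max(vals)
  cand <- which(vals == opt, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  m_pos <- cand[1, 1]; l_pos <- cand[1, 2]
  scale <- 1 + abs(state$criterion)
  improved <- if (minimize) opt < state$criterion - tol * scale
              else opt > state$criterion + tol * scale
  list(improved = improved,
       sel_pos = m_pos, pool_pos = l_pos,
       sel_idx = sel[m_pos], pool_idx = pool[l_pos],
       new_criterion = opt,
       n_evaluated = length(sel) * length(pool))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply an improving swap to the state
apply_swap <- function(state, swap) {
  state$selected[swap$sel_pos] <- swap$pool_idx
  state$pool[swap$pool_pos] <- swap$sel_idx
  state$criterion <- swap$new_criterion
  state$history <- c(state$history, swap$new_criterion)
  state
}

#' Run the E(S2) exchange algorithm
#'
#' Greedy best-swap search: starting from a seeded random split into a
#' selected set of size `n_sample` and a candidate pool, each iteration
#' evaluates every possible single exchange and applies the one that
#' most improves the criterion; the search stops when no exchange
#' improves (or after `max_iter` iterations). `"max_diversity"` drives
#' E(S2) down (toward marker-column orthogonality); `"min_diversity"`
#' drives it up.
#'
#' @inheritParams ssd_state
#' @param max_iter cap on improving iterations (`Inf` = run to
#'   convergence).
#' @param tol strict-improvement tolerance.
#' @return object of class `ssd_result`: list with `selected` (row
#'   indices), `selected_ids` (rownames if present), `criterion`,
#'   `iterations`, `history` (initial value plus one entry per improving
#'   iteration), `evaluations_per_iteration`, `converged`, `direction`,
#'   `variant`.
#' @export
run_exchange <- function(X, n_sample,
                         direction = c("max_diversity", "min_diversity"),
                         seed = NULL, variant = c("trace", "offdiag"),
                         standardize = TRUE, max_iter = Inf, tol = 1e-9) {
  direction <- match.arg(direction)
  variant <- match.arg(variant)
  N <- nrow(as.matrix(X))
  if (n_sample > N) stop("n_sample exceeds the number of candidates",
                         call. = FALSE)
  state <- ssd_state(X, n_sample, direction, seed, variant, standardize)
  evals <- integer(0)
  iter <- 0L
  converged <- TRUE
  while (length(state$pool) > 0) {
    swap <- best_swap(state, tol = tol)
    if (!swap$improved) break
    evals <- c(evals, swap$n_evaluated)
    state <- apply_swap(state, swap)
    iter <- iter + 1L
    if (iter >= max_iter) { converged <- FALSE; break }
  }
  structure(list(
    selected = sort(state$selected),
    selected_ids = if (!is.null(state$ids)) state$ids[sort(state$selected)],
    criterion = state$criterion,
    iterations = iter,
    history = state$history,
    evaluations_per_iteration = evals,
    converged = converged,
    direction = direction,
    variant = variant,
    n_sample = n_sample
  ), class = "ssd_result")
}

#' @export
print.ssd_result <- function(x, ...) {
  cat(sprintf("SSD %s (%s): n=%d, %d iterations, criterion %.4g%s\n",
              x$direction, x$variant, x$n_sample, x$iterations, x$criterion,
              if (x$converged) "" else " (iteration cap hit)"))
  invisible(x)
}
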