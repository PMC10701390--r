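#' Marker quality control and standardization
#'
#' Drops markers with more than `max_missing` missing calls or minor
#' allele frequency below `min_maf` (monomorphic markers have MAF 0 and
#' are always dropped), mean-imputes the remaining missing entries per
#' marker, then centers and standardizes each column (divisor-n
#' variance, so downstream `trace(G) = n`). Columns that end up constant
#' after imputation are dropped as zero-variance.
#'
#' @param raw RIL x marker dosage matrix with entries in \{0, 1, 2\} or
#'   `NA`.
#' @param max_missing maximum missing fraction per marker (default 0.20).
#' @param min_maf minimum minor allele frequency (default 0.03).
#' @return object of class `genotype_qc`: list with `X` (standardized
#'   matrix), `p` (retained marker count), `dropped` (data.frame:
#'   marker, reason), `maf`, `missingness`.
#' @export
qc_filter <- function(raw, max_missing = 0.20, min_maf = 0.03) {
  raw <- as.matrix(raw)
  ok <- raw %in% c(0, 1, 2) | is.na(raw)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  mk <- colnames(raw)
  if (is.null(mk)) mk <- sprintf("M%05d", seq_len(ncol(raw)))
  miss <- colMeans(is.na(raw))
  af <- colMeans(raw, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0  # all-missing column
  reason <- rep(NA_character_, ncol(raw))
  reason[maf < min_maf] <- "maf"
  reason[miss > max_missing] <- "missingness"
  keep <- is.na(reason)
  # impute and check residual variance on the survivors
  Xk <- raw[, keep, drop = FALSE]
  if (ncol(Xk) > 0) {
    cm <- colMeans(Xk, na.rm = TRUE)
    idx <- which(is.na(Xk), arr.ind = TRUE)
    if (nrow(idx) > 0) Xk[idx] <- cm[idx[, 2]]
    v <- colMeans(scale(Xk, center = TRUE, scale = FALSE)^2)
    zv <- v <= 0
    if (any(zv)) {
      reason[which(keep)[zv]] <- "zero_variance"
      keep <- is.na(reason)
      Xk <- Xk[, !zv, drop = FALSE]
    }
  }
  if (ncol(Xk) == 0) stop("no markers survive quality control", call. = FALSE)
  X <- standardize_dosages(Xk)
  colnames(X) <- mk[keep]
  rownames(X) <- rownames(raw)
  structure(list(
    X = X, p = ncol(X),
    dropped = data.frame(marker = mk[!is.na(reason)],
                         reason = reason[!is.na(reason)]),
    maf = setNames(maf, mk), missingness = setNames(miss, mk)
  ), class = "genotype_qc")
}

#' Genomic relationship matrix
#'
#' `G = X X' / p` from the centered, standardized dosage matrix. With
#' divisor-n standardization `trace(G) = n`. Entries describe genomic
#' similarity between pairs of individuals, which is what lets the model
#' borrow information from tested to untested RILs.
#'
#' @param X standardized dosage matrix (e.g. `qc_filter(...)$X`).
#' @param p marker count (defaults to `ncol(X)`).
#' @return symmetric PSD matrix with the rownames of `X`.
#' @export
build_grm <- function(X, p = ncol(X)) {
  if (p == 0) stop("no markers: cannot build G", call. = FALSE)
  tcrossprod(as.matrix(X)) / p
}

#' Record index for all RIL-by-environment cells
#'
#' Builds the environment-major complete grid of records (every RIL in
#' every environment) used as the model frame: missing phenotype cells
#' are part of the index and receive predictions.
#'
#' @param ril_ids RIL identifiers.
#' @param env_ids environment identifiers.
#' @param family_ids family label per RIL (same length/order as
#'   `ril_ids`); optional unless an F/FE model is fitted.
#' @return data.frame with columns `ril_id`, `env_id`, `family_id`.
#' @export
grid_records <- function(ril_ids, env_ids, family_ids = NULL) {
  n <- length(ril_ids)
  if (is.null(family_ids)) family_ids <- rep(NA_character_, n)
  data.frame(
    ril_id = rep(ril_ids, times = length(env_ids)),
    env_id = rep(env_ids, each = n),
    family_id = rep(as.character(family_ids), times = length(env_ids)),
    stringsAsFactors = FALSE
  )
}

# is `records` exactly the env-major complete grid over its levels?
is_complete_grid <- function(records) {
  rils <- unique(records$ril_id)
  envs <- unique(records$env_id)
  n <- length(rils); J <- length(envs)
  if (nrow(records) != n * J) return(FALSE)
  identical(records$ril_id, rep(rils, times = J)) &&
    identical(records$env_id, rep(envs, each = n))
}

# eigenstructure of the block-ones matrix Z Z' over a grouping factor,
# returned as (vectors U, values): one eigenvector per level
ones_block_eigen <- function(f) {
  f <- factor(f)
  n <- length(f)
  U <- matrix(0, n, nlevels(f))
  sizes <- tabulate(f)
  for (k in seq_len(nlevels(f))) U[f == levels(f)[k], k] <- 1 / sqrt(sizes[k])
  list(vectors = U, values = sizes)
}

#' Covariance structures for a model specification
#'
#' Assembles the ordered kernel list of the reaction-norm model family
#' over a record index covering observed and to-predict cells:
#'
#' * `E` — environment grouping `Z_E Z_E'`,
#' * `L` — RIL identity `Z_g Z_g'`,
#' * `G` — genomic main effect `Z_g G Z_g'`,
#' * `GE` — `Z_g G Z_g' \circ Z_E Z_E'` (Hadamard),
#' * `F` — family grouping `Z_F Z_F'`,
#' * `FE` — `Z_F Z_F' \circ Z_E Z_E'`.
#'
#' M1 = \{E, L, G\}; M2 = M1 + GE; M3 = M2 + \{F, FE\}. When the record
#' index is the environment-major complete grid, eigendecompositions are
#' attached analytically via Kronecker identities (only `eigen(G)` is
#' computed numerically), which is what makes repeated Gibbs fits cheap.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param records record index from [grid_records()] (or any data.frame
#'   with `ril_id`, `env_id`, `family_id`).
#' @param G genomic relationship matrix with RIL ids as rownames,
#'   covering every RIL in `records`.
#' @return object of class `kernel_set`: list of terms, each with
#'   `label`, `K` (explicit matrix) and `eig` (list(values, vectors) or
#'   NULL), plus the records and model label.
#' @export
build_kernels <- function(model = c("M1", "M2", "M3"), records, G) {
  model <- match.arg(model)
  stopifnot(all(c("ril_id", "env_id") %in% names(records)))
  if (is.null(rownames(G))) stop("G must carry RIL ids as rownames",
                                 call. = FALSE)
  missing_rils <- setdiff(unique(records$ril_id), rownames(G))
  if (length(missing_rils) > 0) {
    stop("RILs absent from G: ", paste(utils::head(missing_rils, 3),
                                       collapse = ", "), call. = FALSE)
  }
  labels <- switch(model,
                   M1 = c("E", "L", "G"),
                   M2 = c("E", "L", "G", "GE"),
                   M3 = c("E", "L", "G", "GE", "F", "FE"))
  if (any(c("F", "FE") %in% labels) && anyNA(records$family_id)) {
    stop("family_id required for model ", model, call. = FALSE)
  }
  N <- nrow(records)
  ril_i <- match(records$ril_id, rownames(G))
  KG <- G[ril_i, ril_i, drop = FALSE]
  same_env <- outer(records$env_id, records$env_id, "==") * 1
  same_ril <- outer(records$ril_id, records$ril_id, "==") * 1
  same_fam <- if (!anyNA(records$family_id)) {
    outer(records$family_id, records$family_id, "==") * 1
  } else NULL

  grid <- is_complete_grid(records)
  eigs <- vector("list", length(labels))
  names(eigs) <- labels
  if (grid) {
    rils <- unique(records$ril_id)
    envs <- unique(records$env_id)
    n <- length(rils); J <- length(envs)
    onesJ <- matrix(1 / sqrt(J), J, 1)
    eG <- eigen(G[rils, rils, drop = FALSE], symmetric = TRUE)
    keep <- eG$values > max(eG$values) * 1e-10
    UG <- eG$vectors[, keep, drop = FALSE]
    lG <- eG$values[keep]
    if ("E" %in% labels) {
      eigs$E <- list(vectors = kronecker(diag(J), matrix(1 / sqrt(n), n, 1)),
                     values = rep(n, J))
    }
    if ("L" %in% labels) {
      eigs$L <- list(vectors = kronecker(onesJ, diag(n)), values = rep(J, n))
    }
    if ("G" %in% labels) {
      eigs$G <- list(vectors = kronecker(onesJ, UG), values = J * lG)
    }
    if ("GE" %in% labels) {
      eigs$GE <- list(vectors = kronecker(diag(J), UG),
                      values = rep(lG, times = J))
    }
    if ("F" %in% labels || "FE" %in% labels) {
      fam_of_ril <- records$family_id[match(rils, records$ril_id)]
      eF <- ones_block_eigen(fam_of_ril)
      if ("F" %in% labels) {
        eigs$F <- list(vectors = kronecker(onesJ, eF$vectors),
                       values = J * eF$values)
      }
      if ("FE" %in% labels) {
        eigs$FE <- list(vectors = kronecker(diag(J), eF$vectors),
                        values = rep(eF$values, times = J))
      }
    }
  }

  terms <- lapply(labels, function(lab) {
    K <- switch(lab,
                E = same_env,
                L = same_ril,
                G = KG,
                GE = KG * same_env,
                F = same_fam,
                FE = same_fam * same_env)
    list(label = lab, K = K, eig = eigs[[lab]])
  })
  names(terms) <- labels
  structure(list(terms = terms, records = records, model = model),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf("kernel_set %s: %d records, terms %s\n", x$model,
              nrow(x$records), paste(names(x$terms), collapse = " + ")))
  invisible(x)
}
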