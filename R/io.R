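#' Write a simulated population to plain-text files
#'
#' Genotypes as TSV (first column `ril_id`, then one column per marker),
#' with companion marker-map TSV (`marker`, `chromosome`, `order`) and
#' family-table TSV (`ril_id`, `family_id`, `ancestry_group`).
#'
#' @param pop a `nam_population`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_genotypes <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genotypes.tsv")
  geno <- data.table::as.data.table(pop$genotypes)
  geno <- cbind(data.table::data.table(ril_id = pop$ril_ids), geno)
  data.table::fwrite(geno, gpath, sep = "\t")
  mpath <- file.path(dir, "marker_map.tsv")
  data.table::fwrite(pop$marker_map, mpath, sep = "\t")
  fpath <- file.path(dir, "families.tsv")
  data.table::fwrite(data.frame(ril_id = pop$ril_ids,
                                family_id = as.character(pop$family_ids),
                                ancestry_group = as.character(pop$ancestry)),
                     fpath, sep = "\t")
  invisible(c(genotypes = gpath, marker_map = mpath, families = fpath))
}

#' Read genotypes (and companions) from plain-text files
#'
#' Validates the documented schema: unique `ril_id`, dosage entries in
#' \{0, 1, 2\} or missing; violations raise errors naming the offending
#' cell.
#'
#' @param geno_path genotype TSV/CSV (first column `ril_id`).
#' @param map_path,fam_path optional marker map / family table paths.
#' @return list with `genotypes` (matrix, RIL ids as rownames),
#'   `marker_map` (or NULL), `families` (or NULL).
#' @export
read_genotypes <- function(geno_path, map_path = NULL, fam_path = NULL) {
  dt <- data.table::fread(geno_path)
  if (names(dt)[1] != "ril_id") stop("first column must be ril_id",
                                     call. = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate ril_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  geno <- as.matrix(dt[, -1])
  bad <- which(!(geno %in% c(0, 1, 2) | is.na(geno)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(geno))
    stop(sprintf("invalid dosage %s at ril '%s', marker '%s'",
                 geno[bad[1]], ids[rc[1]], colnames(geno)[rc[2]]),
         call. = FALSE)
  }
  storage.mode(geno) <- "numeric"
  rownames(geno) <- ids
  list(
    genotypes = geno,
    marker_map = if (!is.null(map_path)) as.data.frame(data.table::fread(map_path)),
    families = if (!is.null(fam_path)) as.data.frame(data.table::fread(fam_path))
  )
}

#' Write / read a long-format phenotype table
#'
#' CSV with header `ril_id,family_id,ancestry_group,env_id,value,observed`.
#'
#' @param phenotypes long data.frame in the documented schema.
#' @param path CSV path.
#' @return `write_phenotypes`: invisibly the path;
#'   `read_phenotypes`: the data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  data.table::fwrite(phenotypes, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- as.data.frame(data.table::fread(path))
  need <- c("ril_id", "family_id", "ancestry_group", "env_id", "value",
            "observed")
  if (!all(need %in% names(ph))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(ph$observed & !is.finite(ph$value))) {
    stop("observed phenotypes must be finite", call. = FALSE)
  }
  ph
}

#' Serialize / load an allocation as JSON
#'
#' Schema: `{envs: {E1: {no_rils, o_rils, prediction}, ...}, meta: {...}}`.
#'
#' @param alloc an `allocation`.
#' @param path JSON path.
#' @return `write_allocation`: invisibly the path; `read_allocation`:
#'   the `allocation`.
#' @export
write_allocation <- function(alloc, path) {
  obj <- list(
    envs = setNames(lapply(seq_along(alloc$env_ids), function(j) {
      list(no_rils = alloc$no_rils[[j]], o_rils = alloc$o_rils,
           prediction = alloc$prediction[[j]])
    }), alloc$env_ids),
    meta = list(all_rils = alloc$all_rils, n_env = alloc$n_env,
                base_n = alloc$base_n, masked = alloc$masked,
                seed = alloc$seed,
                spec = if (!is.null(alloc$spec)) unclass(alloc$spec))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_allocation
#' @export
read_allocation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  env_ids <- names(obj$envs)
  chr <- function(x) if (length(x) == 0) character(0) else as.character(x)
  spec <- obj$meta$spec
  structure(list(
    env_ids = env_ids,
    no_rils = lapply(obj$envs, function(e) chr(e$no_rils)),
    o_rils = chr(obj$envs[[1]]$o_rils),
    prediction = lapply(obj$envs, function(e) chr(e$prediction)),
    all_rils = chr(obj$meta$all_rils),
    masked = chr(obj$meta$masked),
    n_env = obj$meta$n_env,
    base_n = obj$meta$base_n,
    spec = if (!is.null(spec)) {
      design_spec(spec$n_per_env, spec$n_overlap, spec$group_size)
    },
    seed = obj$meta$seed
  ), class = "allocation")
}

#' Load a run configuration file
#'
#' JSON is always supported; YAML (`.yaml`/`.yml`) requires the
#' suggested `yaml` package.
#'
#' @param path config path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# provenance JSON written next to every CLI output
write_provenance <- function(dir, stage, args, seed = NULL) {
  obj <- list(stage = stage, args = args, seed = seed,
              package_version = as.character(packageVersion("sparsegp")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}
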