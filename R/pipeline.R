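# ---- configuration ---------------------------------------------------

#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. One global seed
#' deterministically derives the per-stage seeds, so a rerun with the
#' same configuration is bit-identical.
#'
#' @param out_dir output directory for tables and the persisted config.
#' @param design a [simulation_design()] (used when no input paths are
#'   given).
#' @param gm_dir,atlas optional paths to per-subject NIfTI value maps
#'   and an atlas volume; when set, networks are built from files
#'   instead of simulation.
#' @param metadata optional path to a subject-metadata TSV.
#' @param sparsities sparsity window (default 0.10-0.34 step 0.01).
#' @param n_nulls random references per thresholded network (default
#'   100).
#' @param n_perm permutations for group tests and NBS (default 5000).
#' @param svm_n_perm label permutations for classifier significance
#'   (default 1000).
#' @param svm_features `"metrics"`, `"matrix"` or both.
#' @param mode metric mode, `"weighted"` (default) or `"binary"`.
#' @param stages character vector of stages to run.
#' @param seed global seed.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("morphkls_run_"),
                       design = simulation_design(),
                       gm_dir = NULL, atlas = NULL, metadata = NULL,
                       sparsities = seq(0.10, 0.34, by = 0.01),
                       n_nulls = 100L, n_perm = 5000L,
                       svm_n_perm = 1000L,
                       svm_features = c("metrics", "matrix"),
                       mode = "weighted",
                       stages = c("simulate", "construct", "metrics",
                                  "compare", "nbs", "correlate",
                                  "classify"),
                       seed = 1L) {
  structure(list(out_dir = out_dir, design = design, gm_dir = gm_dir,
                 atlas = atlas, metadata = metadata,
                 sparsities = sparsities, n_nulls = as.integer(n_nulls),
                 n_perm = as.integer(n_perm),
                 svm_n_perm = as.integer(svm_n_perm),
                 svm_features = svm_features, mode = mode,
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

# one global seed -> reproducible per-stage seeds (kept below 2^31)
stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  names(s) <- c("simulate", "construct", "metrics", "compare", "nbs",
                "correlate", "classify", "extra")
  s
}

# ---- metadata I/O ----------------------------------------------------

meta_schema <- c(subject_id = "character", group = "character",
                 subtype = "character", age = "numeric",
                 gender = "numeric", education = "numeric",
                 updrs3 = "numeric", hoehn_yahr = "numeric",
                 mmse = "numeric")

#' Read / write the subject-metadata table
#'
#' Tab-separated, one row per subject, with the columns subject_id,
#' group (control/patient), subtype (tremor/akinetic_rigid/mixed/none),
#' age, gender (0/1), education, updrs3, hoehn_yahr, mmse. Validation
#' errors name the offending column or row.
#'
#' @param path TSV file path.
#' @return `read_metadata` returns a validated data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("metadata file is empty: ", path)
  miss <- setdiff(names(meta_schema), names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  for (col in names(meta_schema)) {
    if (meta_schema[col] == "numeric" && !is.numeric(df[[col]]))
      stop("metadata column '", col, "' must be numeric")
  }
  bad <- which(!df$group %in% c("control", "patient"))
  if (length(bad))
    stop("malformed group label in metadata row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(!df$subtype %in% c("tremor", "akinetic_rigid", "mixed",
                                  "none"))
  if (length(bad))
    stop("malformed subtype label in metadata row(s): ",
         paste(bad, collapse = ", "))
  bad <- which((df$group == "control") != (df$subtype == "none"))
  if (length(bad))
    stop("subtype must be 'none' exactly for controls; row(s): ",
         paste(bad, collapse = ", "))
  df
}

#' @rdname read_metadata
#' @param meta a metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta[, names(meta_schema)], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#' @param results a data.frame.
#' @param path file path.
#' @export
write_report <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- cohort-level helpers -------------------------------------------

#' Build networks for every subject of a cohort
#' @param cohort a `morph_cohort` (or list of subject lists).
#' @return list of `morph_network`s, named by subject id.
#' @export
cohort_networks <- function(cohort) {
  subjects <- if (inherits(cohort, "morph_cohort")) cohort$subjects else cohort
  nets <- lapply(subjects, build_network)
  names(nets) <- vapply(nets, `[[`, "", "subject_id")
  nets
}

#' Metric curves and AUC summaries for a list of networks
#'
#' @param networks list of `morph_network`s.
#' @param sparsities sparsity grid.
#' @param mode metric mode.
#' @param n_null random references per sparsity (0 skips
#'   gamma/lambda/sigma).
#' @param seed optional seed.
#' @return list with `curves` (per subject) and the stacked AUC arrays:
#'   `global` (subjects x 7) and `nodal` (subjects x n_node x 3).
#' @export
cohort_aucs <- function(networks, sparsities = seq(0.10, 0.34, 0.01),
                        mode = "weighted", n_null = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  curves <- lapply(networks, network_metrics, sparsities = sparsities,
                   mode = mode, n_null = n_null)
  aucs <- lapply(curves, curves_auc)
  gl <- t(vapply(aucs, `[[`, aucs[[1]]$global, "global"))
  keep <- colnames(gl)[colSums(is.na(gl)) == 0]
  nd <- array(NA_real_,
              dim = c(length(aucs), nrow(aucs[[1]]$nodal), 3),
              dimnames = list(names(networks),
                              rownames(aucs[[1]]$nodal),
                              colnames(aucs[[1]]$nodal)))
  for (i in seq_along(aucs)) nd[i, , ] <- aucs[[i]]$nodal
  list(curves = curves, global = gl[, keep, drop = FALSE], nodal = nd)
}

# subset a cohort_aucs result by subject index
subset_aucs <- function(aucs, idx) {
  list(global = aucs$global[idx, , drop = FALSE],
       nodal = aucs$nodal[idx, , , drop = FALSE])
}

#' Partial correlations between nodal AUC metrics and clinical scores
#'
#' Within the patient group, correlates each requested nodal AUC with
#' each clinical variable, adjusting for age, gender and education.
#'
#' @param aucs a [cohort_aucs()] result (patients only).
#' @param meta matching metadata rows.
#' @param regions region indices to test.
#' @param metrics nodal metric names.
#' @param clinical clinical variable names.
#' @return data.frame with region, metric, clinical variable, r, p, n.
#' @export
clinical_correlations <- function(aucs, meta,
                                  regions = seq_len(dim(aucs$nodal)[2]),
                                  metrics = dimnames(aucs$nodal)[[3]],
                                  clinical = c("updrs3", "hoehn_yahr",
                                               "mmse")) {
  cov <- meta[, c("age", "gender", "education")]
  out <- list()
  for (m in metrics) for (r in regions) for (cl in clinical) {
    pc <- tryCatch(partial_correlation(aucs$nodal[, r, m], meta[[cl]], cov),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    out[[length(out) + 1L]] <-
      data.frame(region = dimnames(aucs$nodal)[[2]][r], metric = m,
                 clinical = cl, r = pc$r, p = pc$p, n = nrow(meta),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- orchestrator ----------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) → construct → metrics → compare / NBS /
#' correlate → classify, writing plain TSV/JSON artifacts into the
#' configured output directory. Rerunning with the same configuration
#' reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of each stage
#'   and `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  seeds <- stage_seeds(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  cfg$design <- unclass(cfg$design)
  jsonlite::write_json(unclass(cfg), file.path(config$out_dir,
                                               "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_stage <- function(name, t) {
    message(sprintf("[morphkls] %-10s %6.1fs", name,
                    as.numeric(difftime(Sys.time(), t, units = "secs"))))
  }
  run <- function(s) s %in% config$stages
  res <- list(out_dir = config$out_dir)

  # -- inputs: simulate or load ---------------------------------------
  ts <- Sys.time()
  if (!is.null(config$gm_dir)) {
    if (is.null(config$atlas) || !file.exists(config$atlas))
      stop("stage construct: atlas file not found: ",
           config$atlas %||% "<missing>")
    maps <- sort(list.files(config$gm_dir, pattern = "\\.nii(\\.gz)?$",
                            full.names = TRUE))
    if (!length(maps)) stop("stage construct: no NIfTI maps in ",
                            config$gm_dir)
    subjects <- lapply(maps, function(f) {
      s <- extract_regional_values(f, config$atlas)
      s$subject_id <- sub("(_gm)?\\.nii(\\.gz)?$", "", basename(f))
      s
    })
    meta <- read_metadata(config$metadata)
    cohort <- structure(list(subjects = subjects, meta = meta,
                             design = config$design),
                        class = "morph_cohort")
  } else {
    design <- config$design
    design$seed <- as.integer(seeds["simulate"] %% .Machine$integer.max)
    cohort <- simulate_cohort(design)
  }
  res$cohort <- cohort
  write_metadata(cohort$meta, file.path(config$out_dir, "metadata.tsv"))
  log_stage("inputs", ts)

  grp <- cohort$meta$group
  idx_con <- which(grp == "control")
  idx_pat <- which(grp == "patient")

  # -- construct ------------------------------------------------------
  ts <- Sys.time()
  nets <- cohort_networks(cohort)
  res$networks <- nets
  write_network_tsv(nets[[1]],
                    file.path(config$out_dir,
                              paste0(nets[[1]]$subject_id, "_network.tsv")))
  log_stage("construct", ts)

  # -- metrics --------------------------------------------------------
  if (run("metrics")) {
    ts <- Sys.time()
    aucs <- cohort_aucs(nets, sparsities = config$sparsities,
                        mode = config$mode, n_null = config$n_nulls,
                        seed = seeds["metrics"])
    res$aucs <- aucs
    write_report(data.frame(subject_id = rownames(aucs$global),
                            group = grp, aucs$global,
                            check.names = FALSE),
                 file.path(config$out_dir, "global_auc.tsv"))
    hub_con <- hub_scores(apply(aucs$nodal[idx_con, , , drop = FALSE],
                                c(2, 3), mean))
    hub_pat <- hub_scores(apply(aucs$nodal[idx_pat, , , drop = FALSE],
                                c(2, 3), mean))
    write_report(hub_con, file.path(config$out_dir, "hubs_control.tsv"))
    write_report(hub_pat, file.path(config$out_dir, "hubs_patient.tsv"))
    res$hubs <- list(control = hub_con, patient = hub_pat)
    log_stage("metrics", ts)
  }

  # -- compare --------------------------------------------------------
  if (run("compare") && run("metrics")) {
    ts <- Sys.time()
    set.seed(seeds["compare"])
    cmp <- compare_groups(subset_aucs(res$aucs, idx_pat),
                          subset_aucs(res$aucs, idx_con),
                          n_perm = config$n_perm)
    res$comparison <- cmp
    write_report(cmp$global, file.path(config$out_dir,
                                       "global_comparison.tsv"))
    write_report(cmp$nodal, file.path(config$out_dir,
                                      "nodal_comparison.tsv"))
    log_stage("compare", ts)
  }

  # -- NBS ------------------------------------------------------------
  if (run("nbs")) {
    ts <- Sys.time()
    wa <- lapply(nets[idx_con], `[[`, "weights")
    wb <- lapply(nets[idx_pat], `[[`, "weights")
    res$nbs <- list(
      decreased = nbs(wa, wb, n_perm = config$n_perm,
                      direction = "decreased",
                      seed = seeds["nbs"]),
      increased = nbs(wa, wb, n_perm = config$n_perm,
                      direction = "increased",
                      seed = seeds["nbs"] + 1L))
    for (d in names(res$nbs)) {
      r <- res$nbs[[d]]
      sig <- which(r$p_values < 0.05)
      if (length(sig)) {
        tab <- do.call(rbind, r$components[sig])
        write_report(tab, file.path(config$out_dir,
                                    paste0("nbs_", d, ".tsv")))
      }
    }
    log_stage("nbs", ts)
  }

  # -- correlate ------------------------------------------------------
  if (run("correlate") && run("metrics")) {
    ts <- Sys.time()
    cors <- clinical_correlations(subset_aucs(res$aucs, idx_pat),
                                  cohort$meta[idx_pat, ])
    res$correlations <- cors
    write_report(cors, file.path(config$out_dir,
                                 "clinical_correlations.tsv"))
    log_stage("correlate", ts)
  }

  # -- classify -------------------------------------------------------
  if (run("classify")) {
    ts <- Sys.time()
    res$svm <- list()
    for (kind in config$svm_features) {
      fs <- if (kind == "matrix") {
        feature_set(grp, networks = nets, kind = "matrix")
      } else {
        feature_set(grp, aucs = list(global = res$aucs$global,
                                     nodal = res$aucs$nodal),
                    kind = "metrics")
      }
      sv <- permutation_significance(fs, n_perm = config$svm_n_perm,
                                     seed = seeds["classify"])
      res$svm[[kind]] <- sv
      rc <- region_contributions(sv)
      write_report(rc, file.path(config$out_dir,
                                 paste0("svm_regions_", kind, ".tsv")))
      write_report(sv$folds, file.path(config$out_dir,
                                       paste0("svm_folds_", kind, ".tsv")))
    }
    log_stage("classify", ts)
  }

  message(sprintf("[morphkls] total      %6.1fs -> %s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config$out_dir))
  invisible(res)
}
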