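# File formats (TSV matrices, CSV tables, BrainNet exports, JSON manifests)
# and the end-to-end pipeline runner.

#' Read a connectivity matrix from TSV
#'
#' Expects a header row and first column of region labels and a square
#' numeric body. Asymmetric input is symmetrized by averaging with a
#' warning; negative or missing entries and non-square bodies are errors.
#'
#' @param path Path to a TSV file written by [write_matrix_tsv()].
#' @return A validated connectivity matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  w <- as.matrix(df)
  if (nrow(w) != ncol(w)) stop("non-square matrix", call. = FALSE)
  if (!is.numeric(w) || anyNA(w)) {
    stop("matrix contains non-numeric or missing values", call. = FALSE)
  }
  if (any(w < 0)) stop("negative edge weights are not allowed", call. = FALSE)
  asym <- max(abs(w - t(w)))
  if (asym > 0) {
    warning(sprintf("asymmetric input (max |w_ij - w_ji| = %.3g); symmetrized",
                    asym), call. = FALSE)
    w <- (w + t(w)) / 2
  }
  as_connectivity_matrix(w)
}

#' Write a connectivity matrix as TSV
#'
#' @param w Connectivity matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(w, path) {
  w <- as_connectivity_matrix(w)
  utils::write.table(w, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Read all subject matrices from a directory
#'
#' @param dir Directory of `*.tsv` matrices; subject ids are file names
#'   without extension, sorted.
#' @return Named list of connectivity matrices.
#' @export
read_matrix_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stop("no .tsv matrices in ", dir, call. = FALSE)
  out <- lapply(files, read_matrix_tsv)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Export a network for BrainNet Viewer
#'
#' Writes the standard `.node` file (x, y, z, color, size, label per row)
#' and `.edge` file (N x N whitespace-separated matrix) used for rendering
#' hand-off.
#'
#' @param coords N x 3 matrix of node coordinates.
#' @param w N x N edge matrix.
#' @param path_prefix Output path without extension.
#' @param color,size Numeric per-node columns (default 1).
#' @param labels Node labels (default from `w`).
#' @return `path_prefix`, invisibly.
#' @export
write_brainnet <- function(coords, w, path_prefix, color = 1, size = 1,
                           labels = NULL) {
  n <- nrow(w)
  stopifnot(nrow(coords) == n)
  labels <- labels %||% rownames(w) %||% region_labels(n)
  node <- data.frame(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    color = rep_len(color, n), size = rep_len(size, n), label = labels
  )
  utils::write.table(node, paste0(path_prefix, ".node"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(unname(as.matrix(w)), paste0(path_prefix, ".edge"),
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path_prefix)
}

#' Pipeline run configuration
#'
#' Collects the paths and stage parameters of an end-to-end run. Flags of
#' the command-line interface mirror these fields.
#'
#' @param input_dir Directory of per-subject matrix TSVs.
#' @param phenotypes_csv Path to the phenotype CSV (subject_id, group, age,
#'   sex, education, cognitive scores).
#' @param output_dir Output directory.
#' @param s_min,s_max,s_step Sparsity grid.
#' @param n_random Random networks per sparsity point for small-world
#'   normalization (1000 for reference-quality runs; 100 for screening).
#' @param swaps_per_edge Rewiring intensity.
#' @param n_perm,primary_p,alpha NBS parameters.
#' @param posthoc_correction Correction for post-hoc contrasts.
#' @param gatekeep Gate post-hoc tests on the omnibus p.
#' @param mci_group,hc_group Labels of the patient group used for
#'   brain-behaviour correlations and the reference group.
#' @param seed Master seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, phenotypes_csv, output_dir,
                       s_min = 0.10, s_max = 0.15, s_step = 0.01,
                       n_random = 100, swaps_per_edge = 10,
                       n_perm = 5000, primary_p = 0.01, alpha = 0.05,
                       posthoc_correction = "fdr", gatekeep = TRUE,
                       mci_group = "MCI", hc_group = "HC", seed = 1) {
  cfg <- list(
    input_dir = input_dir, phenotypes_csv = phenotypes_csv,
    output_dir = output_dir, s_min = s_min, s_max = s_max, s_step = s_step,
    n_random = n_random, swaps_per_edge = swaps_per_edge, n_perm = n_perm,
    primary_p = primary_p, alpha = alpha,
    posthoc_correction = posthoc_correction, gatekeep = gatekeep,
    mci_group = mci_group, hc_group = hc_group, seed = seed
  )
  class(cfg) <- "run_config"
  cfg
}

# Hash of the analysis parameters (paths excluded, so runs of the same
# analysis on the same inputs are recognizably identical wherever they live).
config_hash <- function(cfg) {
  core <- unclass(cfg)
  core$input_dir <- core$phenotypes_csv <- core$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_table_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full connectome analysis pipeline
#'
#' Reads per-subject FA-weighted matrices and phenotypes, computes metric
#' curves and AUC summaries per subject, covariate-adjusted group statistics
#' for global and nodal metrics, hub sets per group with a cross-group
#' comparison, NBS contrasts (omnibus plus all pairwise), and Spearman
#' correlations between global AUC metrics and cognitive scores in the
#' patient group. All tables are written to `output_dir` (CSV/JSON, each
#' carrying the configuration hash) together with a manifest; rerunning with
#' the same configuration and inputs reproduces every output byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`auc`, `global_stats`,
#'   `nodal_stats`, `hubs`, `nbs`, `spearman`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  matrices <- read_matrix_dir(config$input_dir)
  pheno <- utils::read.csv(config$phenotypes_csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(pheno))) {
    stop("phenotypes must contain subject_id and group columns", call. = FALSE)
  }
  missing_m <- setdiff(pheno$subject_id, names(matrices))
  missing_p <- setdiff(names(matrices), pheno$subject_id)
  if (length(missing_m) || length(missing_p)) {
    stop("subject mismatch between matrices and phenotypes: ",
         paste(c(missing_m, missing_p), collapse = ", "), call. = FALSE)
  }
  matrices <- matrices[pheno$subject_id]
  groups <- droplevels(factor(pheno$group,
                              levels = unique(c(config$hc_group,
                                                setdiff(unique(pheno$group),
                                                        config$hc_group)))))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  grid <- sparsity_grid(config$s_min, config$s_max, config$s_step)
  ns <- length(matrices)

  # per-subject metric curves and AUCs
  curve_rows <- list()
  auc_glob <- NULL
  auc_ne <- NULL
  auc_bc <- NULL
  for (k in seq_len(ns)) {
    cur <- metric_curves(
      matrices[[k]], grid = grid, n_random = config$n_random,
      swaps_per_edge = config$swaps_per_edge,
      seed = substream_seed(config$seed, k)
    )
    a <- auc_summary(cur)
    curve_rows[[k]] <- cbind(subject_id = pheno$subject_id[k], cur$global)
    auc_glob <- rbind(auc_glob, a$global)
    auc_ne <- cbind(auc_ne, a$nodal_efficiency)
    auc_bc <- cbind(auc_bc, a$betweenness)
  }
  auc_glob <- as.data.frame(auc_glob)
  auc_glob <- cbind(subject_id = pheno$subject_id, auc_glob)
  colnames(auc_ne) <- pheno$subject_id
  colnames(auc_bc) <- pheno$subject_id
  write_table_with_hash(do.call(rbind, curve_rows),
                        file.path(config$output_dir, "metric_curves.csv"),
                        hash)
  write_table_with_hash(auc_glob,
                        file.path(config$output_dir, "global_auc.csv"), hash)
  write_table_with_hash(
    cbind(region = rownames(auc_ne), as.data.frame(auc_ne)),
    file.path(config$output_dir, "nodal_efficiency_auc.csv"), hash
  )
  write_table_with_hash(
    cbind(region = rownames(auc_bc), as.data.frame(auc_bc)),
    file.path(config$output_dir, "betweenness_auc.csv"), hash
  )

  # group statistics
  glob_stats <- group_global_table(
    auc_glob, pheno, metrics = c("Cp", "Lp", "Eglob", "Eloc"),
    correction = config$posthoc_correction, gatekeep = config$gatekeep
  )
  write_table_with_hash(glob_stats,
                        file.path(config$output_dir, "global_stats.csv"),
                        hash)
  nodal_stats <- list(
    efficiency = nodal_group_table(auc_ne, pheno, gatekeep = config$gatekeep),
    betweenness = nodal_group_table(auc_bc, pheno, gatekeep = config$gatekeep)
  )
  write_table_with_hash(
    nodal_stats$efficiency,
    file.path(config$output_dir, "nodal_stats_efficiency.csv"), hash
  )
  write_table_with_hash(
    nodal_stats$betweenness,
    file.path(config$output_dir, "nodal_stats_betweenness.csv"), hash
  )

  # hubs on group-mean matrices
  hub_sets <- lapply(split(seq_len(ns), groups), function(idx) {
    gm <- group_mean_matrix(matrices[idx])
    bc <- nodal_metrics(threshold_by_sparsity(gm, config$s_max))$betweenness
    identify_hubs(stats::setNames(bc, rownames(gm)))$hubs
  })
  hub_cmp <- compare_hubs(hub_sets)
  jsonlite::write_json(
    list(config_hash = hash, hubs = hub_sets, comparison = hub_cmp),
    file.path(config$output_dir, "hubs.json"), auto_unbox = TRUE, digits = NA
  )

  # NBS: omnibus plus all pairwise contrasts
  lev <- levels(groups)
  contrasts <- c(
    if (length(lev) > 2) list("omnibus"),
    utils::combn(lev, 2, simplify = FALSE)
  )
  nbs_out <- list()
  for (ct in contrasts) {
    tag <- if (identical(ct, "omnibus")) "omnibus" else paste(ct, collapse = "_vs_")
    res <- nbs_test(
      matrices, groups,
      params = nbs_params(primary_p = config$primary_p,
                          n_perm = config$n_perm, alpha = config$alpha,
                          seed = substream_seed(config$seed, 7000 + length(nbs_out))),
      contrast = ct
    )
    nbs_out[[tag]] <- res
    comp_df <- if (length(res$components)) {
      do.call(rbind, lapply(seq_along(res$components), function(k) {
        cc <- res$components[[k]]
        data.frame(
          component = k, region_i = cc$labels[, 1], region_j = cc$labels[, 2],
          size = cc$size, p_corrected = cc$p_corrected,
          significant = cc$significant, stringsAsFactors = FALSE
        )
      }))
    } else {
      data.frame(component = integer(0), region_i = character(0),
                 region_j = character(0), size = integer(0),
                 p_corrected = numeric(0), significant = logical(0))
    }
    write_table_with_hash(
      comp_df, file.path(config$output_dir, paste0("nbs_", tag, ".csv")), hash
    )
    write_table_with_hash(
      data.frame(perm = seq_along(res$null_max), max_component = res$null_max),
      file.path(config$output_dir, paste0("nbs_null_", tag, ".csv")), hash
    )
  }

  # Spearman brain-behaviour correlations in the patient group
  spearman <- NULL
  cog_cols <- setdiff(
    names(pheno)[vapply(pheno, is.numeric, logical(1))],
    c("age", "education")
  )
  mci_idx <- which(as.character(groups) == config$mci_group)
  if (length(mci_idx) >= 5 && length(cog_cols)) {
    rows <- list()
    for (m in c("Lp", "Eglob", "Eloc")) {
      for (cg in cog_cols) {
        sc <- spearman_corr(auc_glob[[m]][mci_idx], pheno[[cg]][mci_idx])
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, score = cg, rho = sc$rho, p = sc$p, n = sc$n,
          stringsAsFactors = FALSE
        )
      }
    }
    spearman <- do.call(rbind, rows)
    write_table_with_hash(spearman,
                          file.path(config$output_dir, "spearman_mci.csv"),
                          hash)
  }

  manifest <- list(
    package = "fanet",
    version = as.character(utils::packageVersion("fanet")),
    seed = config$seed, config_hash = hash, config = unclass(config),
    n_subjects = ns, groups = as.list(table(groups))
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    auc = list(global = auc_glob, nodal_efficiency = auc_ne,
               betweenness = auc_bc),
    global_stats = glob_stats, nodal_stats = nodal_stats,
    hubs = list(sets = hub_sets, comparison = hub_cmp), nbs = nbs_out,
    spearman = spearman, manifest = manifest
  ))
}
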