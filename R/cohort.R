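# Synthetic cohort generator: FA-weighted connectomes for three groups
# (HC, NC, MCI) with a graded global-efficiency deficit, a planted impaired
# subnetwork in the MCI group, matched age/sex covariates, and cognitive
# scores linked to each subject's true global efficiency.

#' Configuration for a synthetic connectome cohort
#'
#' Defines the study conditions the generator emulates: three groups of
#' `n_per_group` subjects sharing one random geometric-modular template
#' topology, FA-like edge weights, a multiplicative per-group attenuation of
#' all weights (graded HC > NC > MCI global efficiency), an additional
#' planted deficit on a small connected edge set in the MCI group, and
#' cognitive scores that are affine in each subject's true global efficiency.
#'
#' @param n_per_group Subjects per group (HC, NC, MCI); default 30.
#' @param n_regions Number of network nodes; default 90.
#' @param base_density Fraction of nonzero edges in the shared template.
#' @param fa_mean,fa_sd Mean and SD of template edge weights on the FA scale.
#' @param eglob_effect Multiplicative edge-weight attenuation applied once
#'   per group step (HC -> NC -> MCI); 1 disables the group effect.
#' @param edge_noise_sdlog SD (log scale) of per-edge lognormal subject
#'   noise.
#' @param subject_sdlog SD (log scale) of the per-subject global scaling
#'   factor; controls between-subject efficiency variability.
#' @param planted_edges Optional 2-column matrix of node indices receiving an
#'   additional MCI deficit; `NULL` picks a random 8-edge connected tree (9
#'   nodes) among template edges.
#' @param n_planted_edges Size of the auto-picked planted edge set.
#' @param planted_delta Absolute FA-weight reduction on planted edges in the
#'   MCI group (floored at 0); 0 disables the planted subnetwork.
#' @param cognition_slope Standardized effect of a subject's true global
#'   efficiency on cognitive scores (score SD units per efficiency SD).
#' @param cognition_noise_sd SD of the score noise on the same standardized
#'   scale.
#' @param age_range Uniform age range in years.
#' @param sex_ratio Probability of male sex.
#' @param education_mean,education_sd Normal parameters for years of
#'   education (rounded, floored at 6).
#' @param seed RNG seed; one master seed drives template and per-subject
#'   substreams so generation is reproducible and order-independent.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 30, n_regions = 90,
                          base_density = 0.25, fa_mean = 0.45, fa_sd = 0.10,
                          eglob_effect = 0.93, edge_noise_sdlog = 0.10,
                          subject_sdlog = 0.03, planted_edges = NULL,
                          n_planted_edges = 8, planted_delta = 0.2,
                          cognition_slope = 1.0, cognition_noise_sd = 1.0,
                          age_range = c(45, 65), sex_ratio = 0.5,
                          education_mean = 11.5, education_sd = 3,
                          seed = 1) {
  cfg <- list(
    n_per_group = n_per_group, n_regions = n_regions,
    base_density = base_density, fa_mean = fa_mean, fa_sd = fa_sd,
    eglob_effect = eglob_effect, edge_noise_sdlog = edge_noise_sdlog,
    subject_sdlog = subject_sdlog, planted_edges = planted_edges,
    n_planted_edges = n_planted_edges, planted_delta = planted_delta,
    cognition_slope = cognition_slope,
    cognition_noise_sd = cognition_noise_sd, age_range = age_range,
    sex_ratio = sex_ratio, education_mean = education_mean,
    education_sd = education_sd, seed = seed
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_per_group, min = 2)) {
    stop("n_per_group must be an integer >= 2", call. = FALSE)
  }
  if (!is_count(cfg$n_regions, min = 10)) {
    stop("n_regions must be an integer >= 10", call. = FALSE)
  }
  if (!is_scalar(cfg$base_density) || cfg$base_density <= 0 ||
      cfg$base_density > 1) {
    stop("base_density must lie in (0, 1]", call. = FALSE)
  }
  if (!is_scalar(cfg$eglob_effect) || cfg$eglob_effect <= 0 ||
      cfg$eglob_effect > 1) {
    stop("eglob_effect must lie in (0, 1]", call. = FALSE)
  }
  if (!is_scalar(cfg$planted_delta) || cfg$planted_delta < 0) {
    stop("planted_delta must be non-negative", call. = FALSE)
  }
  if (!is.null(cfg$planted_edges)) {
    pe <- cfg$planted_edges
    if (!is.matrix(pe) || ncol(pe) != 2 ||
        any(pe < 1) || any(pe > cfg$n_regions) || any(pe[, 1] == pe[, 2])) {
      stop("planted_edges must be a 2-column matrix of distinct node indices",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# Shared template: random geometric-modular topology. Nodes get uniform 3-D
# coordinates; connection scores decay exponentially with Euclidean distance
# and are doubled within one of four spatial modules; scores are scaled so
# the expected density matches base_density. Edge weights are FA-like with a
# mild negative distance dependence (short-range tracts are stronger), which
# keeps thresholded networks spatially clustered, as in real connectomes.
build_template <- function(cfg) {
  n <- cfg$n_regions
  coords <- matrix(stats::runif(3 * n), ncol = 3,
                   dimnames = list(region_labels(n), c("x", "y", "z")))
  modules <- 1L + (coords[, 1] >= 0.5) + 2L * (coords[, 2] >= 0.5)
  dist <- as.matrix(stats::dist(coords))
  score <- exp(-dist / 0.3) * (1 + outer(modules, modules, `==`))
  diag(score) <- 0
  ei <- edge_index(n)
  sc <- score[ei]
  target_edges <- cfg$base_density * nrow(ei)
  p <- pmin(sc * target_edges / sum(sc), 1)
  adj <- stats::runif(nrow(ei)) < p
  wts <- cfg$fa_mean - 0.1 * (dist[ei] - mean(dist[ei])) +
    cfg$fa_sd * stats::rnorm(nrow(ei))
  wts <- pmin(pmax(wts, 0.05), 0.95)
  w <- matrix(0, n, n, dimnames = list(rownames(coords), rownames(coords)))
  keep <- which(adj)
  w[ei[keep, , drop = FALSE]] <- wts[keep]
  w[ei[keep, c(2, 1), drop = FALSE]] <- wts[keep]
  planted <- cfg$planted_edges
  if (is.null(planted)) {
    planted <- pick_planted_tree(w, cfg$n_planted_edges)
  } else if (any(w[planted] == 0)) {
    stop("planted_edges must be edges of the generated template",
         call. = FALSE)
  }
  list(weights = w, coords = coords, modules = modules,
       planted_edges = planted)
}

# Grow a random tree of n_edges edges (n_edges + 1 nodes) along template
# edges, so the planted deficit forms one connected subnetwork. Strong edges
# (weight >= 0.25) are preferred so a default planted delta reduces rather
# than deletes tracts, as with the major fiber bundles the deficit emulates.
pick_planted_tree <- function(w, n_edges) {
  deg <- rowSums(w > 0)
  start <- sample(which(deg >= 2), 1)
  nodes <- start
  edges <- matrix(integer(0), 0, 2)
  while (nrow(edges) < n_edges) {
    cand <- which(w[nodes, , drop = FALSE] > 0, arr.ind = TRUE)
    cand <- cbind(nodes[cand[, 1]], cand[, 2])
    cand <- cand[!(cand[, 2] %in% nodes), , drop = FALSE]
    if (nrow(cand) == 0) {
      stop("template too sparse to plant a connected subnetwork",
           call. = FALSE)
    }
    strong <- which(w[cand] >= 0.35)
    if (length(strong)) cand <- cand[strong, , drop = FALSE]
    pick <- cand[sample.int(nrow(cand), 1), ]
    edges <- rbind(edges, range(pick))
    nodes <- c(nodes, pick[2])
  }
  storage.mode(edges) <- "integer"
  unname(edges)
}

#' Generate a synthetic cohort of FA-weighted connectomes
#'
#' Produces `3 * n_per_group` subjects (groups HC, NC, MCI) sharing one
#' random geometric-modular template. Each subject's edge weights are the
#' template weights times the group attenuation (`eglob_effect` per group
#' step), times a per-subject lognormal scale, times per-edge lognormal
#' noise, clipped to `(0, 1]`. MCI subjects are additionally attenuated on
#' the planted edges by `planted_delta`. Cognitive scores (DST_forwards,
#' TMT_A, TMT_B) are affine in the subject's true (unthresholded) global
#' efficiency plus noise; higher efficiency means a better DST score and
#' *lower* (faster) TMT times.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: list with `matrices` (named list of
#'   connectivity matrices), `phenotypes` (data frame: subject_id, group,
#'   age, sex, education and cognitive scores), and `ground_truth` (template,
#'   planted edges, expected group ordering, true per-subject Eglob).
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  n <- cfg$n_regions
  npg <- cfg$n_per_group
  template <- with_seed(cfg$seed, build_template(cfg))
  w0 <- template$weights
  ei <- edge_index(n)
  nz <- which(w0[ei] > 0)
  base_wts <- w0[ei][nz]
  groups <- factor(rep(c("HC", "NC", "MCI"), each = npg),
                   levels = c("HC", "NC", "MCI"))
  step <- as.integer(groups) - 1L
  ns <- length(groups)
  ids <- sprintf("S%03d", seq_len(ns))

  matrices <- vector("list", ns)
  names(matrices) <- ids
  pheno <- data.frame(
    subject_id = ids, group = groups, age = NA_real_,
    sex = NA_character_, education = NA_integer_,
    stringsAsFactors = FALSE
  )
  score_noise <- matrix(NA_real_, ns, 3)
  for (k in seq_len(ns)) {
    sub <- with_seed(substream_seed(cfg$seed, k), {
      scale_k <- exp(stats::rnorm(1, 0, cfg$subject_sdlog))
      noise <- exp(stats::rnorm(length(base_wts), 0, cfg$edge_noise_sdlog))
      list(
        wts = pmin(base_wts * cfg$eglob_effect^step[k] * scale_k * noise, 1),
        age = round(stats::runif(1, cfg$age_range[1], cfg$age_range[2]), 1),
        sex = if (stats::runif(1) < cfg$sex_ratio) "M" else "F",
        edu = max(6L, as.integer(round(stats::rnorm(
          1, cfg$education_mean, cfg$education_sd
        )))),
        eps = stats::rnorm(3, 0, cfg$cognition_noise_sd)
      )
    })
    wk <- matrix(0, n, n, dimnames = dimnames(w0))
    wk[ei[nz, , drop = FALSE]] <- sub$wts
    wk[ei[nz, c(2, 1), drop = FALSE]] <- sub$wts
    matrices[[k]] <- wk
    pheno$age[k] <- sub$age
    pheno$sex[k] <- sub$sex
    pheno$education[k] <- sub$edu
    score_noise[k, ] <- sub$eps
  }

  if (cfg$planted_delta > 0) {
    matrices <- plant_subnetwork_effect(
      matrices, groups, template$planted_edges, cfg$planted_delta,
      target = "MCI"
    )
  }

  true_eglob <- vapply(matrices, efficiency_mean, numeric(1))
  z <- as.numeric(scale(true_eglob))
  if (anyNA(z)) z <- rep(0, ns)  # degenerate: zero variance across subjects
  raw <- cfg$cognition_slope * z
  pheno$DST_forwards <- round(9 + 1.2 * (raw + score_noise[, 1]), 1)
  pheno$TMT_A <- round(55 - 15 * (raw + score_noise[, 2]), 1)
  pheno$TMT_B <- round(70 - 22 * (raw + score_noise[, 3]), 1)

  structure(
    list(
      matrices = matrices,
      phenotypes = pheno,
      ground_truth = list(
        planted_edges = template$planted_edges,
        planted_delta = cfg$planted_delta,
        group_order_eglob = c("HC", "NC", "MCI"),
        template = template,
        true_eglob = true_eglob,
        config = cfg
      )
    ),
    class = "cohort"
  )
}

#' Plant an edge-weight deficit in a targeted group
#'
#' Reduces the listed edge weights by `delta` (symmetrically, floored at 0)
#' in subjects whose group label equals `target`; all other subjects and all
#' other entries are untouched.
#'
#' @param matrices List of connectivity matrices.
#' @param group_labels Group label per subject (same length as `matrices`).
#' @param edges 2-column matrix of node index pairs.
#' @param delta Non-negative weight reduction.
#' @param target Group label to affect.
#' @return The modified list of matrices.
#' @export
plant_subnetwork_effect <- function(matrices, group_labels, edges, delta,
                                    target = "MCI") {
  if (!is_scalar(delta) || delta < 0) {
    stop("delta must be non-negative", call. = FALSE)
  }
  if (length(group_labels) != length(matrices)) {
    stop("group_labels must match matrices in length", call. = FALSE)
  }
  if (!is.matrix(edges) || ncol(edges) != 2) {
    stop("edges must be a 2-column matrix of node indices", call. = FALSE)
  }
  n <- nrow(matrices[[1]])
  if (any(edges < 1) || any(edges > n) || any(edges[, 1] == edges[, 2])) {
    stop("edges contain invalid node pairs", call. = FALSE)
  }
  if (delta == 0) return(matrices)
  floored <- FALSE
  for (k in which(as.character(group_labels) == target)) {
    w <- matrices[[k]]
    cur <- w[edges]
    new <- cur - delta
    if (any(new < 0)) floored <- TRUE
    new <- pmax(new, 0)
    w[edges] <- new
    w[edges[, c(2, 1), drop = FALSE]] <- new
    matrices[[k]] <- w
  }
  if (floored) {
    warning("planted deficit floored some edge weights at 0", call. = FALSE)
  }
  matrices
}

#' Write a cohort to disk
#'
#' One TSV connectivity matrix per subject (`<subject_id>.tsv`), a
#' `phenotypes.csv` table, and a `ground_truth.json` sidecar recording the
#' planted effects.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$matrices)) {
    write_matrix_tsv(cohort$matrices[[id]], file.path(dir, paste0(id, ".tsv")))
  }
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(
      planted_edges = gt$planted_edges,
      planted_delta = gt$planted_delta,
      group_order_eglob = gt$group_order_eglob,
      true_eglob = gt$true_eglob,
      seed = gt$config$seed
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
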