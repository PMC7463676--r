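## End-to-end orchestration: generate/read -> exclude -> index -> scale ->
## SOM -> Ward -> cut -> profile, with deterministic text artifacts.

#' Build and validate a run configuration
#'
#' @param input Path to a cohort CSV, or `NULL` to use the generator.
#' @param generator A [generator_config()] (used when `input` is `NULL`).
#' @param grid_rows,grid_cols SOM grid dimensions (product must equal 27
#'   unless you deliberately change the unit count).
#' @param iterations,lr SOM training schedule.
#' @param n_restarts SOM restarts for the main model.  The reference
#'   protocol uses 1000; the default here is 100 for desk-scale runs - set
#'   `full = TRUE` to restore 1000.
#' @param k_range Candidate cluster numbers for silhouette selection.
#' @param cut_levels Dendrogram cut levels to report.
#' @param n_bootstrap Bootstrap resamples for stability (0 to skip).
#' @param bootstrap_restarts SOM restarts within each resample.
#' @param by_gender Also profile male/female strata.
#' @param seed Master seed.
#' @param out Output directory, or `NULL` for no files.
#' @param full Use the full 1000-restart protocol.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, generator = generator_config(),
                       grid_rows = 3, grid_cols = 9,
                       iterations = 500, lr = c(0.05, 0.01),
                       n_restarts = 100, k_range = 2:10,
                       cut_levels = c(2, 11, 27), n_bootstrap = 100,
                       bootstrap_restarts = 10, by_gender = FALSE,
                       seed = 1, out = NULL, full = FALSE) {
  if (full) n_restarts <- 1000
  n_units <- grid_rows * grid_cols
  stopifnot(iterations >= 0, n_restarts >= 1, length(lr) == 2,
            all(lr > 0), n_bootstrap >= 0, bootstrap_restarts >= 1)
  if (any(k_range < 2 | k_range > n_units - 1))
    stop("k_range must lie within [2, ", n_units - 1, "]")
  if (any(cut_levels < 1 | cut_levels > n_units))
    stop("cut_levels must lie within [1, ", n_units, "]")
  structure(
    list(input = input, generator = generator, grid_rows = grid_rows,
         grid_cols = grid_cols, iterations = iterations, lr = lr,
         n_restarts = n_restarts, k_range = k_range,
         cut_levels = cut_levels, n_bootstrap = n_bootstrap,
         bootstrap_restarts = bootstrap_restarts, by_gender = by_gender,
         seed = as.integer(seed), out = out),
    class = "run_config"
  )
}

#' Read a run configuration from its declarative JSON file
#'
#' Parses the `config.json` a run writes (see [write_artifacts()]), so a
#' run can be reproduced from its own serialized configuration.  The seed
#' can be overridden (the command-line `--seed` semantics).
#'
#' @param path Path to a `config.json`.
#' @param seed Optional replacement master seed.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, seed = NULL) {
  j <- jsonlite::read_json(path)
  gen <- generator_config()
  if (!is.null(j$generator)) {
    g <- j$generator
    archs <- lapply(g$archetypes, function(a)
      archetype(a$name, as.numeric(a$prevalence),
                medians = unlist(a$medians), cv = unlist(a$cv),
                ogtt_rho = as.numeric(a$ogtt_rho)))
    gen <- generator_config(
      n_subjects = as.integer(g$n_subjects), archetypes = archs,
      female_fraction = as.numeric(g$female_fraction),
      missing_rate = as.numeric(g$missing_rate),
      medicated_rate = as.numeric(g$medicated_rate),
      seed = as.integer(g$seed))
  }
  input <- if (is.null(j$input) || !length(j$input)) NULL
    else as.character(j$input)
  run_config(
    input = input, generator = gen,
    grid_rows = as.integer(j$grid[[1]]), grid_cols = as.integer(j$grid[[2]]),
    iterations = as.integer(j$iterations), lr = as.numeric(unlist(j$lr)),
    n_restarts = as.integer(j$n_restarts),
    k_range = as.integer(unlist(j$k_range)),
    cut_levels = as.integer(unlist(j$cut_levels)),
    n_bootstrap = as.integer(j$n_bootstrap),
    bootstrap_restarts = as.integer(j$bootstrap_restarts),
    by_gender = isTRUE(j$by_gender),
    seed = if (is.null(seed)) as.integer(j$seed) else as.integer(seed))
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full metabolic footprint analysis
#'
#' Executes every stage on the configured input (or a generated cohort) and
#' returns all artifacts; when `config$out` is set, also writes them as
#' delimited text (tables), newick text (dendrogram) and a JSON manifest
#' with content hashes, so a rerun with the same config and seed produces
#' byte-identical files.
#'
#' @param config A [run_config()].
#' @return list of class `"run_artifacts"`: `cohort`, `exclusions`,
#'   `panel`, `features`, `model`, `tree`, `assignment`, `optimal_k`,
#'   `silhouette`, `partitions`, `stability`, `percentiles`, `profiles`,
#'   `footprints`, `dysglycemia`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$input)) {
    .stage_log("input", "reading ", config$input)
    read_cohort(config$input)
  } else {
    .stage_log("simulate", "generating ", config$generator$n_subjects,
               " subjects (seed ", config$generator$seed, ")")
    generate_cohort(config$generator)
  }
  ex <- apply_exclusions(cohort)
  .stage_log("exclude", ex$report$n_input, " in; ", ex$report$medicated,
             " medicated and ", ex$report$missing,
             " incomplete removed; ", ex$report$n_retained, " retained")
  included <- ex$cohort

  panel <- compute_panel(included)
  .stage_log("indexes", ncol(panel) - 1, " indexes for ", nrow(panel),
             " subjects")

  features <- scale_features(included)
  grid <- build_grid(config$grid_rows, config$grid_cols)
  model <- restart_best(features, grid, n_restarts = config$n_restarts,
                        iterations = config$iterations, lr = config$lr,
                        seed = config$seed)
  .stage_log("som", config$n_restarts, " restarts; best qe = ",
             format(model$qe, digits = 6))

  tree <- ward_tree(model)
  sil <- silhouette_by_k(tree, config$k_range)
  optimal_k <- config$k_range[which.max(sil)]
  .stage_log("cluster", "optimal K = ", optimal_k)
  assignment <- map_subjects(model, features)
  cuts <- sort(unique(c(config$cut_levels, optimal_k)))
  partitions <- cut_partitions(tree, cuts, assignment)

  stability <- NULL
  if (config$n_bootstrap > 0) {
    ref <- partitions[[paste0("K", optimal_k)]]$subject_clusters
    stability <- bootstrap_stability(
      included, ref, k = optimal_k, grid = grid,
      n_resamples = config$n_bootstrap,
      restarts = config$bootstrap_restarts,
      iterations = config$iterations, lr = config$lr,
      seed = config$seed
    )
    .stage_log("stability", config$n_bootstrap,
               " resamples; overall mean Jaccard = ",
               sprintf("%.3f", stability$overall))
  }

  prof_vars <- cbind(included[, c("id", clustering_variables(), "hba1c",
                                  "tg", "hdl")],
                     panel[match(included$id, panel$id),
                           setdiff(names(panel),
                                   c("id", "glycemia_class", "mets", "t2d"))])
  percentiles <- population_percentiles(prof_vars[, -1])
  glyc <- stats::setNames(panel$glycemia_class, panel$id)

  strata <- list(all = rep(TRUE, nrow(included)))
  if (config$by_gender)
    strata <- c(strata, list(male = included$sex == "male",
                             female = included$sex == "female"))
  profiles <- list(); footprints <- list(); dysg <- list()
  for (nm in names(partitions)) {
    sc <- partitions[[nm]]$subject_clusters
    dysg[[nm]] <- dysglycemia_composition(sc, glyc)
    for (st in names(strata)) {
      pv <- prof_vars[strata[[st]], , drop = FALSE]
      key <- paste0(nm, "_", st)
      profiles[[key]] <- profile_clusters(sc, pv, percentiles, stratum = st)
      footprints[[key]] <- footprint(profiles[[key]])
    }
  }
  .stage_log("profile", length(profiles), " profile matrices (",
             paste(names(partitions), collapse = ", "), ")")

  artifacts <- structure(
    list(cohort = cohort, exclusions = ex$report, panel = panel,
         features = features, model = model, tree = tree,
         assignment = assignment, optimal_k = optimal_k,
         silhouette = sil, partitions = partitions, stability = stability,
         percentiles = percentiles, profiles = profiles,
         footprints = footprints, dysglycemia = dysg, config = config),
    class = "run_artifacts"
  )
  if (!is.null(config$out)) write_artifacts(artifacts, config$out)
  artifacts
}

#' Serialize run artifacts to a directory
#'
#' Writes delimited-text tables, the dendrogram as newick tree text with
#' Ward heights as branch lengths, the resolved configuration, and a
#' manifest JSON with an md5 hash per artifact file.
#'
#' @param artifacts A `run_artifacts` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_artifacts <- function(artifacts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  jsonlite::write_json(artifacts$exclusions, fp("exclusions.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_panel(artifacts$panel, fp("panel.csv"))
  cb <- data.frame(unit = seq_len(nrow(artifacts$model$codebook)),
                   artifacts$model$codebook)
  utils::write.csv(cb, fp("codebooks.csv"), row.names = FALSE, quote = FALSE)
  phy <- ape::as.phylo(artifacts$tree$hclust)
  ape::write.tree(phy, fp("dendrogram.nwk"))
  assign_out <- artifacts$assignment
  for (nm in names(artifacts$partitions))
    assign_out[[nm]] <-
      artifacts$partitions[[nm]]$subject_clusters[assign_out$id]
  utils::write.csv(assign_out, fp("assignments.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(
    data.frame(k = as.integer(names(artifacts$silhouette)),
               mean_silhouette = as.numeric(artifacts$silhouette)),
    fp("silhouette.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(artifacts$stability))
    jsonlite::write_json(
      list(k = artifacts$stability$k,
           n_resamples = artifacts$stability$n_resamples,
           per_cluster = as.list(artifacts$stability$per_cluster),
           overall = artifacts$stability$overall,
           skipped = artifacts$stability$skipped),
      fp("stability.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (key in names(artifacts$profiles)) {
    pr <- artifacts$profiles[[key]]
    long <- data.frame(variable = rownames(pr$bins),
                       pr$medians, check.names = FALSE)
    utils::write.csv(long, fp(paste0("profile_medians_", key, ".csv")),
                     row.names = FALSE, quote = FALSE)
    binsdf <- data.frame(variable = rownames(pr$bins),
                         apply(pr$bins, 2, function(b) .bin_labels[b]),
                         check.names = FALSE)
    utils::write.csv(binsdf, fp(paste0("profile_bins_", key, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(artifacts$footprints[[key]],
                     fp(paste0("footprint_", key, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(artifacts$percentiles, fp("percentiles.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- artifacts$config
  cfg_json <- list(
    input = cfg$input, grid = c(cfg$grid_rows, cfg$grid_cols),
    iterations = cfg$iterations, lr = cfg$lr, n_restarts = cfg$n_restarts,
    k_range = cfg$k_range, cut_levels = cfg$cut_levels,
    n_bootstrap = cfg$n_bootstrap,
    bootstrap_restarts = cfg$bootstrap_restarts,
    by_gender = cfg$by_gender, seed = cfg$seed,
    generator = if (is.null(cfg$input))
      list(n_subjects = cfg$generator$n_subjects,
           seed = cfg$generator$seed,
           archetypes = lapply(cfg$generator$archetypes, function(a)
             list(name = a$name, prevalence = a$prevalence,
                  medians = as.list(a$medians), cv = as.list(a$cv),
                  ogtt_rho = a$ogtt_rho)),
           female_fraction = cfg$generator$female_fraction,
           missing_rate = cfg$generator$missing_rate,
           medicated_rate = cfg$generator$medicated_rate)
  )
  jsonlite::write_json(cfg_json, fp("config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- setdiff(list.files(dir, full.names = TRUE),
                   fp("manifest.json"))
  manifest <- list(
    created = "run",  # no timestamp: artifacts must be byte-reproducible
    optimal_k = artifacts$optimal_k,
    n_retained = artifacts$exclusions$n_retained,
    quantization_error = artifacts$model$qe,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
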