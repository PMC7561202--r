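#' Pipeline configuration
#'
#' Collects input locations, stage toggles and per-stage parameters for
#' [run_pipeline()]. Defaults mirror the full-scale characterization
#' protocol (admixture burn-in 1e5 / 1e6 sweeps, K 1-10, 10 runs, q
#' threshold 0.70, 1000 bootstrap replicates, DAPC Kmax 20, core fractions
#' 0.1/0.2/0.3); scaled-down MCMC settings are a supported first-class mode
#' for desk-scale runs.
#'
#' @param input path to a genotype table, or a `genotype_matrix` directly.
#' @param dialect input dialect for [read_genotype_table()].
#' @param reference_panel optional path to a reference panel CSV, or a
#'   `reference_panel` object.
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; all stage seeds derive from it.
#' @param stages character vector of stages to run, a subset of
#'   `c("diversity", "identity", "tree", "admixture", "dapc", "core")`.
#' @param K_range,runs_per_K,burnin,iters,q_threshold admixture settings.
#' @param hierarchical run the second admixture round per first-round
#'   cluster.
#' @param bootstrap_replicates NJ bootstrap count.
#' @param dapc_Kmax DAPC BIC-scan maximum.
#' @param core_fractions core-collection size fractions.
#' @param core_restarts restarts for the core search.
#' @param resume skip stages whose summary artifact already exists.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, dialect = "pairs_csv",
                            reference_panel = NULL, out_dir = "ssrbank_out",
                            seed = 1L,
                            stages = c("diversity", "identity", "tree",
                                       "admixture", "dapc", "core"),
                            K_range = 1:10, runs_per_K = 10L,
                            burnin = 100000L, iters = 1000000L,
                            q_threshold = 0.70, hierarchical = TRUE,
                            bootstrap_replicates = 1000L, dapc_Kmax = 20L,
                            core_fractions = c(0.1, 0.2, 0.3),
                            core_restarts = 10L, resume = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(q_threshold > 0, q_threshold <= 1, burnin >= 0, iters >= 1,
            all(core_fractions > 0), all(core_fractions <= 1))
  structure(list(input = input, dialect = dialect,
                 reference_panel = reference_panel, out_dir = out_dir,
                 seed = as.integer(seed), stages = stages,
                 K_range = K_range, runs_per_K = runs_per_K,
                 burnin = burnin, iters = iters, q_threshold = q_threshold,
                 hierarchical = hierarchical,
                 bootstrap_replicates = bootstrap_replicates,
                 dapc_Kmax = dapc_Kmax, core_fractions = core_fractions,
                 core_restarts = core_restarts, resume = resume),
            class = "pipeline_config")
}

#' Run the full characterization pipeline
#'
#' Executes the stages in protocol order — diversity statistics, identity
#' resolution, Rogers/NJ tree, admixture (first round plus optional
#' hierarchical second round), DAPC, core collections — writing per-stage
#' plain-text artifacts (CSV/JSON/Newick) plus a machine-readable
#' `summary.json` and a `manifest.json` recording parameters and derived
#' seeds. With `resume = TRUE`, stages whose artifacts already exist are
#' skipped. A stage failure aborts with the stage name; completed artifacts
#' are preserved.
#'
#' @param config a [pipeline_config()].
#' @return named list of stage results (also serialized under
#'   `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- if (is_genotype_matrix(config$input)) config$input
        else read_genotype_table(config$input, dialect = config$dialect)
  panel <- config$reference_panel
  if (is.character(panel)) panel <- read_reference_panel(panel)
  stage_names <- c("diversity", "identity", "tree", "admixture", "dapc", "core")
  seeds <- setNames(vapply(seq_along(stage_names), function(i)
    derive_seed(config$seed, i), 0L), stage_names)
  manifest <- list(package_version = as.character(utils::packageVersion("ssrbank")),
                   master_seed = config$seed, stage_seeds = as.list(seeds),
                   parameters = config[setdiff(names(config),
                                               c("input", "reference_panel"))],
                   n_accessions = length(gm$accession_ids),
                   n_loci = length(gm$locus_ids))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  results <- list()
  run_stage <- function(name, artifact, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    path <- file.path(config$out_dir, artifact)
    if (config$resume && file.exists(path)) {
      message("stage '", name, "': artifact exists, resumed past")
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("stage '%s' done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    results[[name]] <<- res
    invisible(res)
  }

  run_stage("diversity", "diversity.csv", function() {
    cs <- collection_summary(gm, null_r = TRUE)
    write.csv(cs$table, file.path(config$out_dir, "diversity.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(total = as.list(cs$total),
                              mean = as.list(cs$mean), se = as.list(cs$se)),
                         file.path(config$out_dir, "diversity_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cs
  })
  run_stage("identity", "identity.json", function() {
    rep <- identity_report(gm, panel = panel)
    jsonlite::write_json(
      list(n_unique_genotypes = rep$n_unique_genotypes,
           duplicate_groups = rep$duplicate_groups,
           synonym_groups = rep$synonym_groups,
           reference = if (!is.null(rep$reference)) list(
             validated = rep$reference$validated,
             misnamed = rep$reference$misnamed,
             unknown = rep$reference$unknown,
             unreported = rep$reference$unreported)),
      file.path(config$out_dir, "identity.json"),
      auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    rep
  })
  run_stage("tree", "tree.nwk", function() {
    bs <- bootstrap_supports(gm, replicates = config$bootstrap_replicates,
                             seed = seeds[["tree"]])
    write_newick(bs$tree, file.path(config$out_dir, "tree.nwk"))
    d <- rogers_distance(gm)
    write.csv(d, file.path(config$out_dir, "rogers_distance.csv"))
    bs
  })
  run_stage("admixture", "admixture_q.csv", function() {
    scan <- admixture_scan(gm, K_range = config$K_range,
                           runs_per_K = config$runs_per_K,
                           burnin = config$burnin, iters = config$iters,
                           seed = seeds[["admixture"]])
    write.csv(scan$evanno, file.path(config$out_dir, "evanno.csv"),
              row.names = FALSE)
    bK <- scan$best_K
    labels <- NULL
    hier <- NULL
    al <- NULL
    if (!is.na(bK) && bK >= 2L) {
      runs_at_best <- scan$runs[vapply(scan$runs, function(r) r$K, 0L) == bK]
      al <- align_runs_greedy(runs_at_best)
      labels <- assign_memberships(al$Q_mean, threshold = config$q_threshold)
      write.csv(data.frame(accession = rownames(al$Q_mean), al$Q_mean,
                           label = labels),
                file.path(config$out_dir, "admixture_q.csv"),
                row.names = FALSE)
      if (config$hierarchical) {
        hier <- hierarchical_rounds(gm, labels, K_range = config$K_range,
                                    runs_per_K = config$runs_per_K,
                                    burnin = config$burnin,
                                    iters = config$iters,
                                    seed = derive_seed(seeds[["admixture"]], 999L),
                                    threshold = config$q_threshold)
        jsonlite::write_json(as.list(attr(hier, "nested_labels")),
                             file.path(config$out_dir, "admixture_hierarchical.json"),
                             auto_unbox = TRUE)
      }
    } else {
      write.csv(data.frame(accession = gm$accession_ids, C1 = 1,
                           label = "C1"),
                file.path(config$out_dir, "admixture_q.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(as.list(labels),
                         file.path(config$out_dir, "admixture_labels.json"),
                         auto_unbox = TRUE)
    list(scan = scan, alignment = al, labels = labels, hierarchical = hier)
  })
  run_stage("dapc", "dapc_bic.csv", function() {
    res <- dapc_analysis(gm, Kmax = min(config$dapc_Kmax,
                                        length(gm$accession_ids) - 1L),
                         seed = seeds[["dapc"]])
    write.csv(res$bic_curve, file.path(config$out_dir, "dapc_bic.csv"),
              row.names = FALSE)
    write.csv(data.frame(accession = gm$accession_ids,
                         cluster = res$cluster_labels),
              file.path(config$out_dir, "dapc_clusters.csv"),
              row.names = FALSE)
    if (!is.null(res$discriminant_coords))
      write.csv(res$discriminant_coords,
                file.path(config$out_dir, "dapc_coords.csv"))
    res
  })
  run_stage("core", "core_collections.csv", function() {
    series <- core_collection_series(gm, fractions = config$core_fractions,
                                     seed = seeds[["core"]],
                                     restarts = config$core_restarts)
    write.csv(cbind(sample = rownames(series$table), series$table),
              file.path(config$out_dir, "core_collections.csv"),
              row.names = FALSE)
    for (nm in names(series$cores))
      writeLines(series$cores[[nm]]$members,
                 file.path(config$out_dir, paste0(nm, "_members.txt")))
    series
  })

  summary <- list(
    n_accessions = length(gm$accession_ids),
    n_loci = length(gm$locus_ids),
    stages_run = intersect(stage_names, config$stages),
    diversity = if (!is.null(results$diversity))
      list(total = as.list(results$diversity$total),
           mean = as.list(results$diversity$mean)),
    identity = if (!is.null(results$identity))
      list(n_unique_genotypes = results$identity$n_unique_genotypes,
           n_duplicate_groups = length(results$identity$duplicate_groups),
           n_synonym_groups = length(results$identity$synonym_groups)),
    admixture = if (!is.null(results$admixture))
      list(best_K = results$admixture$scan$best_K,
           cluster_sizes = if (!is.null(results$admixture$labels))
             as.list(table(results$admixture$labels))),
    dapc = if (!is.null(results$dapc))
      list(best_K = results$dapc$best_K,
           retained_pcs = results$dapc$retained_pcs,
           variance_explained = results$dapc$variance_explained),
    core = if (!is.null(results$core))
      lapply(results$core$cores, function(cc)
        list(n = length(cc$members), coverage_pct = cc$coverage_pct)))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       force = TRUE)
  invisible(results)
}

#' Recompute the collection-level report for a full dataset
#'
#' Convenience wrapper reproducing, for a collection genotype table in the
#' canonical `pairs_csv` layout, the headline numbers of a germplasm
#' characterization: the per-locus diversity table with totals/means, the
#' unique-genotype/duplicate/synonym counts, and core collections at
#' fractions 0.1-0.3 (with absolute sizes available via `core_sizes`).
#'
#' @param path genotype table path (pairs_csv) or a `genotype_matrix`.
#' @param core_sizes optional absolute core sizes (e.g. `c(41, 82, 120)`);
#'   when `NULL`, fractions 0.1/0.2/0.3 are used.
#' @param seed master seed.
#' @param core_restarts restarts for the core search.
#' @return list with `diversity` ([collection_summary()] output),
#'   `identity` (duplicate/synonym grouping over all loci), and `cores`.
#' @export
reproduce_collection_report <- function(path, core_sizes = NULL, seed = 1L,
                                        core_restarts = 10L) {
  gm <- if (is_genotype_matrix(path)) path else read_genotype_table(path)
  div <- collection_summary(gm, null_r = TRUE)
  idr <- find_duplicates_and_synonyms(gm, min_loci = 0L)
  cores <- if (is.null(core_sizes)) {
    core_collection_series(gm, seed = seed, restarts = core_restarts)$cores
  } else {
    lapply(seq_along(core_sizes), function(i)
      select_core(gm, fraction = core_sizes[i] / length(gm$accession_ids),
                  size_absolute = core_sizes[i],
                  seed = derive_seed(seed, i), restarts = core_restarts))
  }
  list(diversity = div, identity = idr, cores = cores)
}
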