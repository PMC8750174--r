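# End-to-end orchestration: a single validated configuration drives the
# five analysis stages (effect sizes, target catalog, PPI networks,
# enrichment + clustering, drug mining) over real input files or a
# simulated world, writing every stage's outputs plus a hashed manifest.

default_config <- function() {
  list(
    inputs = list(readings = NULL, blast_hits = NULL, annotation = NULL,
                  interactions = NULL, genesets = NULL, drugs_db = NULL,
                  drugs_ttd = NULL),
    simulation = NULL,
    thresholds = list(shell1_score = 900, shell2_score = 900,
                      relaxed_score = 700, adj_p = 0.05, kappa = 0.5),
    control_condition = "negative_control",
    output_dir = "redoxscreen_run"
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (interaction-score thresholds 900/900/700, adjusted-p
#' cutoff 0.05, kappa threshold 0.5) and reports every violation found,
#' not just the first.
#'
#' @param config Named list (possibly nested) or path to a YAML/JSON file.
#' @return The normalized config (invisibly classed
#'   \code{redoxscreen_config}); if anything is invalid, an error listing
#'   all violations.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- default_config()
  for (nm in intersect(names(config), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(config[[nm]])) {
      for (sub in names(config[[nm]])) {
        if (!is.null(config[[nm]][[sub]]))
          cfg[[nm]][[sub]] <- config[[nm]][[sub]]
      }
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  errs <- character()
  th <- cfg$thresholds
  for (f in c("shell1_score", "shell2_score", "relaxed_score")) {
    v <- th[[f]]
    if (!is.numeric(v) || v < SCORE_MIN || v > SCORE_MAX)
      errs <- c(errs, sprintf("thresholds$%s must lie in [%d, %d]",
                              f, SCORE_MIN, SCORE_MAX))
  }
  if (!is.numeric(th$adj_p) || th$adj_p <= 0 || th$adj_p >= 1)
    errs <- c(errs, "thresholds$adj_p must lie in (0, 1)")
  if (!is.numeric(th$kappa) || th$kappa < -1 || th$kappa > 1)
    errs <- c(errs, "thresholds$kappa must lie in [-1, 1]")
  have_sim <- !is.null(cfg$simulation)
  have_paths <- any(!vapply(cfg$inputs, is.null, TRUE))
  if (!have_sim && !have_paths)
    errs <- c(errs, "config needs either input paths or a simulation block")
  if (have_sim && is.null(cfg$simulation$seed))
    errs <- c(errs, "simulation block requires an explicit integer seed")
  if (length(errs))
    ox_stop(paste0("invalid configuration:\n  - ",
                   paste(errs, collapse = "\n  - ")), "invalid_config")
  class(cfg) <- "redoxscreen_config"
  invisible(cfg)
}

# generate the full simulated world for a simulation block; modules and
# enriched sets are planted inside the generated target catalog so the
# stages chain like real data would
simulate_world <- function(sim, dir) {
  seed <- sim$seed
  g <- function(nm, default) if (is.null(sim[[nm]])) default else sim[[nm]]
  scr <- simulate_screen(n_sirnas = g("n_sirnas", 181),
                         replicates = g("replicates", 4),
                         timepoints = g("timepoints", 6),
                         noise_sd = g("noise_sd", 10), seed = seed)
  hits <- simulate_hits_and_annotation(n_genes = g("n_genes", 500),
                                       n_queries = g("n_queries", 167),
                                       decoys_per_query = g("decoys_per_query", 3),
                                       seed = seed + 1L)
  symbols <- sort(unique(unname(hits$truth$planted_symbols)))
  # modules mix catalog targets with dedicated interactor nodes, so the
  # 1st shell at the very-high threshold is non-empty and known
  module_sizes <- g("module_sizes", c(20, 8, 5))
  n_mod <- sum(module_sizes)
  n_int <- min(ceiling(n_mod / 2), n_mod - 1L)
  pool <- c(symbols[seq_len(min(n_mod - n_int, length(symbols)))],
            sprintf("INT%04d", seq_len(n_int)))
  net <- simulate_interactome(module_sizes = module_sizes,
                              n_background = g("n_background", 50),
                              seed = seed + 2L, node_pool = pool)
  shell1 <- sort(unique(unlist(lapply(net$truth$planted_modules,
    function(m) if (any(m %in% symbols)) setdiff(m, symbols)
                else character()))))
  entrez <- as.character(sort(unique(unname(hits$truth$planted_targets))))
  gs <- simulate_genesets(universe_size = g("universe_size", 2000),
                          n_sets = g("n_sets", 50),
                          planted_set_overlap = g("planted_set_overlap", 15),
                          seed = seed + 3L, query_genes = entrez)
  drugs <- simulate_drug_tables(gene_listA = symbols, gene_listB = shell1,
                                n_common_drugs = g("n_common_drugs", 5),
                                n_cross_db_common = g("n_cross_db_common", 3),
                                seed = seed + 4L)
  world <- list(readings = scr$readings, hits = hits$hits,
                annotation = hits$annotation,
                interactions = net$interactions,
                collection = gs$collection, query = gs$query,
                db = drugs$db, ttd = drugs$ttd,
                truth = new_truth(seed,
                                  planted_effects = scr$truth$planted_effects,
                                  planted_bins = scr$truth$planted_bins,
                                  planted_targets = hits$truth$planted_targets,
                                  planted_modules = net$truth$planted_modules,
                                  planted_shell1 = shell1,
                                  planted_set = gs$truth$planted_set,
                                  planted_drug_overlaps =
                                    drugs$truth$planted_drug_overlaps))
  paths <- write_simulation(world, dir)
  list(world = world, paths = paths)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: per-siRNA effect sizes and bin counts; BLAST hit
#' reduction to a target catalog; four PPI networks (targets-only at the
#' very-high threshold, 1st shell at the relaxed and very-high thresholds,
#' 1st+2nd shell at the very-high threshold) with summaries; ORA with
#' kappa clustering; drug mining over targets and 1st-shell interactors.
#' Any stage failure aborts with the failing stage named; outputs of
#' completed stages are retained. A manifest records the config hash and
#' an MD5 content hash per output file.
#'
#' @param config A config list, \code{redoxscreen_config}, or path to a
#'   YAML/JSON config file (see [validate_config()]).
#' @return Invisibly, a list with per-stage results and \code{manifest}.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "redoxscreen_config")) config
    else validate_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    logf("[%s] start", name)
    tryCatch(expr, error = function(e) {
      ox_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "stage_failure")
    })
  }
  inputs <- cfg$inputs
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- stage("simulate",
                 simulate_world(cfg$simulation, file.path(out_dir, "inputs")))
    inputs <- list(readings = sim$paths[["readings"]],
                   blast_hits = sim$paths[["hits"]],
                   annotation = sim$paths[["annotation"]],
                   interactions = sim$paths[["interactions"]],
                   genesets = sim$paths[["collection"]],
                   drugs_db = sim$paths[["db"]],
                   drugs_ttd = sim$paths[["ttd"]])
    truth <- sim$world$truth
  }
  results <- list(truth = truth)
  th <- cfg$thresholds

  # stage 1: effect sizes
  if (!is.null(inputs$readings)) {
    results$effects <- stage("screen_stats", {
      readings <- utils::read.csv(inputs$readings, stringsAsFactors = FALSE)
      eff <- screen_effects(readings, cfg$control_condition)
      write_tsv(eff[, c("sirna_id", "timepoint_h", "delta", "ci_low",
                        "ci_high", "bin")],
                file.path(out_dir, "effect_sizes.tsv"))
      counts <- summarize_screen(eff, min(eff$timepoint_h))
      jsonlite::write_json(as.list(counts),
                           file.path(out_dir, "bin_counts.json"),
                           auto_unbox = TRUE, digits = NA)
      eff
    })
  }

  # stage 2: target catalog
  catalog <- NULL
  if (!is.null(inputs$blast_hits)) {
    catalog <- stage("target_catalog", {
      cat_ <- reduce_hits(inputs$blast_hits, inputs$annotation)
      write_catalog(cat_, tsv = file.path(out_dir, "target_catalog.tsv"),
                    json = file.path(out_dir, "catalog_tally.json"))
      cat_
    })
    results$catalog <- catalog
  }

  # stage 3: PPI networks (Table-1-style quartet)
  if (!is.null(inputs$interactions) && !is.null(catalog)) {
    results$networks <- stage("ppi_network", {
      edges <- load_interactions(inputs$interactions)
      targets <- unique(catalog$per_query$symbol)
      specs <- list(
        targets_only = list(shells = 0, t1 = th$shell1_score),
        shell1_relaxed = list(shells = 1, t1 = th$relaxed_score),
        shell1 = list(shells = 1, t1 = th$shell1_score),
        shell2 = list(shells = 2, t1 = th$shell1_score))
      nets <- lapply(names(specs), function(nm) {
        sp <- specs[[nm]]
        net <- expand_network(targets, edges, shells = sp$shells,
                              t1 = sp$t1, t2 = th$shell2_score)
        write_network(net, file.path(out_dir, sprintf("network_%s_edges.tsv", nm)),
                      file.path(out_dir, sprintf("network_%s_nodes.tsv", nm)))
        list(network = net, summary = summarize_network(net, targets))
      })
      names(nets) <- names(specs)
      summaries <- lapply(nets, function(x) unclass(x$summary))
      jsonlite::write_json(summaries,
                           file.path(out_dir, "network_summaries.json"),
                           auto_unbox = TRUE, digits = NA)
      nets
    })
  }

  # stage 4: enrichment + term clustering
  if (!is.null(inputs$genesets) && !is.null(catalog)) {
    results$enrichment <- stage("enrichment", {
      collection <- read_gmt(inputs$genesets)
      query <- as.character(catalog$unique_genes)
      ora <- run_ora(query, collection, alpha = th$adj_p)
      clusters <- cluster_terms(ora, collection, kappa_threshold = th$kappa)
      write_enrichment(ora, clusters,
                       tsv = file.path(out_dir, "enrichment.tsv"),
                       json = file.path(out_dir, "term_clusters.json"))
      list(ora = ora, clusters = clusters)
    })
  }

  # stage 5: drug mining (targets vs 1st-shell interactors)
  if (!is.null(inputs$drugs_db) && !is.null(catalog)) {
    results$drugs <- stage("drug_mining", {
      db <- load_drug_table(inputs$drugs_db, "DB")
      ttd <- if (!is.null(inputs$drugs_ttd))
        load_drug_table(inputs$drugs_ttd, "TTD")
        else load_drug_table(data.frame(drug_code = character(),
                                        name = character(),
                                        status = character(),
                                        gene = character()), "TTD")
      targets <- unique(catalog$per_query$symbol)
      shell1 <- if (!is.null(results$networks))
        results$networks$shell1$network$nodes$node[
          results$networks$shell1$network$nodes$role == "shell1"]
        else character()
      rep_ <- drug_mining_report(targets, shell1, db, ttd)
      jsonlite::write_json(
        list(targets_db = list(genes_hit = rep_$A_db$n_genes_hit,
                               drugs = rep_$A_db$n_drugs,
                               approved = rep_$A_db$n_approved,
                               approved_pct = rep_$A_db$pct_approved,
                               patented = rep_$A_db$n_patented),
             shell1_db = list(genes_hit = rep_$B_db$n_genes_hit,
                              drugs = rep_$B_db$n_drugs,
                              approved = rep_$B_db$n_approved,
                              approved_pct = rep_$B_db$pct_approved,
                              patented = rep_$B_db$n_patented),
             targets_ttd = list(genes_hit = rep_$A_ttd$n_genes_hit,
                                drugs = rep_$A_ttd$n_drugs,
                                approved = rep_$A_ttd$n_approved,
                                patented = rep_$A_ttd$n_patented),
             shell1_ttd = list(genes_hit = rep_$B_ttd$n_genes_hit,
                               drugs = rep_$B_ttd$n_drugs,
                               approved = rep_$B_ttd$n_approved,
                               patented = rep_$B_ttd$n_patented),
             db_common = nrow(rep_$db_common),
             cross_db_common = nrow(rep_$cross_db_common)),
        file.path(out_dir, "drug_mining.json"), auto_unbox = TRUE,
        digits = NA)
      rep_
    })
  }

  # manifest: config hash + content hash per output
  outputs <- setdiff(list.files(out_dir, recursive = TRUE),
                     c("manifest.json", "run.log"))
  cfg_hash <- digest_config(cfg)
  manifest <- list(config_hash = cfg_hash,
                   seed = if (!is.null(cfg$simulation)) cfg$simulation$seed,
                   files = lapply(stats::setNames(outputs, outputs),
                                  function(f) unname(tools::md5sum(
                                    file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  logf("pipeline complete: %d output file(s)", length(outputs))
  invisible(results)
}

# stable hash of the normalized config
digest_config <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
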