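# Synthetic-data generators for every pipeline input, each with planted
# ground truth (a `sim_truth` object) so downstream stages are testable
# without external downloads. Identical seed + parameters give identical
# tables, hence byte-identical files through the deterministic writers.

BIOTYPES <- c("protein coding", "lncRNA", "pseudogene", "TEC")

new_truth <- function(seed, ...) {
  structure(c(list(seed = seed), list(...)), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulation truth (seed %d): %s\n", x$seed,
              paste(setdiff(names(x), "seed"), collapse = ", ")))
  invisible(x)
}

# deterministic residual pattern with exact sample mean 0 and SD 1;
# realizes the zero-noise limit of the effect-size estimator
exact_pattern <- function(n) {
  z <- seq_len(n) - (n + 1) / 2
  z / stats::sd(z)
}

#' Simulate screen viability plate readings
#'
#' Emulates a viability screen read at several timepoints: a negative
#' control condition with mean reading 100 (arbitrary survival units) and
#' one condition per test siRNA with mean \code{100 + d * noise_sd}, where
#' \code{d} is the siRNA's planted standardized difference, cycled through
#' \code{bin_centers}. Readings carry Gaussian noise with SD
#' \code{noise_sd} (homoscedastic across conditions).
#'
#' With \code{noise = "exact"} the residuals are instead a fixed pattern
#' with exact sample mean 0 and SD 1 (scaled by \code{noise_sd}), so the
#' estimated Cohen's d equals the planted d exactly — the zero-noise limit
#' of the estimator, useful for exact recovery checks.
#'
#' @param n_sirnas Number of test siRNAs.
#' @param bin_centers Planted standardized differences, recycled over
#'   siRNAs. Defaults to one representative value per effect bin.
#' @param replicates Replicates per condition per timepoint (>= 2).
#' @param timepoints Number of reading timepoints; the screen's geometry
#'   uses 6 (19, 24, 48, 72, 120, 144 h).
#' @param noise_sd Reading noise SD (> 0).
#' @param seed Integer seed; fully determines the output.
#' @param noise "gaussian" (default) or "exact".
#' @return List with \code{readings} (data frame \code{condition},
#'   \code{sirna_id}, \code{replicate}, \code{timepoint_h}, \code{reading})
#'   and \code{truth} (\code{sim_truth} with \code{planted_effects} and
#'   \code{planted_bins}).
#' @export
simulate_screen <- function(n_sirnas = 181, bin_centers = c(1.2, 0.65, 0.35, 0.1, 0),
                            replicates = 4, timepoints = 6, noise_sd = 10,
                            seed = 1, noise = c("gaussian", "exact")) {
  noise <- match.arg(noise)
  n_sirnas <- assert_count(n_sirnas, "n_sirnas")
  replicates <- assert_count(replicates, "replicates", min = 2L)
  timepoints <- assert_count(timepoints, "timepoints")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    ox_stop("noise_sd must be > 0", "invalid_parameter")
  hours <- c(19, 24, 48, 72, 120, 144)
  tps <- if (timepoints <= 6) hours[seq_len(timepoints)] else
    c(hours, 144 + 24 * seq_len(timepoints - 6))
  ids <- sprintf("siRNA%03d", seq_len(n_sirnas))
  d <- rep_len(bin_centers, n_sirnas)
  names(d) <- ids
  conditions <- c("negative_control", ids)
  mu <- stats::setNames(c(100, 100 + d * noise_sd), conditions)
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(replicates),
                        condition = conditions, timepoint_h = tps,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$condition, rows$timepoint_h, rows$replicate), ]
    eps <- if (noise == "gaussian") {
      stats::rnorm(nrow(rows))
    } else {
      rep(exact_pattern(replicates), length.out = nrow(rows))
    }
    rows$reading <- mu[rows$condition] + noise_sd * eps
    rows$sirna_id <- ifelse(rows$condition == "negative_control", "",
                            rows$condition)
    rows <- rows[, c("condition", "sirna_id", "replicate", "timepoint_h",
                     "reading")]
    rownames(rows) <- NULL
    list(readings = rows,
         truth = new_truth(seed, planted_effects = d,
                           planted_bins = stats::setNames(classify_effect(d),
                                                          ids)))
  })
}

# accessions look like PREFIX_######.# ; version ignored by parsers
make_accession <- function(prefix, num, version = 1L) {
  sprintf("%s_%06d.%d", prefix, num, version)
}

#' Simulate BLAST tabular hits and a gene annotation table
#'
#' Builds a gene pool with a biotype mix, plants one best hit per query
#' (minimum E-value, allowed RefSeq-style prefix, valid Entrez annotation)
#' and adds decoys that each violate at least one hit-reduction rule:
#' disallowed accession prefix, missing annotation row, empty Entrez field,
#' or a strictly higher E-value (by >= 1 order of magnitude, so the planted
#' best is never tied with a decoy). E-values are log-uniform in
#' [1e-30, 1e-2].
#'
#' @param n_genes Size of the gene pool.
#' @param biotype_mix Named proportions over the four biotypes (must sum
#'   to 1).
#' @param n_queries Number of siRNA queries (<= n_genes; targets sampled
#'   without replacement).
#' @param decoys_per_query Decoy hits added per query.
#' @param seed Integer seed.
#' @return List with \code{hits} (outfmt-6 data frame),
#'   \code{annotation} (accession/entrez_id/symbol/biotype data frame) and
#'   \code{truth} (\code{planted_targets}: query -> entrez;
#'   \code{planted_symbols}; \code{planted_biotype_tally}).
#' @export
simulate_hits_and_annotation <- function(n_genes = 500,
                                         biotype_mix = c("protein coding" = 0.9,
                                                         "lncRNA" = 0.06,
                                                         "pseudogene" = 0.03,
                                                         "TEC" = 0.01),
                                         n_queries = 167,
                                         decoys_per_query = 3, seed = 1) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_queries <- assert_count(n_queries, "n_queries")
  decoys_per_query <- assert_count(decoys_per_query, "decoys_per_query",
                                   min = 0L)
  if (!setequal(names(biotype_mix), BIOTYPES) ||
      abs(sum(biotype_mix) - 1) > 1e-8)
    ox_stop("biotype_mix must be named over the four biotypes and sum to 1",
            "invalid_parameter")
  if (n_queries > n_genes)
    ox_stop("n_queries must not exceed n_genes", "invalid_parameter")
  with_seed(seed, {
    biotype <- sample(BIOTYPES, n_genes, replace = TRUE,
                      prob = biotype_mix[BIOTYPES])
    entrez <- 100000L + seq_len(n_genes)
    symbol <- sprintf("GENE%04d", seq_len(n_genes))
    # transcript-level accessions: NM for coding, NR otherwise
    prefix <- ifelse(biotype == "protein coding", "NM", "NR")
    accession <- make_accession(prefix, seq_len(n_genes))
    ann <- data.frame(accession = strip_version(accession),
                      entrez_id = as.character(entrez), symbol = symbol,
                      biotype = biotype, stringsAsFactors = FALSE)
    queries <- sprintf("query%03d", seq_len(n_queries))
    target_idx <- sample.int(n_genes, n_queries)
    best_e <- 10^stats::runif(n_queries, -30, -6)
    blast_row <- function(q, acc, e) {
      data.frame(qseqid = q, sseqid = acc, pident = 100, length = 19,
                 mismatch = 0, gapopen = 0, qstart = 1, qend = 19,
                 sstart = 1, send = 19, evalue = e,
                 bitscore = round(-log10(e) * 2, 1),
                 stringsAsFactors = FALSE)
    }
    rows <- vector("list", n_queries * (1L + decoys_per_query))
    extra_ann <- list()
    r <- 0L
    for (i in seq_len(n_queries)) {
      r <- r + 1L
      rows[[r]] <- blast_row(queries[i], accession[target_idx[i]], best_e[i])
      if (decoys_per_query > 0) for (j in seq_len(decoys_per_query)) {
        # decoy E strictly >= 10x the planted best
        e <- best_e[i] * 10^stats::runif(1, 1, 4)
        kind <- (j - 1L) %% 3L
        if (kind == 0L) {
          # disallowed prefix (genomic region accession), annotated or not
          acc <- make_accession("NG", 900000L + i * 10L + j)
        } else if (kind == 1L) {
          # allowed prefix but no annotation row at all
          acc <- make_accession("XM", 800000L + i * 10L + j)
        } else {
          # allowed prefix, annotation row present but Entrez empty
          acc <- make_accession("XR", 700000L + i * 10L + j)
          extra_ann[[length(extra_ann) + 1L]] <-
            data.frame(accession = strip_version(acc), entrez_id = "",
                       symbol = sprintf("LOC%06d", 700000L + i * 10L + j),
                       biotype = "TEC", stringsAsFactors = FALSE)
        }
        r <- r + 1L
        rows[[r]] <- blast_row(queries[i], acc, e)
      }
    }
    hits <- do.call(rbind, rows)
    rownames(hits) <- NULL
    ann <- rbind(ann, do.call(rbind, extra_ann))
    rownames(ann) <- NULL
    planted_entrez <- stats::setNames(entrez[target_idx], queries)
    tally <- table(factor(biotype[target_idx], levels = BIOTYPES))
    list(hits = hits, annotation = ann,
         truth = new_truth(seed,
                           planted_targets = planted_entrez,
                           planted_symbols = stats::setNames(symbol[target_idx],
                                                             queries),
                           planted_biotype_tally =
                             stats::setNames(as.integer(tally), BIOTYPES)))
  })
}

#' Simulate a scored interactome with planted connected modules
#'
#' Plants modules whose internal edges (each unordered pair drawn with
#' probability \code{p_within}) score in the very-high-confidence tier
#' (900 up to the range maximum); with \code{p_within = 1} each module is a
#' clique and hence connected at the high-score threshold. Background
#' nodes attach sparsely (one edge each, to a random earlier node) at
#' low scores (range minimum up to 400). Each unordered pair appears once.
#'
#' @param module_sizes Integer vector of planted module sizes.
#' @param n_background Number of sparse background nodes.
#' @param score_range Integer interval within [41, 998].
#' @param p_within Probability of each within-module edge.
#' @param seed Integer seed.
#' @param node_pool Optional character vector to draw module node names
#'   from (e.g. catalog gene symbols); background nodes are always
#'   generated.
#' @return List with \code{interactions} (data frame \code{protein1},
#'   \code{protein2}, \code{combined_score}) and \code{truth}
#'   (\code{planted_modules}: list of node-name vectors).
#' @export
simulate_interactome <- function(module_sizes = c(20, 8, 5),
                                 n_background = 50,
                                 score_range = c(41, 998), p_within = 1,
                                 seed = 1, node_pool = NULL) {
  if (length(score_range) != 2 || score_range[1] < SCORE_MIN ||
      score_range[2] > SCORE_MAX || score_range[1] > score_range[2])
    ox_stop("score_range must lie within [41, 998]", "invalid_parameter")
  if (p_within < 0 || p_within > 1)
    ox_stop("p_within must be a probability", "invalid_parameter")
  n_mod <- sum(module_sizes)
  with_seed(seed, {
    mod_nodes <- if (is.null(node_pool)) {
      sprintf("TGT%04d", seq_len(n_mod))
    } else {
      if (length(node_pool) < n_mod)
        ox_stop("node_pool smaller than total module size",
                "invalid_parameter")
      sample(node_pool, n_mod)
    }
    bg_nodes <- sprintf("BG%04d", seq_len(n_background))
    modules <- split(mod_nodes, rep(seq_along(module_sizes), module_sizes))
    modules <- lapply(modules, sort)
    hi_lo <- max(score_range[1], min(900, score_range[2]))
    hi_hi <- score_range[2]
    lo_hi <- max(score_range[1], min(400, score_range[2]))
    edges <- list()
    for (m in modules) {
      if (length(m) < 2) next
      pairs <- utils::combn(m, 2)
      keep <- stats::runif(ncol(pairs)) < p_within
      if (any(keep))
        edges[[length(edges) + 1L]] <-
          data.frame(protein1 = pairs[1, keep], protein2 = pairs[2, keep],
                     combined_score = sample(hi_lo:hi_hi, sum(keep),
                                             replace = TRUE),
                     stringsAsFactors = FALSE)
    }
    # sparse low-score background attachment
    all_prior <- c(mod_nodes, bg_nodes)
    if (n_background > 0) {
      partners <- vapply(seq_len(n_background), function(i) {
        pool <- setdiff(all_prior, bg_nodes[i])
        sample(pool, 1)
      }, "")
      edges[[length(edges) + 1L]] <-
        data.frame(protein1 = bg_nodes, protein2 = partners,
                   combined_score = sample(score_range[1]:lo_hi,
                                           n_background, replace = TRUE),
                   stringsAsFactors = FALSE)
    }
    tab <- if (length(edges)) do.call(rbind, edges) else
      data.frame(protein1 = character(), protein2 = character(),
                 combined_score = integer(), stringsAsFactors = FALSE)
    # enforce unordered-pair uniqueness
    a <- pmin(tab$protein1, tab$protein2)
    b <- pmax(tab$protein1, tab$protein2)
    tab$protein1 <- a; tab$protein2 <- b
    tab <- tab[!duplicated(paste(a, b, sep = "\r")), , drop = FALSE]
    tab <- tab[order(tab$protein1, tab$protein2), , drop = FALSE]
    rownames(tab) <- NULL
    list(interactions = tab,
         truth = new_truth(seed, planted_modules = unname(modules)))
  })
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' The planted set shares exactly \code{planted_set_overlap} genes with the
#' query; every other set is a uniform draw from the universe, so its
#' overlap with the query is hypergeometric-random.
#'
#' @param universe_size Number of genes in the universe.
#' @param n_sets Number of gene sets (>= 1; the first is the planted one).
#' @param set_size_range Integer interval of set sizes.
#' @param planted_set_overlap Genes shared between planted set and query.
#' @param query_size Query gene-list size.
#' @param seed Integer seed.
#' @param query_genes Optional explicit query gene vector (its length
#'   overrides \code{query_size}; the universe is extended to contain it).
#' @return List with \code{collection} (as [read_gmt()] returns),
#'   \code{query}, \code{universe} and \code{truth}
#'   (\code{planted_set = "SET0001"}, \code{planted_overlap}).
#' @export
simulate_genesets <- function(universe_size = 2000, n_sets = 50,
                              set_size_range = c(20, 80),
                              planted_set_overlap = 15, query_size = 40,
                              seed = 1, query_genes = NULL) {
  universe_size <- assert_count(universe_size, "universe_size")
  n_sets <- assert_count(n_sets, "n_sets")
  with_seed(seed, {
    universe <- sprintf("g%05d", seq_len(universe_size))
    if (is.null(query_genes)) {
      query <- sample(universe, query_size)
    } else {
      query <- unique(as.character(query_genes))
      universe <- unique(c(universe, query))
    }
    if (planted_set_overlap > length(query))
      ox_stop("planted_set_overlap exceeds query size", "invalid_parameter")
    sizes <- sample(set_size_range[1]:set_size_range[2], n_sets,
                    replace = TRUE)
    sizes[1] <- max(sizes[1], planted_set_overlap)
    ids <- sprintf("SET%04d", seq_len(n_sets))
    planted_genes <- c(if (planted_set_overlap > 0)
                         sample(query, planted_set_overlap),
                       sample(setdiff(universe, query),
                              sizes[1] - planted_set_overlap))
    sets <- vector("list", n_sets)
    sets[[1]] <- list(set_id = ids[1], name = "planted enriched set",
                      source = "synthetic", genes = sort(planted_genes))
    for (i in seq_len(n_sets)[-1]) {
      sets[[i]] <- list(set_id = ids[i],
                        name = sprintf("background set %d", i),
                        source = "synthetic",
                        genes = sort(sample(universe, sizes[i])))
    }
    names(sets) <- ids
    list(collection = sets, query = query, universe = universe,
         truth = new_truth(seed, planted_set = ids[1],
                           planted_overlap = planted_set_overlap))
  })
}

#' Simulate drug-target tables in two database dialects
#'
#' Plants exactly \code{n_common_drugs} approved drugs targeting genes in
#' both gene lists within the DB-dialect table, and exactly
#' \code{n_cross_db_common} approved drugs whose normalized names appear in
#' both the DB- and TTD-dialect tables. All other drugs target genes of
#' one list only and carry names unique to their database, so the planted
#' counts are the exact intersection sizes.
#'
#' @param gene_listA,gene_listB Disjoint gene lists (e.g. targets and
#'   first interactors).
#' @param n_common_drugs Approved drugs targeting both lists within DB.
#' @param n_cross_db_common Approved drugs shared by name across DB and
#'   TTD.
#' @param n_private_per_list Additional drugs private to each list in each
#'   database.
#' @param approved_fraction Fraction of the private drugs that are
#'   approved (planted common drugs are always approved); the TTD
#'   remainder splits between patented and other.
#' @param seed Integer seed.
#' @return List with \code{db} and \code{ttd} tables (dialect schemas) and
#'   \code{truth} (\code{planted_drug_overlaps}: named counts).
#' @export
simulate_drug_tables <- function(gene_listA, gene_listB, n_common_drugs = 5,
                                 n_cross_db_common = 3,
                                 n_private_per_list = 10,
                                 approved_fraction = 0.6, seed = 1) {
  if (length(intersect(gene_listA, gene_listB)))
    ox_stop("gene lists must be disjoint", "invalid_parameter")
  if (approved_fraction < 0 || approved_fraction > 1)
    ox_stop("approved_fraction must be a proportion", "invalid_parameter")
  if (n_common_drugs > 0 && (length(gene_listA) == 0 ||
                             length(gene_listB) == 0))
    ox_stop("both gene lists must be non-empty to plant common drugs",
            "invalid_parameter")
  with_seed(seed, {
    db_rows <- list(); ttd_rows <- list()
    drug_no <- 0L
    nxt <- function() {
      drug_no <<- drug_no + 1L
      drug_no
    }
    db_row <- function(id, name, group, genes)
      data.frame(drug_id = id, name = name, group = group, gene = genes,
                 stringsAsFactors = FALSE)
    ttd_row <- function(code, name, status, genes)
      data.frame(drug_code = code, name = name, status = status,
                 gene = genes, stringsAsFactors = FALSE)
    pick <- function(pool) sample(pool, 1)
    # planted DB drugs common to both lists (approved, one gene from each)
    for (i in seq_len(n_common_drugs)) {
      k <- nxt()
      db_rows[[length(db_rows) + 1L]] <-
        db_row(sprintf("DB%05d", k), sprintf("drug common %03d", k),
               "approved", c(pick(gene_listA), pick(gene_listB)))
    }
    # planted cross-database drugs: same name in DB and TTD, approved,
    # each targeting one list only (half A, half B)
    for (i in seq_len(n_cross_db_common)) {
      k <- nxt()
      gene <- if (i %% 2 == 1) pick(gene_listA) else pick(gene_listB)
      nm <- sprintf("Drug Shared %03d", k)
      db_rows[[length(db_rows) + 1L]] <-
        db_row(sprintf("DB%05d", k), nm, "approved", gene)
      ttd_rows[[length(ttd_rows) + 1L]] <-
        ttd_row(sprintf("D0X%03d", k), toupper(nm), "approved", gene)
    }
    # private drugs per list per database
    statuses <- function(n, ttd = FALSE) {
      n_app <- round(approved_fraction * n)
      rest <- n - n_app
      if (ttd) c(rep("approved", n_app),
                 rep(c("patented", "investigative"), length.out = rest))
      else c(rep("approved", n_app), rep("experimental", rest))
    }
    for (lst in list(gene_listA, gene_listB)) {
      if (length(lst) == 0) next
      st_db <- statuses(n_private_per_list)
      st_ttd <- statuses(n_private_per_list, ttd = TRUE)
      for (i in seq_len(n_private_per_list)) {
        k <- nxt()
        db_rows[[length(db_rows) + 1L]] <-
          db_row(sprintf("DB%05d", k), sprintf("db private %03d", k),
                 st_db[i], pick(lst))
        k <- nxt()
        ttd_rows[[length(ttd_rows) + 1L]] <-
          ttd_row(sprintf("D0X%03d", k), sprintf("ttd private %03d", k),
                  st_ttd[i], pick(lst))
      }
    }
    db <- do.call(rbind, db_rows)
    ttd <- if (length(ttd_rows)) do.call(rbind, ttd_rows) else
      data.frame(drug_code = character(), name = character(),
                 status = character(), gene = character(),
                 stringsAsFactors = FALSE)
    rownames(db) <- rownames(ttd) <- NULL
    list(db = db, ttd = ttd,
         truth = new_truth(seed, planted_drug_overlaps =
                             c(db_common_approved = n_common_drugs,
                               cross_db_common = n_cross_db_common)))
  })
}

#' Write a simulated world to disk
#'
#' Serializes the outputs of the five generators into the plain-text file
#' formats the pipeline readers consume, plus a truth JSON.
#'
#' @param sim Named list holding any of \code{readings}, \code{hits},
#'   \code{annotation}, \code{interactions}, \code{collection},
#'   \code{query}, \code{db}, \code{ttd}, \code{truth}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- function(f) file.path(dir, f)
  if (!is.null(sim$readings)) {
    write_csv(sim$readings, p("plate_readings.csv"))
    paths["readings"] <- p("plate_readings.csv")
  }
  if (!is.null(sim$hits)) {
    utils::write.table(sim$hits, p("blast_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths["hits"] <- p("blast_hits.tsv")
  }
  if (!is.null(sim$annotation)) {
    write_tsv(sim$annotation, p("annotation.tsv"))
    paths["annotation"] <- p("annotation.tsv")
  }
  if (!is.null(sim$interactions)) {
    write_tsv(sim$interactions, p("interactions.tsv"))
    paths["interactions"] <- p("interactions.tsv")
  }
  if (!is.null(sim$collection)) {
    write_gmt(sim$collection, p("genesets.gmt"))
    paths["collection"] <- p("genesets.gmt")
  }
  if (!is.null(sim$query)) {
    writeLines(sim$query, p("query_genes.txt"))
    paths["query"] <- p("query_genes.txt")
  }
  if (!is.null(sim$db)) {
    write_tsv(sim$db, p("drugs_db.tsv"))
    paths["db"] <- p("drugs_db.tsv")
  }
  if (!is.null(sim$ttd)) {
    write_tsv(sim$ttd, p("drugs_ttd.tsv"))
    paths["ttd"] <- p("drugs_ttd.tsv")
  }
  if (!is.null(sim$truth)) {
    tr <- sim$truth
    tr_out <- lapply(unclass(tr), function(v)
      if (is.list(v)) lapply(v, as.vector) else as.vector(v))
    jsonlite::write_json(tr_out, p("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    paths["truth"] <- p("truth.json")
  }
  invisible(paths)
}
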