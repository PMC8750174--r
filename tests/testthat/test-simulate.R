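test_that("simulate_screen reproduces the screen geometry and is seed-deterministic", {
  s <- simulate_screen(n_sirnas = 181, replicates = 4, timepoints = 6,
                       noise_sd = 10, seed = 5)
  r <- s$readings
  expect_equal(length(unique(r$condition)), 182)  # 181 siRNAs + control
  expect_equal(sort(unique(r$timepoint_h)), c(19, 24, 48, 72, 120, 144))
  per <- table(r$condition, r$timepoint_h)
  expect_true(all(per == 4))  # four replicates per siRNA per timepoint
  expect_false(any(duplicated(r[, c("condition", "replicate", "timepoint_h")])))
  s2 <- simulate_screen(n_sirnas = 181, replicates = 4, timepoints = 6,
                        noise_sd = 10, seed = 5)
  expect_identical(s$readings, s2$readings)
  s3 <- simulate_screen(n_sirnas = 181, replicates = 4, timepoints = 6,
                        noise_sd = 10, seed = 6)
  expect_false(identical(s$readings, s3$readings))
  expect_error(simulate_screen(n_sirnas = 0), class = "invalid_parameter")
  expect_error(simulate_screen(noise_sd = 0), class = "invalid_parameter")
})

test_that("exact-noise mode realizes the zero-noise limit: planted deltas and bins recovered exactly", {
  s <- simulate_screen(n_sirnas = 20, replicates = 4, timepoints = 3,
                       noise_sd = 7, seed = 9, noise = "exact")
  eff <- screen_effects(s$readings, "negative_control")
  planted <- s$truth$planted_effects[eff$sirna_id]
  expect_equal(unname(eff$delta), unname(planted), tolerance = 1e-9)
  expect_equal(unname(eff$bin),
               unname(s$truth$planted_bins[eff$sirna_id]))
  counts <- summarize_screen(eff, 19)
  expect_equal(unname(counts),
               as.integer(table(factor(s$truth$planted_bins,
                                       levels = names(counts)))))
})

test_that("simulated hit tables round-trip through the reducer to the planted catalog", {
  for (seed in c(1, 2)) {
    h <- simulate_hits_and_annotation(n_genes = 80, n_queries = 30,
                                      decoys_per_query = 3, seed = seed)
    cat_ <- suppressMessages(reduce_hits(h$hits, h$annotation))
    got <- setNames(cat_$per_query$entrez_id, cat_$per_query$query_id)
    expect_equal(got[names(h$truth$planted_targets)],
                 h$truth$planted_targets)
    expect_equal(nrow(cat_$per_query), 30)  # exactly one surviving hit each
    expect_equal(sum(cat_$biotype_tally), length(cat_$unique_genes))
    tally <- h$truth$planted_biotype_tally
    expect_equal(cat_$biotype_tally[names(cat_$biotype_tally)],
                 tally[tally > 0][names(cat_$biotype_tally)])
  }
  # no decoys: every generated hit survives reduction
  h0 <- simulate_hits_and_annotation(n_genes = 40, n_queries = 10,
                                     decoys_per_query = 0, seed = 3)
  cat0 <- suppressMessages(reduce_hits(h0$hits, h0$annotation))
  expect_equal(nrow(cat0$per_query), nrow(h0$hits))
  expect_error(simulate_hits_and_annotation(biotype_mix = c("protein coding" = 0.5,
                                                            "lncRNA" = 0.2,
                                                            "pseudogene" = 0.2,
                                                            "TEC" = 0.2)),
               class = "invalid_parameter")
})

test_that("simulated interactomes plant connected modules and never duplicate pairs", {
  si <- simulate_interactome(module_sizes = c(12, 6, 4), n_background = 40,
                             p_within = 1, seed = 4)
  tab <- si$interactions
  key <- paste(pmin(tab$protein1, tab$protein2),
               pmax(tab$protein1, tab$protein2))
  expect_false(any(duplicated(key)))
  expect_true(all(tab$combined_score >= 41 & tab$combined_score <= 998))
  # LCC at the very-high threshold is the largest planted module
  edges <- load_interactions(tab, min_score = 900)
  lcc <- unionfind_lcc(edges)
  expect_identical(lcc, sort(si$truth$planted_modules[[1]]))
  # p_within = 0: no module edges, so nothing clusters at the threshold
  si0 <- simulate_interactome(module_sizes = c(10, 5), n_background = 20,
                              p_within = 0, seed = 4)
  e0 <- load_interactions(si0$interactions, min_score = 900)
  expect_lte(length(largest_connected_component(e0)), 2)
  expect_error(simulate_interactome(score_range = c(41, 1000)),
               class = "invalid_parameter")
})

test_that("simulated gene sets put the planted set at the minimum p-value and GMT round-trips", {
  gs <- simulate_genesets(universe_size = 1000, n_sets = 40,
                          planted_set_overlap = 15, query_size = 40, seed = 6)
  ora <- run_ora(gs$query, gs$collection)
  expect_equal(ora$set_id[1], gs$truth$planted_set)
  expect_true(ora$significant[1])
  expect_equal(min(ora$adj_p), ora$adj_p[1])
  # zero planted overlap: planted set never flagged
  gs0 <- simulate_genesets(universe_size = 1000, n_sets = 40,
                           planted_set_overlap = 0, query_size = 40, seed = 6)
  ora0 <- run_ora(gs0$query, gs0$collection)
  expect_false(ora0$significant[ora0$set_id == gs0$truth$planted_set])
  # GMT identity: parse(write(x)) = x
  tmp <- tempfile(fileext = ".gmt")
  write_gmt(gs$collection, tmp)
  back <- read_gmt(tmp, source = "synthetic")
  expect_equal(back, gs$collection)
})

test_that("simulated drug tables plant exact intersection counts", {
  A <- sprintf("A%02d", 1:8); B <- sprintf("B%02d", 1:8)
  dr <- simulate_drug_tables(A, B, n_common_drugs = 4, n_cross_db_common = 3,
                             approved_fraction = 0.5, seed = 7)
  db <- load_drug_table(dr$db, "DB")
  ttd <- load_drug_table(dr$ttd, "TTD")
  rep_ <- drug_mining_report(A, B, db, ttd)
  expect_equal(nrow(rep_$db_common),
               unname(dr$truth$planted_drug_overlaps["db_common_approved"]))
  expect_equal(nrow(rep_$cross_db_common),
               unname(dr$truth$planted_drug_overlaps["cross_db_common"]))
  # n_common_drugs = 0 gives an empty intersection
  dr0 <- simulate_drug_tables(A, B, n_common_drugs = 0,
                              n_cross_db_common = 0, seed = 7)
  rep0 <- drug_mining_report(A, B, load_drug_table(dr0$db, "DB"),
                             load_drug_table(dr0$ttd, "TTD"))
  expect_equal(nrow(rep0$db_common), 0)
  # approved_fraction = 1: approved subset is the full drug set
  dr1 <- simulate_drug_tables(A, B, n_common_drugs = 2,
                              n_cross_db_common = 1,
                              approved_fraction = 1, seed = 7)
  db1 <- load_drug_table(dr1$db, "DB")
  hits1 <- query_drugs(c(A, B), db1)
  expect_equal(hits1$n_approved, hits1$n_drugs)
  expect_error(simulate_drug_tables(A, c(A[1], B), seed = 1),
               class = "invalid_parameter")
})

test_that("written simulation files are byte-identical across reruns and parse cleanly", {
  make <- function(dir) {
    s <- simulate_screen(n_sirnas = 6, replicates = 3, timepoints = 2,
                         noise_sd = 5, seed = 11)
    h <- simulate_hits_and_annotation(n_genes = 30, n_queries = 8,
                                      decoys_per_query = 2, seed = 11)
    si <- simulate_interactome(module_sizes = c(6, 4), n_background = 10,
                               seed = 11)
    gs <- simulate_genesets(universe_size = 200, n_sets = 10,
                            planted_set_overlap = 5, query_size = 15,
                            seed = 11)
    dr <- simulate_drug_tables(c("A1", "A2"), c("B1", "B2"),
                               n_common_drugs = 1, n_cross_db_common = 1,
                               seed = 11)
    write_simulation(list(readings = s$readings, hits = h$hits,
                          annotation = h$annotation,
                          interactions = si$interactions,
                          collection = gs$collection, query = gs$query,
                          db = dr$db, ttd = dr$ttd, truth = s$truth), dir)
  }
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  p1 <- make(d1); p2 <- make(d2)
  for (nm in names(p1))
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
                     readBin(p2[[nm]], "raw", file.size(p2[[nm]])),
                     label = nm)
  # every generated file parses by its pipeline reader without warnings
  expect_no_warning(utils::read.csv(p1[["readings"]]))
  expect_no_warning(parse_blast_tabular(p1[["hits"]]))
  expect_no_warning(load_interactions(p1[["interactions"]]))
  expect_no_warning(read_gmt(p1[["collection"]]))
  expect_no_warning(load_drug_table(p1[["db"]], "DB"))
  expect_no_warning(load_drug_table(p1[["ttd"]], "TTD"))
  unlink(c(d1, d2), recursive = TRUE)
})
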