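make_hit <- function(q, acc, e) {
  data.frame(qseqid = q, sseqid = acc, pident = 100, length = 19,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 19, sstart = 1,
             send = 19, evalue = e, bitscore = 40, stringsAsFactors = FALSE)
}

test_that("parse_blast_tabular handles empty, valid and malformed input", {
  f <- tempfile()
  writeLines(character(), f)
  expect_equal(nrow(parse_blast_tabular(f)), 0)
  writeLines("q1\tNM_000546.6\t100.0\t19\t0\t0\t1\t19\t100\t118\t1e-05\t38.2", f)
  hits <- parse_blast_tabular(f)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$evalue, 1e-05)  # scientific notation parsed as real
  writeLines("q1\tNM_1\t100\t19\t0\t0\t1\t19\t1\t19\t1e-05", f)  # 11 columns
  expect_error(parse_blast_tabular(f), "line", class = "parse_error")
  unlink(f)
})

test_that("accession prefix whitelist keeps NM-style and drops NG-style hits, idempotently", {
  hits <- rbind(make_hit("q1", "NM_000546.6", 1e-6),
                make_hit("q1", "NG_017013.2", 1e-8),
                make_hit("q2", "XP_011520.1", 1e-4),
                make_hit("q2", "AC_000001.1", 1e-9))
  kept <- suppressMessages(filter_accession_prefix(hits))
  expect_equal(kept$sseqid, c("NM_000546.6", "XP_011520.1"))
  expect_identical(suppressMessages(filter_accession_prefix(kept)), kept)
  all_bad <- rbind(make_hit("q1", "NG_1.1", 1e-6), make_hit("q1", "NC_2.1", 1e-6))
  expect_equal(nrow(suppressMessages(filter_accession_prefix(all_bad))), 0)
})

test_that("best_hits_per_query keeps all minimum-E ties and matches an exhaustive scan", {
  hits <- rbind(make_hit("q1", "NM_000001.1", 1e-5),
                make_hit("q1", "NM_000002.1", 1e-5),
                make_hit("q1", "NM_000003.1", 1e-3))
  best <- best_hits_per_query(hits)
  expect_equal(sort(best$sseqid), c("NM_000001.1", "NM_000002.1"))
  one <- make_hit("q9", "NM_000009.1", 1e-2)
  expect_equal(best_hits_per_query(one)$sseqid, one$sseqid)
  # oracle: per-query minimum via full scan on a random table
  set.seed(21)
  rnd <- do.call(rbind, lapply(1:60, function(i)
    make_hit(sample(paste0("q", 1:8), 1),
             sprintf("NM_%06d.1", i), 10^runif(1, -20, -2))))
  best_rnd <- best_hits_per_query(rnd)
  for (q in unique(rnd$qseqid)) {
    expect_equal(unique(best_rnd$evalue[best_rnd$qseqid == q]),
                 min(rnd$evalue[rnd$qseqid == q]))
  }
})

test_that("annotation pruning removes unannotated and Entrez-less hits; versions are ignored", {
  ann <- data.frame(accession = c("NM_000546", "NM_000111"),
                    entrez_id = c("7157", ""),
                    symbol = c("TP53", "LOC1"),
                    biotype = c("protein coding", "TEC"),
                    stringsAsFactors = FALSE)
  hits <- rbind(make_hit("q1", "NM_000546.6", 1e-6),  # annotated
                make_hit("q1", "NM_000999.1", 1e-6),  # no annotation row
                make_hit("q1", "NM_000111.2", 1e-6))  # empty Entrez
  out <- suppressMessages(annotate_and_prune(hits, ann))
  expect_equal(nrow(out), 1)
  expect_equal(out$entrez_id, 7157L)
  expect_equal(out$symbol, "TP53")
})

test_that("symbol deduplication is per-query, case-insensitive, min-E and idempotent", {
  ann <- data.frame(accession = c("NM_000001", "NM_000002", "NM_000003"),
                    entrez_id = c("11", "11", "22"),
                    symbol = c("ABC1", "abc1", "XYZ2"),
                    biotype = rep("protein coding", 3),
                    stringsAsFactors = FALSE)
  hits <- rbind(make_hit("q1", "NM_000001.1", 1e-6),
                make_hit("q1", "NM_000002.1", 1e-4),  # same symbol, higher E
                make_hit("q1", "NM_000003.1", 1e-5),
                make_hit("q2", "NM_000002.1", 1e-4))  # other query untouched
  annotated <- suppressMessages(annotate_and_prune(hits, ann))
  dd <- dedupe_symbols(annotated)
  q1 <- dd[dd$qseqid == "q1", ]
  expect_equal(nrow(q1), 2)
  expect_equal(q1$evalue[tolower(q1$symbol) == "abc1"], 1e-6)
  expect_equal(nrow(dd[dd$qseqid == "q2", ]), 1)
  expect_identical(dedupe_symbols(dd), dd)
})

test_that("catalog tallies unique genes once regardless of query multiplicity", {
  ann <- data.frame(accession = c("NM_000001", "NR_000002"),
                    entrez_id = c("11", "22"),
                    symbol = c("ABC1", "LNC2"),
                    biotype = c("protein coding", "lncRNA"),
                    stringsAsFactors = FALSE)
  hits <- rbind(make_hit("q1", "NM_000001.1", 1e-6),
                make_hit("q2", "NM_000001.2", 1e-7),  # same gene, second query
                make_hit("q2", "NR_000002.1", 1e-7))
  cat_ <- suppressMessages(reduce_hits(hits, ann))
  expect_equal(length(cat_$unique_genes), 2)
  expect_equal(sum(cat_$biotype_tally), length(cat_$unique_genes))
  expect_equal(unname(cat_$biotype_tally[c("protein coding", "lncRNA")]),
               c(1L, 1L))
})

test_that("prefix filtering and best-hit selection commute on generated hit tables", {
  for (seed in c(31, 32)) {
    h <- simulate_hits_and_annotation(n_genes = 50, n_queries = 15,
                                      decoys_per_query = 3, seed = seed)
    a <- suppressMessages(best_hits_per_query(filter_accession_prefix(h$hits)))
    b <- suppressMessages(filter_accession_prefix(best_hits_per_query(h$hits)))
    key <- function(x) x[order(x$qseqid, x$sseqid), c("qseqid", "sseqid", "evalue")]
    expect_equal(key(a), key(b), ignore_attr = TRUE)
  }
})

test_that("cross_annotate intersects the catalog with a term gene set", {
  ann <- data.frame(accession = sprintf("NM_%06d", 1:4),
                    entrez_id = as.character(1:4),
                    symbol = paste0("G", 1:4),
                    biotype = rep("protein coding", 4),
                    stringsAsFactors = FALSE)
  hits <- do.call(rbind, lapply(1:4, function(i)
    make_hit(paste0("q", i), sprintf("NM_%06d.1", i), 1e-6)))
  cat_ <- suppressMessages(reduce_hits(hits, ann))
  expect_equal(cross_annotate(cat_, integer())$count, 0)
  expect_equal(cross_annotate(cat_, 1:10)$members, 1:4)
  # oracle: nested-loop membership count
  term <- c(2L, 4L, 9L)
  brute <- sum(vapply(cat_$unique_genes, function(g) g %in% term, TRUE))
  expect_equal(cross_annotate(cat_, term, "GO:0006979")$count, brute)
})
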