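set_list <- function(...) {
  sets <- list(...)
  names(sets) <- vapply(sets, `[[`, "", "set_id")
  sets
}
gs <- function(id, genes, name = id)
  list(set_id = id, name = name, source = "test", genes = genes)

test_that("hypergeometric upper tail matches enumeration and analytic points", {
  expect_equal(hypergeometric_p(0, 5, 5, 10), 1)
  # all 5 draws inside the 5-member set: exactly 1 of C(10,5)=252 draws
  expect_equal(hypergeometric_p(5, 5, 5, 10), 1 / 252)
  expect_error(hypergeometric_p(6, 5, 5, 10), class = "invalid_parameter")
  expect_error(hypergeometric_p(2, 11, 5, 10), class = "invalid_parameter")
  # enumeration oracle across all feasible (K, n, k) for N <= 12
  for (N in c(6, 9, 12)) {
    for (K in c(2, N %/% 2)) {
      for (n in c(2, N %/% 2)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeometric_p(k, K, n, N), enum_hyper_p(k, K, n, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
  # decreasing in k for fixed (K, n, N)
  ps <- vapply(0:5, hypergeometric_p, 0, K = 6, n = 5, N = 12)
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment equals the hand step-up and preserves input order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(61)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stepup_bh_adjust(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # rejection set at alpha equals the classic step-up rejection set
    for (alpha in c(0.05, 0.2))
      expect_equal(adj <= alpha, stepup_bh_reject(p, alpha))
  }
})

test_that("run_ora tests every set, defaults the universe to the annotation union", {
  coll <- set_list(gs("S1", c("a", "b", "c", "d")),
                   gs("S2", c("c", "d", "e", "f")),
                   gs("S3", c("g", "h")))
  ora <- run_ora(c("a", "b", "c"), coll)
  expect_equal(nrow(ora), 3)
  expect_equal(sort(unique(ora$N)), 8)  # union a..h
  expect_equal(ora$k[ora$set_id == "S1"], 3)
  expect_equal(ora$k[ora$set_id == "S3"], 0)
  expect_equal(ora$p_value[ora$set_id == "S3"], 1)
  # query disjoint from the universe: no significant sets, no error
  far <- run_ora(c("zz1", "zz2"), coll)
  expect_true(all(far$k == 0) && all(far$p_value == 1))
  expect_false(any(far$significant))
  expect_true(all(ora$adj_p >= ora$p_value))
})

test_that("ORA power to recover the planted set grows with planted overlap", {
  hits <- vapply(c(4, 15), function(ov) {
    found <- vapply(1:8, function(seed) {
      g <- simulate_genesets(universe_size = 1500, n_sets = 40,
                             planted_set_overlap = ov, query_size = 40,
                             seed = seed)
      o <- run_ora(g$query, g$collection)
      o$significant[o$set_id == g$truth$planted_set]
    }, TRUE)
    mean(found)
  }, 0)
  expect_lte(hits[1], hits[2])
  expect_equal(hits[2], 1)  # large planted overlap: always recovered
})

test_that("kappa score matches the hand 2x2 computation, is symmetric and bounded", {
  ref <- paste0("g", 1:4)
  # p_o = 0.5, p_e = 0.625 from the 2x2 table
  expect_equal(kappa_score(c("g1", "g2", "g3"), c("g1", "g2", "g4"), ref),
               -1 / 3)
  expect_equal(kappa_score(c("g1", "g2"), c("g1", "g2"), ref), 1)
  set.seed(71)
  universe <- paste0("g", 1:30)
  for (i in 1:15) {
    A <- sample(universe, sample(2:20, 1))
    B <- sample(universe, sample(2:20, 1))
    kab <- kappa_score(A, B, universe)
    expect_equal(kab, kappa_score(B, A, universe))
    expect_lte(kab, 1)
    if (!setequal(A, B)) expect_lt(kab, 1)
  }
  expect_error(kappa_score(character(), character(), universe),
               class = "undefined_kappa")
  expect_error(kappa_score(universe, universe, universe),
               class = "undefined_kappa")
  expect_error(kappa_score("zz", "g1", ref), class = "invalid_parameter")
})

test_that("term clustering groups redundant terms, picks leading terms, and ignores input order", {
  coll <- set_list(
    gs("T01", paste0("a", 1:10)),           # block 1
    gs("T02", paste0("a", c(1:9, 11))),
    gs("T03", paste0("a", 1:10)),           # identical to T01
    gs("T10", paste0("b", 1:10)),           # block 2, disjoint from block 1
    gs("T11", paste0("b", c(1:9, 11))))
  res <- data.frame(set_id = c("T01", "T02", "T03", "T10", "T11"),
                    adj_p = c(0.001, 0.01, 0.002, 0.03, 0.004),
                    significant = TRUE, stringsAsFactors = FALSE)
  cl <- cluster_terms(res, coll, kappa_threshold = 0.5)
  expect_equal(length(cl), 2)
  members <- lapply(cl, `[[`, "members")
  expect_true(list(c("T01", "T02", "T03")) %in% members ||
                any(vapply(members, setequal, TRUE, c("T01", "T02", "T03"))))
  expect_true(any(vapply(members, setequal, TRUE, c("T10", "T11"))))
  leads <- sort(vapply(cl, `[[`, "", "leading_term"))
  expect_equal(leads, c("T01", "T11"))  # minimum adj_p per group
  # permuting the input rows yields identical groups
  perm <- res[c(4, 2, 5, 1, 3), ]
  cl2 <- cluster_terms(perm, coll, kappa_threshold = 0.5)
  expect_equal(lapply(cl, `[[`, "members"), lapply(cl2, `[[`, "members"))
  # single significant term: one singleton group, itself leading
  solo <- cluster_terms(res[1, ], coll)
  expect_equal(length(solo), 1)
  expect_equal(solo[[1]]$members, "T01")
  expect_equal(solo[[1]]$leading_term, "T01")
  # identical gene sets always share a group
  two <- cluster_terms(res[c(1, 3), ], coll)
  expect_equal(length(two), 1)
  expect_equal(two[[1]]$members, c("T01", "T03"))
  # no significant terms: empty cluster list
  none <- res; none$significant <- FALSE
  expect_equal(length(cluster_terms(none, coll)), 0)
})

test_that("leading-term ties break to the lexicographically smaller set_id", {
  coll <- set_list(gs("B2", paste0("x", 1:5)), gs("A9", paste0("x", 1:5)))
  res <- data.frame(set_id = c("B2", "A9"), adj_p = c(0.01, 0.01),
                    significant = TRUE, stringsAsFactors = FALSE)
  cl <- cluster_terms(res, coll)
  expect_equal(cl[[1]]$leading_term, "A9")
})
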