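# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive route: combinatorial enumeration, the classic step-up
# procedure written out, and union-find for connected components.

# P(X >= k) by enumerating all C(N, n) draws of a size-n query from a
# universe of N genes of which the first K are set members.
enum_hyper_p <- function(k, K, n, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  members <- seq_len(K)
  hits <- apply(draws, 2, function(cols) sum(cols %in% members))
  mean(hits >= k)
}

# BH adjusted values by the textbook route: sort, p * m / i, cumulative
# minimum from the largest rank down, cap at 1, unsort.
stepup_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# classic BH rejection set at level alpha: reject the i* smallest p-values
# where i* is the largest i with p_(i) <= i * alpha / m.
stepup_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * alpha / m)
  rejected <- logical(m)
  if (length(ok)) rejected[o[seq_len(max(ok))]] <- TRUE
  rejected
}

# largest connected component via union-find over an edge data frame with
# columns node_a, node_b.
unionfind_lcc <- function(edges) {
  nodes <- unique(c(edges$node_a, edges$node_b))
  if (length(nodes) == 0) return(character())
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$node_a[i]); rb <- find(edges$node_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  comp <- split(nodes, roots)
  sort(comp[[which.max(lengths(comp))]])
}

# random scored edge table on n nodes, for LCC and threshold-sweep checks
random_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  df <- data.frame(protein1 = a[keep], protein2 = b[keep],
                   combined_score = sample(41:998, sum(keep), replace = TRUE),
                   stringsAsFactors = FALSE)
  load_interactions(df)
}

# paths to the packaged fixture reproducing the common-drug table
# (drug names and database codes in-paper; gene assignments synthetic)
table2_paths <- function() {
  list(
    db = system.file("extdata", "common_drugs_db_synthetic.tsv",
                     package = "redoxscreen"),
    ttd = system.file("extdata", "common_drugs_ttd_synthetic.tsv",
                      package = "redoxscreen"),
    targets = system.file("extdata", "target_genes_synthetic.txt",
                          package = "redoxscreen"),
    interactors = system.file("extdata", "interactor_genes_synthetic.txt",
                              package = "redoxscreen"))
}
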