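# Role-tagged protein-protein interaction networks around a target set:
# 1st/2nd-shell expansion at confidence thresholds, largest connected
# component, and summary tables in the style of STRING-based screens.

SCORE_MIN <- 41L
SCORE_MAX <- 998L

#' Load a scored interaction table
#'
#' Reads a STRING-links-like TSV (columns \code{protein1}, \code{protein2},
#' \code{combined_score}), drops edges below \code{min_score}, collapses
#' duplicate unordered pairs keeping the maximum score, and removes
#' self-loops.
#'
#' @param file Path to the interaction TSV, or a data frame with the same
#'   columns.
#' @param min_score Inclusive minimum combined score (default keeps all).
#' @return Data frame \code{node_a}, \code{node_b}, \code{score} with
#'   \code{node_a < node_b} and one row per unordered pair.
#' @export
load_interactions <- function(file, min_score = SCORE_MIN) {
  df <- if (is.character(file)) read_tsv(file) else file
  if (nrow(df) == 0L)
    return(data.frame(node_a = character(), node_b = character(),
                      score = integer(), stringsAsFactors = FALSE))
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df)))
    ox_stop("interaction table needs columns protein1, protein2, combined_score",
            "format_error")
  score <- as.integer(df$combined_score)
  if (any(is.na(score)) || any(score < SCORE_MIN) || any(score > SCORE_MAX))
    ox_stop(sprintf("combined_score outside [%d, %d]", SCORE_MIN, SCORE_MAX),
            "format_error")
  a <- as.character(df$protein1); b <- as.character(df$protein2)
  na <- pmin(a, b); nb <- pmax(a, b)
  out <- data.frame(node_a = na, node_b = nb, score = score,
                    stringsAsFactors = FALSE)
  out <- out[out$node_a != out$node_b, , drop = FALSE]
  # collapse duplicates to the maximum score
  out <- out[order(out$node_a, out$node_b, -out$score), , drop = FALSE]
  out <- out[!duplicated(paste(out$node_a, out$node_b, sep = "\r")), ,
             drop = FALSE]
  out <- out[out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a network around target genes by interaction shells
#'
#' With \code{shells = 0} the network holds only the targets and their
#' mutual edges at score >= \code{t1}. \code{shells = 1} adds 1st-shell
#' interactors: non-target nodes with at least one edge at >= \code{t1} to a
#' target. \code{shells = 2} additionally adds 2nd-shell interactors: nodes
#' (not target/shell-1) with at least one edge at >= \code{t2} to a
#' shell-1 node. The final edge set is the induced subgraph over the
#' selected nodes: edges among targets/shell-1 qualify at >= \code{t1},
#' edges touching a shell-2 node at >= \code{t2}. Thresholds are inclusive.
#'
#' @param targets Character vector of target gene identifiers.
#' @param edges Edge data frame from [load_interactions()].
#' @param shells 0, 1 or 2.
#' @param t1 Score threshold for target/1st-shell edges (default 900, very
#'   high confidence).
#' @param t2 Score threshold for 2nd-shell edges (default 900).
#' @return Object of class \code{ppi_network}: list with \code{nodes}
#'   (data frame \code{node}, \code{role} in target/shell1/shell2),
#'   \code{edges} (\code{node_a}, \code{node_b}, \code{score}) and
#'   \code{build_params}.
#' @export
expand_network <- function(targets, edges, shells = 1, t1 = 900, t2 = 900) {
  if (!shells %in% 0:2)
    ox_stop("shells must be 0, 1 or 2", "invalid_parameter")
  for (t in c(t1, t2))
    if (t < SCORE_MIN || t > SCORE_MAX)
      ox_stop(sprintf("threshold outside [%d, %d]", SCORE_MIN, SCORE_MAX),
              "invalid_parameter")
  targets <- unique(as.character(targets))
  e1 <- edges[edges$score >= t1, , drop = FALSE]
  in_t_a <- e1$node_a %in% targets
  in_t_b <- e1$node_b %in% targets
  shell1 <- character()
  if (shells >= 1) {
    shell1 <- unique(c(e1$node_b[in_t_a], e1$node_a[in_t_b]))
    shell1 <- setdiff(shell1, targets)
  }
  core <- c(targets, shell1)
  shell2 <- character()
  if (shells == 2) {
    e2 <- edges[edges$score >= t2, , drop = FALSE]
    touch1 <- unique(c(e2$node_b[e2$node_a %in% shell1],
                       e2$node_a[e2$node_b %in% shell1]))
    shell2 <- setdiff(touch1, core)
  }
  all_nodes <- c(core, shell2)
  role <- c(rep("target", length(targets)), rep("shell1", length(shell1)),
            rep("shell2", length(shell2)))
  # induced edges: core-core pairs at >= t1, shell2-touching pairs at >= t2
  in_core_a <- edges$node_a %in% core
  in_core_b <- edges$node_b %in% core
  in_all_a <- in_core_a | edges$node_a %in% shell2
  in_all_b <- in_core_b | edges$node_b %in% shell2
  thr <- ifelse(in_core_a & in_core_b, t1, t2)
  keep <- in_all_a & in_all_b & edges$score >= thr
  sub <- edges[keep, , drop = FALSE]
  sub <- sub[order(sub$node_a, sub$node_b), , drop = FALSE]
  nodes <- data.frame(node = all_nodes, role = role,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(match(nodes$role, c("target", "shell1", "shell2")),
                       nodes$node), , drop = FALSE]
  rownames(nodes) <- rownames(sub) <- NULL
  structure(list(nodes = nodes, edges = sub,
                 build_params = list(shells = shells, t1 = t1, t2 = t2)),
            class = "ppi_network")
}

# internal: igraph object over the network's nodes and edges
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("node_a", "node_b")],
                                directed = FALSE,
                                vertices = network$nodes$node)
}

#' Largest connected component of a network
#'
#' @param network A \code{ppi_network} (or a bare edge data frame with
#'   \code{node_a}, \code{node_b} columns).
#' @return Sorted character vector of the node set of a maximal connected
#'   component of greatest cardinality. Only nodes with at least one edge
#'   are considered; an edgeless network yields an empty set.
#' @export
largest_connected_component <- function(network) {
  edges <- if (inherits(network, "ppi_network")) network$edges else network
  if (nrow(edges) == 0L) return(character())
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sort(names(comp$membership)[comp$membership == big])
}

#' Summarize a network in screen-report style
#'
#' Counts only nodes with at least one interaction. Percentages are
#' relative to that total, rounded to one decimal.
#'
#' @param network A \code{ppi_network}.
#' @param targets Character vector of target genes.
#' @param flag_set Character vector of flagged genes (e.g. an
#'   oxidative-stress annotation set); may be empty.
#' @return List of class \code{ppi_summary} with \code{total_genes},
#'   \code{n_targets}, \code{pct_targets}, \code{n_interactions},
#'   \code{n_flagged}, \code{pct_flagged}, \code{lcc_size}, \code{pct_lcc}.
#' @export
summarize_network <- function(network, targets, flag_set = character()) {
  connected <- sort(unique(c(network$edges$node_a, network$edges$node_b)))
  total <- length(connected)
  n_t <- length(intersect(connected, targets))
  n_f <- length(intersect(connected, flag_set))
  lcc <- largest_connected_component(network)
  structure(list(total_genes = total,
                 n_targets = n_t, pct_targets = pct1(n_t, total),
                 n_interactions = nrow(network$edges),
                 n_flagged = n_f, pct_flagged = pct1(n_f, total),
                 lcc_size = length(lcc), pct_lcc = pct1(length(lcc), total)),
            class = "ppi_summary")
}

#' @export
print.ppi_network <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = c("target", "shell1", "shell2")))
  cat(sprintf("PPI network (shells=%d, t1=%d, t2=%d): %d nodes (%d targets, %d shell-1, %d shell-2), %d edges\n",
              x$build_params$shells, x$build_params$t1, x$build_params$t2,
              nrow(x$nodes), tab[["target"]], tab[["shell1"]],
              tab[["shell2"]], nrow(x$edges)))
  invisible(x)
}

#' @export
print.ppi_summary <- function(x, ...) {
  cat(sprintf("Total genes (>=1 interaction): %d\n", x$total_genes))
  cat(sprintf("siRNA target genes: %d (%.1f%%)\n", x$n_targets, x$pct_targets))
  cat(sprintf("Total interactions: %d\n", x$n_interactions))
  cat(sprintf("Flagged genes: %d (%.1f%%)\n", x$n_flagged, x$pct_flagged))
  cat(sprintf("LCC size: %d (%.1f%%)\n", x$lcc_size, x$pct_lcc))
  invisible(x)
}

#' Write a network as edge-list TSV plus node-role sidecar
#' @param network A \code{ppi_network}.
#' @param edges_tsv,nodes_tsv Output paths.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, edges_tsv, nodes_tsv) {
  write_tsv(network$edges, edges_tsv)
  write_tsv(network$nodes, nodes_tsv)
  invisible(c(edges_tsv, nodes_tsv))
}
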