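# Hypergeometric over-representation analysis with BH-FDR across gene-set
# collections, and kappa-score clustering of significant terms with
# leading-term selection.

#' Read a GMT gene-set file
#'
#' One set per line: \code{set_id <TAB> description <TAB> gene1 <TAB> ...}.
#'
#' @param file Path to the GMT file.
#' @param source Knowledgebase label attached to every set (default the
#'   file name).
#' @return Named list of gene sets; each element is a list with
#'   \code{set_id}, \code{name}, \code{source}, \code{genes}.
#' @export
read_gmt <- function(file, source = basename(file)) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      ox_stop("GMT line needs set_id, description and >= 1 gene",
              "parse_error")
    list(set_id = parts[1], name = parts[2], source = source,
         genes = unique(parts[-(1:2)]))
  })
  ids <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(ids))
    ox_stop("duplicate set_id in GMT collection", "parse_error")
  stats::setNames(sets, ids)
}

#' Write gene sets to a GMT file
#' @param collection List of gene sets as returned by [read_gmt()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(collection, file) {
  lines <- vapply(collection, function(s) {
    paste(c(s$set_id, s$name, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, file)
  invisible(file)
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Probability that a size-\code{n} draw from a universe of \code{N} genes
#' containing \code{K} set members captures at least \code{k} of them.
#'
#' @param k Observed overlap. @param K Set size. @param n Query size.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (K > N || n > N || k < 0 || K < 0 || n < 0)
    ox_stop("need 0 <= K, n <= N and k >= 0", "invalid_parameter")
  if (k > min(K, n))
    ox_stop("impossible configuration: k > min(K, n)", "invalid_parameter")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a query gene list
#'
#' One hypergeometric upper-tail test per set, BH-adjusted across the whole
#' collection; a set is significant when its adjusted p-value is below
#' \code{alpha}. The universe defaults to the union of all collection
#' genes ("all available annotations"); the query is intersected with the
#' universe before testing.
#'
#' @param query Character vector of query gene identifiers.
#' @param collection Gene-set list as returned by [read_gmt()].
#' @param universe Background gene vector; default union of collection
#'   genes.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param min_set_size,max_set_size Optional size filters applied before
#'   testing (defaults impose none).
#' @return Data frame of class \code{ora_result}: \code{set_id},
#'   \code{name}, \code{source}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{p_value}, \code{adj_p}, \code{significant}.
#' @export
run_ora <- function(query, collection, universe = NULL, alpha = 0.05,
                    min_set_size = 1L, max_set_size = Inf) {
  if (is.null(universe))
    universe <- unique(unlist(lapply(collection, `[[`, "genes")))
  universe <- unique(as.character(universe))
  query <- intersect(unique(as.character(query)), universe)
  N <- length(universe); n <- length(query)
  sizes <- vapply(collection, function(s)
    length(intersect(s$genes, universe)), 0L)
  collection <- collection[sizes >= min_set_size & sizes <= max_set_size]
  rows <- lapply(collection, function(s) {
    genes <- intersect(s$genes, universe)
    K <- length(genes)
    k <- length(intersect(query, genes))
    data.frame(set_id = s$set_id, name = s$name, source = s$source,
               k = k, K = K, n = n, N = N,
               p_value = hypergeometric_p(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$adj_p <- bh_adjust(out$p_value)
  out$significant <- out$adj_p < alpha
  out <- out[order(out$adj_p, out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("ORA: %d sets tested, %d significant (BH adj p < 0.05), universe %d genes, query %d genes\n",
              nrow(x), sum(x$significant), x$N[1], x$n[1]))
  NextMethod()
}

#' Cohen's kappa between two terms' gene memberships
#'
#' Chance-corrected agreement of the two membership indicator vectors over
#' a reference gene universe:
#' \code{kappa = (p_o - p_e) / (1 - p_e)} from the 2x2 contingency table.
#'
#' @param genesA,genesB Gene sets (character vectors), both subsets of
#'   \code{reference}.
#' @param reference Reference gene universe (length >= 2).
#' @return Kappa in [-1, 1]; 1 iff the sets are identical over the
#'   reference.
#' @export
kappa_score <- function(genesA, genesB, reference) {
  reference <- unique(as.character(reference))
  genesA <- unique(as.character(genesA)); genesB <- unique(as.character(genesB))
  if (length(reference) < 2L || !all(c(genesA, genesB) %in% reference))
    ox_stop("reference must contain both sets and have >= 2 genes",
            "invalid_parameter")
  n <- length(reference)
  a <- length(intersect(genesA, genesB))
  b <- length(setdiff(genesA, genesB))
  c <- length(setdiff(genesB, genesA))
  d <- n - a - b - c
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (p_e == 1)
    ox_stop("kappa undefined: expected agreement is 1 (both sets empty or both equal to the reference)",
            "undefined_kappa")
  (p_o - p_e) / (1 - p_e)
}

# kappa for clustering: identical sets always count as perfect agreement,
# even in the degenerate case where both equal the reference
cluster_kappa <- function(genesA, genesB, reference) {
  if (setequal(genesA, genesB)) return(1)
  tryCatch(kappa_score(genesA, genesB, reference),
           redoxscreen_error = function(e) -Inf)
}

#' Cluster significant terms by kappa score
#'
#' ClueGO-style grouping: each significant term seeds a candidate group
#' holding itself plus every term with kappa >= \code{kappa_threshold} to
#' it (kappa computed over the union of all significant terms' genes);
#' groups sharing more than 50% of their terms (relative to the smaller
#' group) are merged to a fixed point. Each final group's leading term is
#' its member with the smallest adjusted p-value (ties broken by
#' lexicographically smaller set_id). The procedure is deterministic and
#' input-order independent.
#'
#' @param results An \code{ora_result} data frame (only rows with
#'   \code{significant == TRUE} are used).
#' @param collection The gene-set collection the results came from.
#' @param kappa_threshold Minimum kappa to join a seed group (default 0.5).
#' @return List of class \code{term_clusters}; each element has
#'   \code{group_id}, \code{members}, \code{leading_term}. The kappa matrix
#'   over significant terms is attached as attribute \code{kappa}.
#' @export
cluster_terms <- function(results, collection, kappa_threshold = 0.5) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(structure(list(), class = "term_clusters",
                     kappa = matrix(numeric(), 0, 0)))
  ids <- sort(sig$set_id)
  genes <- lapply(collection[ids], `[[`, "genes")
  reference <- unique(unlist(genes))
  m <- length(ids)
  kmat <- matrix(1, m, m, dimnames = list(ids, ids))
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      kmat[i, j] <- kmat[j, i] <-
        cluster_kappa(genes[[i]], genes[[j]], reference)
    }
  }
  groups <- lapply(seq_len(m), function(i) sort(ids[kmat[i, ] >= kappa_threshold]))
  groups <- unique(groups)
  # fixed-point merge: smallest-group containment > 50%
  repeat {
    merged <- FALSE
    ng <- length(groups)
    if (ng > 1) {
      for (i in seq_len(ng - 1)) {
        for (j in (i + 1):ng) {
          shared <- length(intersect(groups[[i]], groups[[j]]))
          if (shared > 0.5 * min(length(groups[[i]]), length(groups[[j]]))) {
            groups[[i]] <- sort(union(groups[[i]], groups[[j]]))
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
    groups <- unique(groups)
  }
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  adj <- stats::setNames(sig$adj_p, sig$set_id)
  out <- lapply(seq_along(groups), function(g) {
    members <- groups[[g]]
    lead <- members[order(adj[members], members)][1]
    list(group_id = sprintf("G%03d", g), members = members,
         leading_term = lead)
  })
  structure(out, class = "term_clusters", kappa = kmat)
}

#' @export
print.term_clusters <- function(x, ...) {
  cat(sprintf("%d term cluster(s)\n", length(x)))
  for (g in x)
    cat(sprintf("  %s (%d terms, leading: %s)\n", g$group_id,
                length(g$members), g$leading_term))
  invisible(x)
}

#' Write ORA results and term clusters
#' @param results An \code{ora_result}. @param clusters A
#'   \code{term_clusters} (optional). @param tsv,json Output paths.
#' @return Invisibly, the paths written.
#' @export
write_enrichment <- function(results, clusters = NULL, tsv = NULL,
                             json = NULL) {
  if (!is.null(tsv)) write_tsv(as.data.frame(results), tsv)
  if (!is.null(json) && !is.null(clusters)) {
    payload <- lapply(unclass(clusters), function(g)
      list(group_id = g$group_id, members = as.list(g$members),
           leading_term = g$leading_term))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv, json))
}
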