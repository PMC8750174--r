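# Reduction of BLAST tabular hits to a per-siRNA target-gene catalog:
# RefSeq-style prefix whitelist, lowest-E-value selection, Entrez
# annotation pruning, case-insensitive symbol deduplication.

ALLOWED_PREFIXES <- c("NM", "NR", "NP", "XM", "XR", "XP")

BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")

#' Parse a BLAST tabular (outfmt 6) file
#'
#' Expects the standard 12-column tab-separated layout with no header.
#'
#' @param file Path to the tabular hit file.
#' @return Data frame with the 12 outfmt-6 columns; \code{evalue} and
#'   \code{bitscore} numeric. Empty file yields a zero-row frame.
#' @export
parse_blast_tabular <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(matrix(character(), 0, 12),
                         stringsAsFactors = FALSE)
    names(out) <- BLAST_COLS
    for (col in c("pident", "length", "mismatch", "gapopen", "qstart",
                  "qend", "sstart", "send", "evalue", "bitscore"))
      out[[col]] <- numeric()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L)
  if (length(bad))
    ox_stop(sprintf("malformed BLAST tabular line(s) %s: expected 12 columns, got %s",
                    paste(bad, collapse = ", "),
                    paste(nf[bad], collapse = ", ")), "parse_error")
  m <- do.call(rbind, parts)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- BLAST_COLS
  for (col in c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore"))
    out[[col]] <- as.numeric(out[[col]])
  if (any(out$evalue < 0))
    ox_stop("negative E-value in BLAST tabular file", "parse_error")
  out
}

# accession prefix = text before the underscore; "NM_000546.6" -> "NM"
accession_prefix <- function(accession) {
  sub("_.*$", "", accession)
}

# strip the ".version" suffix; annotation tables are versionless
strip_version <- function(accession) {
  sub("\\.[0-9]+$", "", accession)
}

#' Keep hits with an allowed RefSeq-style accession prefix
#'
#' Retains hits whose subject accession prefix (text before "_") is one of
#' NM, NR, NP, XM, XR, XP — the mRNA/RNA/protein molecule types. Other
#' prefixes are dropped; the dropped count is reported as a message.
#'
#' @param hits Data frame as returned by [parse_blast_tabular()].
#' @return Filtered hit data frame.
#' @export
filter_accession_prefix <- function(hits) {
  keep <- accession_prefix(hits$sseqid) %in% ALLOWED_PREFIXES
  if (any(!keep))
    message(sprintf("filter_accession_prefix: dropped %d hit(s) with disallowed prefix",
                    sum(!keep)))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-query lowest-E-value hits
#'
#' For each query, keeps every hit tied at that query's minimum E-value
#' (ties are retained: one siRNA can have several equally-best targets).
#'
#' @inheritParams filter_accession_prefix
#' @return Filtered hit data frame.
#' @export
best_hits_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  min_e <- tapply(hits$evalue, hits$qseqid, min)
  keep <- hits$evalue == as.numeric(min_e[hits$qseqid])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach gene annotation and prune unannotated hits
#'
#' Joins hits to the annotation table on the versionless accession. Hits
#' whose accession has no annotation row, or whose row carries no Entrez
#' identifier, are removed (removal count reported as a message).
#'
#' @inheritParams filter_accession_prefix
#' @param annotation Data frame with columns \code{accession},
#'   \code{entrez_id}, \code{symbol}, \code{biotype}.
#' @return Hit data frame with added \code{entrez_id}, \code{symbol},
#'   \code{biotype} columns.
#' @export
annotate_and_prune <- function(hits, annotation) {
  need <- c("accession", "entrez_id", "symbol", "biotype")
  if (!all(need %in% names(annotation)))
    ox_stop("annotation must have columns accession, entrez_id, symbol, biotype",
            "invalid_parameter")
  ann <- annotation
  ann$accession <- strip_version(ann$accession)
  key <- strip_version(hits$sseqid)
  idx <- match(key, ann$accession)
  entrez <- ann$entrez_id[idx]
  entrez[!is.na(entrez) & entrez == ""] <- NA
  ok <- !is.na(idx) & !is.na(entrez)
  if (any(!ok))
    message(sprintf("annotate_and_prune: removed %d hit(s) without an Entrez annotation",
                    sum(!ok)))
  out <- hits[ok, , drop = FALSE]
  out$entrez_id <- as.integer(entrez[ok])
  out$symbol <- ann$symbol[idx[ok]]
  out$biotype <- ann$biotype[idx[ok]]
  rownames(out) <- NULL
  out
}

#' Deduplicate gene symbols within each query
#'
#' Within a query, a symbol appearing several times (case-insensitively) is
#' reduced to its minimum-E-value occurrence.
#'
#' @param annotated Annotated hit data frame from [annotate_and_prune()].
#' @return Data frame with one row per (query, symbol).
#' @export
dedupe_symbols <- function(annotated) {
  if (nrow(annotated) == 0L) return(annotated)
  key <- paste(annotated$qseqid, tolower(annotated$symbol), sep = "\r")
  ord <- order(key, annotated$evalue)
  out <- annotated[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  out <- out[order(out$qseqid, out$evalue, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a target-gene catalog from annotated per-query gene lists
#'
#' @param per_query Deduplicated annotated hits from [dedupe_symbols()].
#' @return Object of class \code{target_catalog}: list with
#'   \code{per_query} (data frame query_id, entrez_id, symbol, biotype,
#'   best_evalue), \code{unique_genes} (sorted integer Entrez set) and
#'   \code{biotype_tally} (named counts over unique genes — each gene counts
#'   once however many queries hit it).
#' @export
build_catalog <- function(per_query) {
  pq <- data.frame(query_id = per_query$qseqid,
                   entrez_id = per_query$entrez_id,
                   symbol = per_query$symbol,
                   biotype = per_query$biotype,
                   best_evalue = per_query$evalue,
                   stringsAsFactors = FALSE)
  pq <- pq[order(pq$query_id, pq$best_evalue, pq$symbol), , drop = FALSE]
  rownames(pq) <- NULL
  uniq <- sort(unique(pq$entrez_id))
  first <- pq[!duplicated(pq$entrez_id), , drop = FALSE]
  tally <- table(first$biotype)
  tally <- stats::setNames(as.integer(tally), names(tally))
  structure(list(per_query = pq, unique_genes = uniq,
                 biotype_tally = tally),
            class = "target_catalog")
}

#' @export
print.target_catalog <- function(x, ...) {
  cat(sprintf("Target catalog: %d annotated target genes over %d queries; %d unique Entrez IDs\n",
              nrow(x$per_query), length(unique(x$per_query$query_id)),
              length(x$unique_genes)))
  cat("Biotype tally:",
      paste(sprintf("%s=%d", names(x$biotype_tally), x$biotype_tally),
            collapse = ", "), "\n")
  invisible(x)
}

#' Full hit-reduction pipeline: BLAST hits to catalog
#'
#' Applies, in order: accession-prefix whitelist, per-query lowest-E-value
#' selection, Entrez annotation pruning, symbol deduplication, catalog
#' assembly.
#'
#' @param hits Data frame from [parse_blast_tabular()] (or a file path).
#' @param annotation Annotation data frame (or a TSV file path).
#' @return A \code{target_catalog}.
#' @export
reduce_hits <- function(hits, annotation) {
  if (is.character(hits)) hits <- parse_blast_tabular(hits)
  if (is.character(annotation)) annotation <- read_tsv(annotation)
  out <- filter_accession_prefix(hits)
  out <- best_hits_per_query(out)
  out <- annotate_and_prune(out, annotation)
  out <- dedupe_symbols(out)
  build_catalog(out)
}

#' Intersect a catalog with an annotation term's gene set
#'
#' @param catalog A \code{target_catalog}.
#' @param term_genes Vector of gene identifiers annotated to the term
#'   (e.g. an oxidative-stress GO term).
#' @param term_id Optional term label, carried into the result.
#' @return List with \code{term_id}, \code{members} (sorted intersection
#'   with the catalog's unique genes) and \code{count}.
#' @export
cross_annotate <- function(catalog, term_genes, term_id = NA_character_) {
  members <- sort(intersect(catalog$unique_genes, term_genes))
  list(term_id = term_id, members = members, count = length(members))
}

#' Write a catalog to a TSV plus a tally JSON
#' @param catalog A \code{target_catalog}.
#' @param tsv,json Output paths; omit either with \code{NULL}.
#' @return Invisibly, the paths written.
#' @export
write_catalog <- function(catalog, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) write_tsv(catalog$per_query, tsv)
  if (!is.null(json))
    jsonlite::write_json(
      list(unique_genes = length(catalog$unique_genes),
           biotype_tally = as.list(catalog$biotype_tally)),
      json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
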