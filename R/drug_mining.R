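# Drug-target cross-database mining: loading DrugBank-like and TTD-like
# tables into a common schema, querying gene lists, intersecting hit sets
# within and across databases, and per-pathway drug coverage.

# development-stage tokens mapped silently to "other"
OTHER_STATUS_TOKENS <- c("experimental", "investigational", "investigative",
                         "withdrawn", "nutraceutical", "illicit",
                         "vet_approved", "clinical trial", "terminated",
                         "discontinued", "preclinical", "phase 1", "phase 2",
                         "phase 3", "other")

map_status <- function(tokens) {
  s <- normalize_name(tokens)
  out <- rep("other", length(s))
  out[s == "approved"] <- "approved"
  out[s == "patented"] <- "patented"
  unknown <- !(s %in% c("approved", "patented", OTHER_STATUS_TOKENS))
  if (any(unknown))
    warning(sprintf("unknown drug status token(s) mapped to 'other': %s",
                    paste(unique(tokens[unknown]), collapse = ", ")),
            call. = FALSE)
  out
}

#' Load a drug-target table in one of two dialects
#'
#' Normalizes to a common record schema. DB dialect has columns
#' \code{drug_id}, \code{name}, \code{group}, \code{gene} (the group maps
#' to status); TTD dialect has \code{drug_code}, \code{name},
#' \code{status}, \code{gene}. Status lands in the closed vocabulary
#' approved/patented/other (unknown tokens warn and become "other").
#' Duplicate (drug, gene) rows collapse to one.
#'
#' @param file Path to the TSV (or a data frame in the dialect's schema).
#' @param dialect "DB" or "TTD".
#' @return Data frame with \code{drug_id}, \code{drug_name}, \code{status},
#'   \code{gene}, \code{source}.
#' @export
load_drug_table <- function(file, dialect = c("DB", "TTD")) {
  dialect <- match.arg(dialect)
  df <- if (is.character(file)) read_tsv(file) else file
  if (nrow(df) == 0L)
    return(data.frame(drug_id = character(), drug_name = character(),
                      status = character(), gene = character(),
                      source = character(), stringsAsFactors = FALSE))
  if (dialect == "DB") {
    need <- c("drug_id", "name", "group", "gene")
    if (!all(need %in% names(df)))
      ox_stop("DB-dialect table needs columns drug_id, name, group, gene",
              "format_error")
    out <- data.frame(drug_id = df$drug_id, drug_name = df$name,
                      status = map_status(df$group), gene = df$gene,
                      source = "DB", stringsAsFactors = FALSE)
  } else {
    need <- c("drug_code", "name", "status", "gene")
    if (!all(need %in% names(df)))
      ox_stop("TTD-dialect table needs columns drug_code, name, status, gene",
              "format_error")
    out <- data.frame(drug_id = df$drug_code, drug_name = df$name,
                      status = map_status(df$status), gene = df$gene,
                      source = "TTD", stringsAsFactors = FALSE)
  }
  out <- out[!duplicated(paste(out$drug_id, out$gene, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Query a gene list against drug-target records
#'
#' @param genes Character vector of gene identifiers.
#' @param records Record data frame from [load_drug_table()].
#' @return Object of class \code{drug_hits}: list with \code{genes_hit}
#'   (sorted genes that are drug targets), \code{drugs} (data frame
#'   \code{drug_id}, \code{drug_name}, \code{status}, one row per distinct
#'   drug), \code{records} (the matching records), and counts
#'   \code{n_drugs}, \code{n_approved}, \code{pct_approved},
#'   \code{n_patented}.
#' @export
query_drugs <- function(genes, records) {
  genes <- unique(as.character(genes))
  sub <- records[records$gene %in% genes, , drop = FALSE]
  genes_hit <- sort(unique(sub$gene))
  drugs <- sub[!duplicated(sub$drug_id),
               c("drug_id", "drug_name", "status"), drop = FALSE]
  drugs <- drugs[order(drugs$drug_id), , drop = FALSE]
  rownames(drugs) <- rownames(sub) <- NULL
  n_app <- sum(drugs$status == "approved")
  structure(list(genes_hit = genes_hit, drugs = drugs, records = sub,
                 n_genes_hit = length(genes_hit), n_drugs = nrow(drugs),
                 n_approved = n_app,
                 pct_approved = pct1(n_app, nrow(drugs)),
                 n_patented = sum(drugs$status == "patented")),
            class = "drug_hits")
}

#' @export
print.drug_hits <- function(x, ...) {
  cat(sprintf("%d target gene(s) hit; %d drug(s): %d approved (%.1f%%), %d patented\n",
              x$n_genes_hit, x$n_drugs, x$n_approved, x$pct_approved,
              x$n_patented))
  invisible(x)
}

#' Drugs common to two hit sets within one database
#'
#' Intersection by \code{drug_id} (codes are stable within a database;
#' names are not, across salts and formulations).
#'
#' @param hitsA,hitsB \code{drug_hits} objects from the same source.
#' @param status_filter "approved" restricts to approved drugs; "any" does
#'   not.
#' @return Data frame \code{drug_id}, \code{drug_name}, \code{status} of
#'   the common drugs, sorted by id.
#' @export
intersect_hits <- function(hitsA, hitsB, status_filter = c("approved", "any")) {
  status_filter <- match.arg(status_filter)
  da <- hitsA$drugs; db <- hitsB$drugs
  if (status_filter == "approved") {
    da <- da[da$status == "approved", , drop = FALSE]
    db <- db[db$status == "approved", , drop = FALSE]
  }
  out <- da[da$drug_id %in% db$drug_id, , drop = FALSE]
  out <- out[order(out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drugs common to two databases, matched by normalized name
#'
#' Codes differ across databases, so identity is the normalized drug name
#' (lowercase, trimmed, internal whitespace collapsed). One matched pair
#' per name.
#'
#' @param db_hits,ttd_hits \code{drug_hits} from the two sources.
#' @param status_filter As in [intersect_hits()].
#' @return Data frame \code{name}, \code{db_id}, \code{ttd_id}, sorted by
#'   name.
#' @export
cross_database_common <- function(db_hits, ttd_hits,
                                  status_filter = c("approved", "any")) {
  status_filter <- match.arg(status_filter)
  da <- db_hits$drugs; dt <- ttd_hits$drugs
  if (status_filter == "approved") {
    da <- da[da$status == "approved", , drop = FALSE]
    dt <- dt[dt$status == "approved", , drop = FALSE]
  }
  da$key <- normalize_name(da$drug_name)
  dt$key <- normalize_name(dt$drug_name)
  da <- da[!duplicated(da$key), , drop = FALSE]
  dt <- dt[!duplicated(dt$key), , drop = FALSE]
  common <- intersect(da$key, dt$key)
  out <- data.frame(name = common,
                    db_id = da$drug_id[match(common, da$key)],
                    ttd_id = dt$drug_id[match(common, dt$key)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pathway drug coverage
#'
#' For every significant pathway in an ORA result, lists the member genes
#' that are drug targets and the approved drugs targeting them. Pathways
#' with no drug-targeted member yield zero rows.
#'
#' @param enrichment An \code{ora_result} data frame.
#' @param collection The gene-set collection behind it.
#' @param hits A \code{drug_hits} object.
#' @return Data frame \code{set_id}, \code{gene}, \code{drug_id},
#'   \code{drug_name} (approved drugs only).
#' @export
pathway_drug_coverage <- function(enrichment, collection, hits) {
  sig <- enrichment$set_id[enrichment$significant]
  rec <- hits$records[hits$records$status == "approved", , drop = FALSE]
  rows <- lapply(sig, function(id) {
    genes <- intersect(collection[[id]]$genes, hits$genes_hit)
    sub <- rec[rec$gene %in% genes, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(set_id = id, gene = sub$gene, drug_id = sub$drug_id,
               drug_name = sub$drug_name, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(set_id = character(), gene = character(),
                      drug_id = character(), drug_name = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$set_id, out$gene, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a full mining report over two gene lists and two databases
#'
#' @param gene_listA,gene_listB Gene lists (e.g. siRNA targets and their
#'   first interactors).
#' @param db_records,ttd_records Record tables from [load_drug_table()].
#' @return List of class \code{drug_mining_report}: per (list x source)
#'   \code{drug_hits}, plus \code{db_common} (approved drugs common to
#'   both lists within DB), and \code{cross_db_common} (approved drugs
#'   common to DB and TTD over both lists, matched by name).
#' @export
drug_mining_report <- function(gene_listA, gene_listB, db_records,
                               ttd_records) {
  hits <- list(A_db = query_drugs(gene_listA, db_records),
               B_db = query_drugs(gene_listB, db_records),
               A_ttd = query_drugs(gene_listA, ttd_records),
               B_ttd = query_drugs(gene_listB, ttd_records))
  db_common <- intersect_hits(hits$A_db, hits$B_db, "approved")
  all_db <- query_drugs(c(gene_listA, gene_listB), db_records)
  all_ttd <- query_drugs(c(gene_listA, gene_listB), ttd_records)
  cross <- cross_database_common(all_db, all_ttd, "approved")
  structure(c(hits, list(db_common = db_common, cross_db_common = cross)),
            class = "drug_mining_report")
}

#' @export
print.drug_mining_report <- function(x, ...) {
  cat("Drug mining report\n")
  for (nm in c("A_db", "B_db", "A_ttd", "B_ttd")) {
    cat(sprintf("  %s: ", nm)); print(x[[nm]])
  }
  cat(sprintf("  DB common approved drugs between lists: %d\n",
              nrow(x$db_common)))
  cat(sprintf("  Cross-database common approved drugs: %d\n",
              nrow(x$cross_db_common)))
  invisible(x)
}
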