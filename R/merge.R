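#' Merge a candidate database into a reference database
#'
#' The pairwise integration step of the database-merging workflow. For each
#' candidate entry, in input order:
#'
#' 1. If the candidate's full 7-rank taxonomy string is absent from the
#'    growing merged set, the entry is added (`added_new_taxon`).
#' 2. Otherwise the candidate sequence is compared against every sequence
#'    already held under that exact taxonomy. If it is identical to, or
#'    occurs as a contiguous substring of, any of them the entry is skipped
#'    (`skipped_duplicate`); otherwise it is added (`added_new_sequence`).
#'
#' Reference entries are never modified or removed, and candidate entries
#' accepted earlier take part in the duplicate test for later candidates
#' (the data set grows as entries are integrated). The containment test is
#' one-directional: a reference sequence contained in a longer candidate
#' does not block the addition. Comparison is forward-strand only.
#'
#' Taxonomy identity is exact, case-sensitive string equality, which
#' presumes both inputs have been curated and synonym-unified (see
#' [curate_database()]). Candidate ids colliding with ids already present
#' are renamed by prefixing the candidate's source label.
#'
#' @param reference,candidate reference-database data.frames with
#'   non-empty taxonomy strings.
#' @return list with `db` (the merged database) and `decisions` (a
#'   data.frame with one row per candidate: `candidate_id`, `action`,
#'   `matched_reference_id`).
#' @export
merge_pair <- function(reference, candidate) {
  for (nm in c("reference", "candidate")) {
    db <- get(nm)
    if (nrow(db) && any(db$taxonomy == "" | is.na(db$taxonomy)))
      stop(nm, " database has entries with empty taxonomy; curate first")
  }
  # sequences already held, indexed by exact taxonomy string
  pool <- new.env(parent = emptyenv(), hash = TRUE)
  add_to_pool <- function(tax, seq, id) {
    key <- tax
    cur <- pool[[key]]
    pool[[key]] <- rbind(cur, data.frame(sequence = seq, id = id,
                                         stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(reference)))
    add_to_pool(reference$taxonomy[[i]], reference$sequence[[i]],
                reference$id[[i]])

  ids_seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (id in reference$id) ids_seen[[id]] <- TRUE

  merged <- reference
  kept <- list()
  n_cand <- nrow(candidate)
  action <- character(n_cand)
  matched <- rep(NA_character_, n_cand)
  new_id <- candidate$id

  for (i in seq_len(n_cand)) {
    tax <- candidate$taxonomy[[i]]
    seq <- candidate$sequence[[i]]
    held <- pool[[tax]]
    if (is.null(held)) {
      action[[i]] <- "added_new_taxon"
    } else {
      hit <- which(vapply(held$sequence,
                          function(s) {
                            nchar(seq) <= nchar(s) &&
                              grepl(seq, s, fixed = TRUE)
                          }, logical(1)))
      if (length(hit)) {
        action[[i]] <- "skipped_duplicate"
        matched[[i]] <- held$id[[hit[[1L]]]]
        next
      }
      action[[i]] <- "added_new_sequence"
    }
    id <- candidate$id[[i]]
    if (!is.null(ids_seen[[id]])) {
      src <- candidate$source[[i]]
      id <- paste(if (is.na(src)) "candidate" else src, id, sep = "_")
    }
    ids_seen[[id]] <- TRUE
    new_id[[i]] <- id
    row <- candidate[i, , drop = FALSE]
    row$id <- id
    kept[[length(kept) + 1L]] <- row
    add_to_pool(tax, seq, id)
  }
  if (length(kept)) merged <- rbind(merged, do.call(rbind, kept))
  rownames(merged) <- NULL
  list(db = merged,
       decisions = data.frame(candidate_id = candidate$id,
                              action = action,
                              matched_reference_id = matched,
                              stringsAsFactors = FALSE))
}

#' Chain-merge an ordered list of databases
#'
#' Left fold of [merge_pair()]: the first database is the initial
#' reference, each subsequent database is integrated as candidate into the
#' result so far. The merge is order-sensitive by design — the first
#' databases get priority as references.
#'
#' @param dbs non-empty named list of reference-database data.frames, in
#'   merge order. Unnamed elements fall back to their `source` column.
#' @return list with `db` (merged database) and `report` (class
#'   `merge_report`: per-source entry counts and percentages).
#' @export
merge_chain <- function(dbs) {
  if (!length(dbs)) stop("merge_chain needs at least one database")
  labels <- names(dbs)
  if (is.null(labels)) labels <- rep("", length(dbs))
  for (i in seq_along(dbs)) {
    if (labels[[i]] == "")
      labels[[i]] <- if (!is.na(dbs[[i]]$source[1] %||% NA_character_))
        dbs[[i]]$source[[1]] else paste0("db", i)
    dbs[[i]]$source <- labels[[i]]
  }
  merged <- dbs[[1L]]
  decisions <- list()
  for (i in seq_along(dbs)[-1L]) {
    res <- merge_pair(merged, dbs[[i]])
    merged <- res$db
    decisions[[labels[[i]]]] <- res$decisions
  }
  counts <- table(factor(merged$source, levels = unique(labels)))
  report <- structure(list(
    total = nrow(merged),
    source_counts = as.integer(counts),
    source_percent = if (nrow(merged)) 100 * as.integer(counts) / nrow(merged)
                     else rep(0, length(counts)),
    sources = names(counts),
    decisions = decisions), class = "merge_report")
  list(db = merged, report = report)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.merge_report <- function(x, ...) {
  cat("Merged database:", x$total, "entries\n")
  for (i in seq_along(x$sources))
    cat(sprintf("  %-12s %6d (%.2f%%)\n", x$sources[[i]],
                x$source_counts[[i]], x$source_percent[[i]]))
  invisible(x)
}

#' Write a merge report as TSV
#' @param report a `merge_report`.
#' @param path output file.
#' @export
write_merge_report <- function(report, path) {
  df <- data.frame(source = report$sources,
                   entries = report$source_counts,
                   percent = round(report$source_percent, 2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
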