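#' Curation rules
#'
#' Bundles the quality filters applied to a raw reference database:
#'
#' * `unknown_patterns` — case-insensitive substrings that mark a label as
#'   uninformative (defaults: `"uncultured"`, `"unidentified"`,
#'   `"candidate"`). Matching is a literal substring test on each rank
#'   label; note that `"candidate"` does not match `"Candidatus_..."` —
#'   add `"candidatus"` to the list if that behaviour is wanted.
#' * `allowed_kingdoms` — kingdoms retained by the kingdom filter
#'   (default Bacteria and Archaea; Eukaryota and Viruses are dropped).
#' * `drop_rank_sparse` — drop entries annotated only at the kingdom and
#'   species levels (typically rare isolates from uncharacterised
#'   environments).
#'
#' @param unknown_patterns character vector of patterns; must be non-empty
#'   when `filter_unknown` is `TRUE`.
#' @param allowed_kingdoms character vector of kingdom names.
#' @param drop_rank_sparse logical.
#' @param filter_unknown,filter_kingdom,filter_cross_kingdom logicals
#'   enabling the individual filters.
#' @return object of class `curation_rules`.
#' @export
curation_rules <- function(unknown_patterns = c("uncultured", "unidentified",
                                                "candidate"),
                           allowed_kingdoms = c("Bacteria", "Archaea"),
                           drop_rank_sparse = TRUE,
                           filter_unknown = TRUE,
                           filter_kingdom = TRUE,
                           filter_cross_kingdom = TRUE) {
  if (filter_unknown && !length(unknown_patterns))
    stop("unknown_patterns must be non-empty when unknown-label filtering is on")
  structure(list(unknown_patterns = as.character(unknown_patterns),
                 allowed_kingdoms = as.character(allowed_kingdoms),
                 drop_rank_sparse = isTRUE(drop_rank_sparse),
                 filter_unknown = isTRUE(filter_unknown),
                 filter_kingdom = isTRUE(filter_kingdom),
                 filter_cross_kingdom = isTRUE(filter_cross_kingdom)),
            class = "curation_rules")
}

#' Keep only entries from allowed kingdoms
#'
#' @param db reference-database data.frame.
#' @param rules a [curation_rules()] object.
#' @return list with `db` (retained entries, order preserved) and
#'   `removed` (count).
#' @export
filter_kingdoms <- function(db, rules = curation_rules()) {
  kingdoms <- parse_taxonomy(db$taxonomy)[, "kingdom"]
  keep <- kingdoms %in% rules$allowed_kingdoms
  list(db = db[keep, , drop = FALSE], removed = sum(!keep))
}

#' Flag lineages with unknown or missing labels
#'
#' `TRUE` when the species label is empty or any rank label contains one of
#' the configured patterns (case-insensitive substring match).
#'
#' @param taxonomy character matrix from [parse_taxonomy()] (or lineage
#'   strings, parsed on the fly).
#' @param rules a [curation_rules()] object.
#' @return logical vector, one element per lineage.
#' @export
flag_unknown_labels <- function(taxonomy, rules = curation_rules()) {
  m <- if (is.null(dim(taxonomy))) parse_taxonomy(taxonomy) else taxonomy
  flag <- m[, "species"] == ""
  low <- matrix(tolower(m), nrow = nrow(m))
  for (pat in tolower(rules$unknown_patterns)) {
    hit <- matrix(grepl(pat, low, fixed = TRUE), nrow = nrow(m))
    flag <- flag | rowSums(hit) > 0L
  }
  unname(flag)
}

#' Flag rank-sparse lineages
#'
#' `TRUE` when kingdom and species are annotated while all five
#' intermediate ranks (phylum through genus) are empty — e.g.
#' `k__Bacteria; ...; s__bacterium_Te63R`.
#'
#' @inheritParams flag_unknown_labels
#' @return logical vector.
#' @export
flag_rank_sparse <- function(taxonomy) {
  m <- if (is.null(dim(taxonomy))) parse_taxonomy(taxonomy) else taxonomy
  mid <- m[, c("phylum", "class", "order", "family", "genus"), drop = FALSE]
  unname(m[, "kingdom"] != "" & m[, "species"] != "" &
           rowSums(mid != "") == 0L)
}

# Unify one vector of rank labels. Clustered labels (containing the
# cluster separators) are expanded, unified per component, and re-merged,
# so a synonym inside a merged label is still normalised.
.unify_labels <- function(labels, synonyms, rank, policy = merge_policy()) {
  out <- labels
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    if (lab == "") next
    if (grepl("[-:]", lab) && lab != policy$unknown_placeholder) {
      parts <- expand_clustered_name(lab)
      canon <- synonym_lookup(synonyms, parts)
      parts <- ifelse(is.na(canon), parts, canon)
      out[[i]] <- if (rank == "species")
        compress_species_names(parts, policy)
      else merge_rank_names(parts, policy)
    } else {
      canon <- synonym_lookup(synonyms, lab)
      if (!is.na(canon)) out[[i]] <- canon
    }
  }
  out
}

#' Unify taxonomy labels against a synonym map
#'
#' Replaces every rank label by its canonical name when the label is
#' present in the map; unmapped labels pass through unchanged. Clustered
#' (multi-name) labels are unified component-wise and re-merged.
#'
#' @param taxonomy lineage strings or a matrix from [parse_taxonomy()].
#' @param synonyms a [synonym_map()].
#' @return list with `taxonomy` (same representation as the input) and
#'   `changed` (logical vector).
#' @export
unify_taxonomy <- function(taxonomy, synonyms) {
  as_string <- is.null(dim(taxonomy))
  m <- if (as_string) parse_taxonomy(taxonomy) else taxonomy
  out <- m
  for (rank in colnames(m))
    out[, rank] <- .unify_labels(m[, rank], synonyms, rank)
  changed <- rowSums(out != m) > 0L
  list(taxonomy = if (as_string) format_taxonomy(out) else out,
       changed = unname(changed))
}

#' Detect cross-kingdom misannotations
#'
#' `TRUE` when the species name resolves in the synonym map to a canonical
#' record whose kingdom is outside the allowed set — e.g. a plant species
#' filed under a Bacteria lineage. Species absent from the map cannot be
#' judged and return `FALSE`.
#'
#' @inheritParams flag_unknown_labels
#' @param synonyms a [synonym_map()] whose entries carry the canonical
#'   kingdom.
#' @export
detect_cross_kingdom <- function(taxonomy, synonyms,
                                 rules = curation_rules()) {
  m <- if (is.null(dim(taxonomy))) parse_taxonomy(taxonomy) else taxonomy
  kingdom <- synonym_lookup(synonyms, m[, "species"], field = "kingdom")
  unname(!is.na(kingdom) & !(kingdom %in% rules$allowed_kingdoms))
}

#' Curate a reference database
#'
#' Applies, in order: the kingdom filter, the unknown-label filter, the
#' rank-sparsity filter, the cross-kingdom filter, and synonym
#' unification. Removals are judged on the original labels because
#' unification runs last. The report satisfies the accounting identity
#' `input_count == output_count + sum(removed_by_rule)`.
#'
#' @param db reference-database data.frame.
#' @param rules a [curation_rules()] object.
#' @param synonyms a [synonym_map()]; an empty map disables unification
#'   and the cross-kingdom filter effectively.
#' @return list with `db` (curated database) and `report` (class
#'   `curation_report`).
#' @export
curate_database <- function(db, rules = curation_rules(),
                            synonyms = synonym_map()) {
  input_count <- nrow(db)
  removed <- c(kingdom = 0L, unknown_label = 0L, rank_sparse = 0L,
               cross_kingdom = 0L)

  if (rules$filter_kingdom) {
    res <- filter_kingdoms(db, rules)
    removed[["kingdom"]] <- res$removed
    db <- res$db
  }
  if (rules$filter_unknown && nrow(db)) {
    drop <- flag_unknown_labels(db$taxonomy, rules)
    removed[["unknown_label"]] <- sum(drop)
    db <- db[!drop, , drop = FALSE]
  }
  if (rules$drop_rank_sparse && nrow(db)) {
    drop <- flag_rank_sparse(db$taxonomy)
    removed[["rank_sparse"]] <- sum(drop)
    db <- db[!drop, , drop = FALSE]
  }
  if (rules$filter_cross_kingdom && nrow(db) && nrow(synonyms)) {
    drop <- detect_cross_kingdom(db$taxonomy, synonyms, rules)
    removed[["cross_kingdom"]] <- sum(drop)
    db <- db[!drop, , drop = FALSE]
  }
  renamed <- 0L
  if (nrow(db) && nrow(synonyms)) {
    uni <- unify_taxonomy(db$taxonomy, synonyms)
    renamed <- sum(uni$changed)
    db$taxonomy <- uni$taxonomy
  }
  rownames(db) <- NULL
  report <- structure(list(input_count = input_count,
                           removed_by_rule = removed,
                           renamed_count = renamed,
                           output_count = nrow(db)),
                      class = "curation_report")
  stopifnot(report$input_count ==
              report$output_count + sum(report$removed_by_rule))
  list(db = db, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat("  input entries:   ", x$input_count, "\n")
  for (rule in names(x$removed_by_rule))
    cat(sprintf("  removed (%s): %d\n", rule, x$removed_by_rule[[rule]]))
  cat("  renamed by unification:", x$renamed_count, "\n")
  cat("  output entries:  ", x$output_count, "\n")
  invisible(x)
}

#' Write a curation report as TSV
#' @param report a `curation_report`.
#' @param path output file.
#' @export
write_curation_report <- function(report, path) {
  df <- data.frame(
    metric = c("input_count",
               paste0("removed_", names(report$removed_by_rule)),
               "renamed_count", "output_count"),
    value = c(report$input_count, unname(report$removed_by_rule),
              report$renamed_count, report$output_count))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
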