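#' Policy for merging taxonomies of clustered sequences
#'
#' Controls the clustered-nomenclature grammar: distinct names at a rank
#' are joined with `name_separator`; species names are compressed per
#' genus group with `genus_group_separator` between groups; and a merged
#' label that would list more than `max_names` distinct names is replaced
#' by `unknown_placeholder` to prevent wordy, uninformative labels.
#'
#' @param max_names maximum number of distinct names listed verbatim
#'   (default 10; beyond it the placeholder is used).
#' @param unknown_placeholder replacement label (default `"Unknown"`).
#' @param name_separator separator between names (default `"-"`).
#' @param genus_group_separator separator between genus groups in
#'   compressed species labels (default `":"`).
#' @return object of class `merge_policy`.
#' @export
merge_policy <- function(max_names = 10L, unknown_placeholder = "Unknown",
                         name_separator = "-", genus_group_separator = ":") {
  stopifnot(max_names >= 1L)
  structure(list(max_names = as.integer(max_names),
                 unknown_placeholder = unknown_placeholder,
                 name_separator = name_separator,
                 genus_group_separator = genus_group_separator),
            class = "merge_policy")
}

.sort_ci <- function(x) x[order(tolower(x), x, method = "radix")]

#' Merge distinct rank names into one clustered label
#'
#' Names are deduplicated, sorted alphabetically (case-insensitive,
#' original case preserved) and joined with the policy separator; more
#' than `max_names` distinct names collapse to the placeholder. Used for
#' kingdom through genus; species labels go through
#' [compress_species_names()].
#'
#' @param names character vector of rank labels (empties ignored).
#' @param policy a [merge_policy()].
#' @return single merged label.
#' @examples
#' merge_rank_names(c("Limosilactobacillus", "Lactobacillus"))
#' @export
merge_rank_names <- function(names, policy = merge_policy()) {
  names <- unique(names[names != "" & !is.na(names)])
  if (!length(names)) return("")
  if (length(names) > policy$max_names) return(policy$unknown_placeholder)
  paste(.sort_ci(names), collapse = policy$name_separator)
}

#' Compress species names into the per-genus clustered form
#'
#' Species names in `Genus_epithet` form are grouped by their genus token
#' (text before the first underscore). Within a group the alphabetically
#' first full name is kept and later members contribute only their
#' epithet, joined with `-`; groups are sorted alphabetically and joined
#' with `:`. Names without an underscore form their own verbatim group.
#' More than `max_names` distinct names collapse to the placeholder.
#'
#' @param names character vector of species labels (empties ignored).
#' @param policy a [merge_policy()].
#' @return single compressed label, e.g.
#'   `"Lactobacillus_crispatus:Limosilactobacillus_fermentum-oris"`.
#' @seealso [expand_clustered_name()] for the inverse.
#' @export
compress_species_names <- function(names, policy = merge_policy()) {
  names <- unique(names[names != "" & !is.na(names)])
  if (!length(names)) return("")
  if (length(names) > policy$max_names) return(policy$unknown_placeholder)
  has_genus <- grepl("_", names, fixed = TRUE)
  key <- ifelse(has_genus, sub("_.*$", "", names), names)
  groups <- split(seq_along(names), key)
  labels <- vapply(groups, function(idx) {
    members <- .sort_ci(names[idx])
    if (!grepl("_", members[[1L]], fixed = TRUE))
      return(paste(members, collapse = policy$name_separator))
    epithets <- sub("^[^_]*_", "", members[-1L])
    paste(c(members[[1L]], epithets), collapse = policy$name_separator)
  }, character(1))
  paste(.sort_ci(unname(labels)), collapse = policy$genus_group_separator)
}

#' Merge the taxonomies of one sequence cluster
#'
#' Ranks kingdom through genus are merged with [merge_rank_names()], the
#' species rank with [compress_species_names()]; empty labels are ignored.
#'
#' @param taxonomies lineage strings or a matrix from [parse_taxonomy()].
#' @param policy a [merge_policy()].
#' @return single formatted lineage string.
#' @export
merge_cluster_taxonomy <- function(taxonomies, policy = merge_policy()) {
  m <- if (is.null(dim(taxonomies))) parse_taxonomy(taxonomies) else taxonomies
  merged <- vapply(tax_ranks(), function(rank) {
    if (rank == "species") compress_species_names(m[, rank], policy)
    else merge_rank_names(m[, rank], policy)
  }, character(1))
  format_taxonomy(matrix(merged, nrow = 1L))
}

#' Cluster sequences at 100% identity with substring containment
#'
#' Greedy longest-first clustering in the style of CD-HIT at a 100%
#' identity threshold: sequences are visited longest first (ties broken by
#' sequence then id) and each sequence joins the first existing cluster
#' whose representative contains it as an exact substring (identity is a
#' special case); otherwise it founds a new cluster with itself as
#' representative. Every representative is therefore a longest member of
#' its cluster, and every member is contained in it.
#'
#' @param db reference-database data.frame (normally dereplicated first).
#' @return list of clusters, each a list with `representative_id` and
#'   `member_ids` (in visiting order, representative first).
#' @export
cluster_identical <- function(db) {
  if (!nrow(db)) return(list())
  ord <- order(-nchar(db$sequence), db$sequence, db$id, method = "radix")
  rep_seq <- character(0)
  rep_id <- character(0)
  members <- list()
  for (i in ord) {
    s <- db$sequence[[i]]
    hit <- NA_integer_
    if (length(rep_seq)) {
      cand <- which(grepl(s, rep_seq, fixed = TRUE))
      if (length(cand)) hit <- cand[[1L]]
    }
    if (is.na(hit)) {
      rep_seq <- c(rep_seq, s)
      rep_id <- c(rep_id, db$id[[i]])
      members[[length(members) + 1L]] <- db$id[[i]]
    } else {
      members[[hit]] <- c(members[[hit]], db$id[[i]])
    }
  }
  mapply(function(rid, mem) list(representative_id = rid, member_ids = mem),
         rep_id, members, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Cluster a database and merge member taxonomies
#'
#' One output entry per cluster: the representative sequence with the
#' merged (clustered) taxonomy of all members. Membership is returned as a
#' sidecar table.
#'
#' @param db reference-database data.frame.
#' @param policy a [merge_policy()].
#' @return list with `db` (clustered database; no two sequences
#'   identical), `membership` (data.frame `cluster_id`, `member_id`) and
#'   `clusters` (the [cluster_identical()] result).
#' @export
cluster_database <- function(db, policy = merge_policy()) {
  clusters <- cluster_identical(db)
  idx <- match(vapply(clusters, `[[`, "", "representative_id"), db$id)
  taxonomy <- vapply(clusters, function(cl) {
    merge_cluster_taxonomy(db$taxonomy[match(cl$member_ids, db$id)], policy)
  }, character(1))
  out <- data.frame(id = db$id[idx],
                    sequence = db$sequence[idx],
                    taxonomy = taxonomy,
                    source = db$source[idx],
                    stringsAsFactors = FALSE)
  membership <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$representative_id, member_id = cl$member_ids,
               stringsAsFactors = FALSE)))
  if (is.null(membership))
    membership <- data.frame(cluster_id = character(0),
                             member_id = character(0))
  list(db = out, membership = membership, clusters = clusters)
}
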