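#' Expand a clustered label into its member names
#'
#' Inverse of the clustered-nomenclature grammar: the label is split on
#' `:` into genus groups; within a group whose leading token is in
#' `Genus_epithet` form, each subsequent `-`-joined bare epithet
#' re-attaches the group's genus; labels without underscores (non-species
#' ranks) simply split on `-`. The placeholder (`"Unknown"`) and the empty
#' label expand to the empty set.
#'
#' @param label one clustered (or plain) label.
#' @param policy a [merge_policy()].
#' @return character vector of member names.
#' @examples
#' expand_clustered_name("Lactobacillus_crispatus:Limosilactobacillus_fermentum-oris")
#' @export
expand_clustered_name <- function(label, policy = merge_policy()) {
  if (is.na(label) || label == "" || label == policy$unknown_placeholder)
    return(character(0))
  groups <- strsplit(label, policy$genus_group_separator, fixed = TRUE)[[1]]
  out <- lapply(groups, function(g) {
    tokens <- strsplit(g, policy$name_separator, fixed = TRUE)[[1]]
    if (length(tokens) <= 1L || !grepl("_", tokens[[1L]], fixed = TRUE))
      return(tokens)
    genus <- sub("_.*$", "", tokens[[1L]])
    rest <- tokens[-1L]
    rest <- ifelse(grepl("_", rest, fixed = TRUE), rest,
                   paste(genus, rest, sep = "_"))
    c(tokens[[1L]], rest)
  })
  unique(unlist(out))
}

# The name set a label answers to: itself plus its expansion.
.name_set <- function(label, policy = merge_policy()) {
  unique(c(label, expand_clustered_name(label, policy)))
}

#' Do two taxonomic labels match?
#'
#' A match is called when the labels are identical or, for clustered
#' labels, when one name is included in the other — implemented as a
#' non-empty intersection of the two labels' name sets (the label itself
#' plus its expansion). Symmetric by construction. Labels are assumed to
#' be synonym-unified already.
#'
#' @param assigned_label,expected_label labels to compare.
#' @param policy a [merge_policy()].
#' @export
names_match <- function(assigned_label, expected_label,
                        policy = merge_policy()) {
  if (identical(assigned_label, expected_label)) return(TRUE)
  length(intersect(.name_set(assigned_label, policy),
                   .name_set(expected_label, policy))) > 0L
}

# Adjacency between distinct labels under names_match, via shared names.
# Returns, for each label index, the integer indices of matching labels.
.label_match_sets <- function(labels, policy = merge_policy()) {
  sets <- lapply(labels, .name_set, policy = policy)
  by_name <- split(rep(seq_along(labels), lengths(sets)), unlist(sets))
  lapply(sets, function(s) sort(unique(unlist(by_name[s], use.names = FALSE))))
}

#' Per-taxon confusion counts at one rank
#'
#' For every taxon id in the union of the expected and assigned labels,
#' tallies each evaluated sequence as TP (taxon matches both the assigned
#' and the expected label), FP (assigned only), FN (expected only) or TN
#' (neither), with matching via [names_match()]. Consequently
#' `TP + FP + FN + TN` equals the number of sequences for every taxon.
#'
#' @param expected,assigned named character vectors (sequence id -> label
#'   or full lineage string); the two id sets must coincide. The empty
#'   string marks an unassigned sequence and never becomes a taxon id.
#' @param rank when given, inputs are full lineage strings and the label
#'   at this rank is evaluated; when `NULL`, inputs are bare labels.
#' @param policy a [merge_policy()].
#' @return data.frame `taxon`, `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(expected, assigned, rank = NULL,
                             policy = merge_policy()) {
  if (!setequal(names(expected), names(assigned)) ||
      length(expected) != length(assigned))
    stop("expected and assigned tables must cover the same sequence ids")
  assigned <- assigned[names(expected)]
  if (!is.null(rank)) {
    rank <- match.arg(rank, tax_ranks())
    blank <- assigned == ""
    expected <- parse_taxonomy(unname(expected))[, rank]
    a_lab <- rep("", length(assigned))
    if (any(!blank))
      a_lab[!blank] <- parse_taxonomy(unname(assigned[!blank]))[, rank]
    assigned <- a_lab
  }
  e_lab <- unname(expected); a_lab <- unname(assigned)
  labels <- unique(c(e_lab, a_lab))
  taxa <- setdiff(labels, "")
  if (!length(taxa))
    return(data.frame(taxon = character(0), TP = integer(0), FP = integer(0),
                      FN = integer(0), TN = integer(0)))
  match_sets <- .label_match_sets(labels, policy)
  e_idx <- match(e_lab, labels)
  a_idx <- match(a_lab, labels)
  n <- length(e_lab)
  res <- t(vapply(match(taxa, labels), function(t_idx) {
    memb <- logical(length(labels))
    memb[match_sets[[t_idx]]] <- TRUE
    if ("" %in% labels) memb[match("", labels)] <- FALSE
    mE <- memb[e_idx]; mA <- memb[a_idx]
    c(TP = sum(mE & mA), FP = sum(mA & !mE),
      FN = sum(mE & !mA), TN = sum(!mE & !mA))
  }, integer(4)))
  data.frame(taxon = taxa, TP = res[, "TP"], FP = res[, "FP"],
             FN = res[, "FN"], TN = res[, "TN"], stringsAsFactors = FALSE)
}

#' Validation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 (harmonic mean of precision and recall). A `0/0`
#' ratio is reported as 0 and flagged in the matching `*_undefined`
#' column, so fully missed taxa penalise downstream weighted means rather
#' than silently vanishing.
#'
#' @param counts data.frame from [confusion_counts()].
#' @return the input with columns `accuracy`, `precision`, `recall`,
#'   `f1`, `precision_undefined`, `recall_undefined`, `f1_undefined`
#'   appended.
#' @export
metrics_from_counts <- function(counts) {
  with_default <- function(num, den) ifelse(den > 0, num / den, 0)
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  counts$accuracy <- with_default(tp + tn, tp + fp + tn + fn)
  counts$precision <- with_default(tp, tp + fp)
  counts$recall <- with_default(tp, tp + fn)
  counts$f1 <- with_default(2 * counts$precision * counts$recall,
                            counts$precision + counts$recall)
  counts$precision_undefined <- (tp + fp) == 0
  counts$recall_undefined <- (tp + fn) == 0
  counts$f1_undefined <- (counts$precision + counts$recall) == 0
  counts
}

#' Abundance-weighted mean of per-taxon scores
#'
#' The community-level summary of a validation metric: per-taxon scores
#' averaged with the expected relative abundances as weights,
#' `s_bar = sum(a_i * s_i) / sum(a_i)`. Taxa absent from the expected
#' composition carry weight 0.
#'
#' @param scores,weights equal-length numerics; weights non-negative.
#' @return the weighted mean, `NA` when all weights are zero.
#' @export
weighted_mean_score <- function(scores, weights) {
  stopifnot(length(scores) == length(weights))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) == 0) return(NA_real_)
  sum(scores * weights) / sum(weights)
}

#' Bray-Curtis distance between two compositions
#'
#' Computed over the union of taxon labels (absent taxa count as zero
#' abundance; unassigned mass stays as its own label). 0 for identical
#' compositions, 1 for disjoint ones.
#'
#' @param expected_comp,assigned_comp named numeric vectors of relative
#'   abundances.
#' @return distance in `[0, 1]`.
#' @export
bray_curtis <- function(expected_comp, assigned_comp) {
  taxa <- union(names(expected_comp), names(assigned_comp))
  e <- setNames(numeric(length(taxa)), taxa)
  a <- e
  e[names(expected_comp)] <- expected_comp
  a[names(assigned_comp)] <- assigned_comp
  if (sum(e) == 0 && sum(a) == 0) return(0)
  as.numeric(vegan::vegdist(rbind(e, a), method = "bray"))
}

# Aggregate per-member abundances of one sample by label.
.aggregate_abundance <- function(abund, labels) {
  v <- tapply(abund, labels, sum)
  setNames(as.numeric(v), names(v))
}

#' Evaluate an assignment table against a mock community
#'
#' The full benchmarking chain: both the expected and the assigned
#' taxonomies are synonym-unified, then at every rank the per-taxon
#' confusion counts and metrics are computed once (the evaluated sequence
#' set is shared by all samples) and summarised per sample with the
#' sample's expected abundances as weights. Bray-Curtis distances between
#' the expected and assigned per-rank compositions are computed per
#' sample, with unassigned mass kept under the label `"Unassigned"`.
#'
#' @param mock a [build_mock_community()] object.
#' @param assignment assignment table (data.frame `id`, `taxonomy`);
#'   member ids missing from it count as unassigned, unknown ids are an
#'   error.
#' @param synonyms optional [synonym_map()] applied to both sides before
#'   comparison.
#' @param ranks ranks to evaluate (default all seven).
#' @param policy a [merge_policy()].
#' @return list with `per_taxon` (one row per rank x taxon: counts,
#'   scores, flags) and `summary` (one row per sample x rank: weighted
#'   accuracy, precision, recall, F1, Bray-Curtis distance, `n_taxa`).
#' @export
evaluate_dataset <- function(mock, assignment, synonyms = NULL,
                             ranks = tax_ranks(), policy = merge_policy()) {
  ranks <- match.arg(ranks, tax_ranks(), several.ok = TRUE)
  ids <- mock$members$id
  unknown <- setdiff(assignment$id, ids)
  if (length(unknown))
    stop("assignment contains ids absent from the mock community: ",
         paste(head(unknown, 5L), collapse = ", "))
  assigned_full <- setNames(rep("", length(ids)), ids)
  assigned_full[assignment$id] <- assignment$taxonomy
  expected_full <- setNames(mock$members$taxonomy, ids)

  if (!is.null(synonyms) && nrow(synonyms)) {
    expected_full[] <- unify_taxonomy(unname(expected_full), synonyms)$taxonomy
    nz <- assigned_full != ""
    if (any(nz))
      assigned_full[nz] <- unify_taxonomy(unname(assigned_full[nz]),
                                          synonyms)$taxonomy
  }
  e_mat <- parse_taxonomy(unname(expected_full))
  a_mat <- matrix("", nrow = length(ids), ncol = 7L,
                  dimnames = list(NULL, tax_ranks()))
  nz <- assigned_full != ""
  if (any(nz)) a_mat[nz, ] <- parse_taxonomy(unname(assigned_full[nz]))

  samples <- rownames(mock$composition)
  per_taxon <- list()
  summary_rows <- list()
  for (rank in ranks) {
    e_lab <- setNames(e_mat[, rank], ids)
    a_lab <- setNames(ifelse(nz, a_mat[, rank], ""), ids)
    metrics <- metrics_from_counts(confusion_counts(e_lab, a_lab,
                                                    policy = policy))
    per_taxon[[rank]] <- cbind(rank = rank, metrics,
                               stringsAsFactors = FALSE)
    for (s in samples) {
      abund <- mock$composition[s, ]
      w_expected <- .aggregate_abundance(abund, unname(e_lab))
      weights <- setNames(numeric(nrow(metrics)), metrics$taxon)
      shared <- intersect(names(w_expected), metrics$taxon)
      weights[shared] <- w_expected[shared]
      a_comp_lab <- ifelse(unname(a_lab) == "", "Unassigned", unname(a_lab))
      bc <- bray_curtis(w_expected,
                        .aggregate_abundance(abund, a_comp_lab))
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        sample = s, rank = rank, n_taxa = nrow(metrics),
        accuracy = weighted_mean_score(metrics$accuracy, weights),
        precision = weighted_mean_score(metrics$precision, weights),
        recall = weighted_mean_score(metrics$recall, weights),
        f1 = weighted_mean_score(metrics$f1, weights),
        bray_curtis = bc, stringsAsFactors = FALSE)
    }
  }
  list(per_taxon = do.call(rbind, c(per_taxon, make.row.names = FALSE)),
       summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)))
}

#' Write evaluation results as tidy TSVs
#'
#' @param result an [evaluate_dataset()] result.
#' @param prefix output prefix; writes `<prefix>.per-taxon.tsv` and
#'   `<prefix>.summary.tsv`.
#' @export
write_evaluation <- function(result, prefix) {
  pt <- paste0(prefix, ".per-taxon.tsv")
  sm <- paste0(prefix, ".summary.tsv")
  write.table(result$per_taxon, pt, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$summary, sm, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(per_taxon = pt, summary = sm))
}

#' Compare evaluation summaries across configurations
#'
#' Averages each metric per (configuration, rank) across samples (and
#' communities, if the summaries were row-bound) and flags the best
#' configuration per rank by mean F1.
#'
#' @param summaries named list of `summary` data.frames from
#'   [evaluate_dataset()].
#' @return data.frame with one row per configuration x rank: mean and sd
#'   of each metric, plus a logical `best_f1`.
#' @export
summarize_configurations <- function(summaries) {
  stopifnot(length(summaries) >= 1L, !is.null(names(summaries)))
  metrics <- c("accuracy", "precision", "recall", "f1", "bray_curtis")
  rows <- list()
  for (config in names(summaries)) {
    df <- summaries[[config]]
    for (rank in unique(df$rank)) {
      sub <- df[df$rank == rank, , drop = FALSE]
      row <- data.frame(configuration = config, rank = rank,
                        n = nrow(sub), stringsAsFactors = FALSE)
      for (m in metrics) {
        row[[paste0("mean_", m)]] <- mean(sub[[m]], na.rm = TRUE)
        row[[paste0("sd_", m)]] <- if (nrow(sub) > 1L)
          sd(sub[[m]], na.rm = TRUE) else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$best_f1 <- FALSE
  for (rank in unique(out$rank)) {
    idx <- which(out$rank == rank)
    out$best_f1[idx[which.max(out$mean_f1[idx])]] <- TRUE
  }
  out
}
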