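# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference database
#'
#' Builds a fixture database of `n_species` species with random sequences
#' and a consistent synthetic taxonomy (each genus nested under one
#' family, order, class and phylum; the last phylum is filed under
#' Archaea, the rest under Bacteria). All randomness flows through `seed`;
#' identical seeds give identical databases.
#'
#' With `with_overlaps = TRUE` the database additionally contains one
#' identical-sequence pair (same taxonomy) and one substring pair whose
#' shorter member carries a different species of the same genus — the
#' cases exercised by merging, dereplication and clustering.
#'
#' @param n_species number of species entries.
#' @param seed integer seed.
#' @param with_overlaps add the engineered duplicate/substring entries.
#' @param seq_length_range insert length range for the random sequences.
#' @return reference-database data.frame (`source = "synthetic"`).
#' @export
generate_fixture_database <- function(n_species, seed = 1L,
                                      with_overlaps = FALSE,
                                      seq_length_range = c(400L, 800L)) {
  stopifnot(n_species >= 1L)
  .with_seed(seed, {
    n_genera <- max(4L, ceiling(sqrt(n_species)))
    n_families <- max(2L, ceiling(n_genera / 3))
    n_orders <- max(2L, ceiling(n_families / 2))
    n_classes <- max(2L, ceiling(n_orders / 2))
    n_phyla <- max(2L, min(8L, ceiling(n_classes / 2)))

    genus_of <- function(i) ((i - 1L) %% n_genera) + 1L
    family_of <- function(g) ((g - 1L) %% n_families) + 1L
    order_of <- function(f) ((f - 1L) %% n_orders) + 1L
    class_of <- function(o) ((o - 1L) %% n_classes) + 1L
    phylum_of <- function(cl) ((cl - 1L) %% n_phyla) + 1L

    i <- seq_len(n_species)
    g <- genus_of(i); f <- family_of(g); o <- order_of(f)
    cl <- class_of(o); p <- phylum_of(cl)
    kingdom <- ifelse(p == n_phyla, "Archaea", "Bacteria")
    genus <- sprintf("Genus%03d", g)
    species <- sprintf("%s_sp%04d", genus, i)
    tax <- format_taxonomy(cbind(kingdom,
                                 sprintf("Phylum%02d", p),
                                 sprintf("Class%02d", cl),
                                 sprintf("Order%02d", o),
                                 sprintf("Family%02d", f),
                                 genus, species))
    lens <- sample(seq(seq_length_range[[1]], seq_length_range[[2]]),
                   n_species, replace = TRUE)
    seqs <- vapply(lens, .random_seq, character(1))
    db <- data.frame(id = sprintf("SYN%05d", i), sequence = seqs,
                     taxonomy = tax, source = "synthetic",
                     stringsAsFactors = FALSE)
    if (with_overlaps) {
      dup <- db[1L, ]
      dup$id <- "SYNDUP00001"
      sub <- db[min(2L, nrow(db)), ]
      sub$id <- "SYNSUB00001"
      full <- sub$sequence
      sub$sequence <- substr(full, 26L, nchar(full) - 25L)
      m <- parse_taxonomy(sub$taxonomy)
      m[, "species"] <- paste0(m[, "genus"], "_spvar")
      sub$taxonomy <- format_taxonomy(m)
      db <- rbind(db, dup, sub)
    }
    rownames(db) <- NULL
    db
  })
}

#' Build an in-silico mock community
#'
#' Draws `n_taxa` species (without replacement) from a species-resolved
#' reference database and gives each of the `n_samples` samples its own
#' relative-abundance profile:
#'
#' * `"uniform"` — normalised uniform draws (a flat, even community);
#' * `"lognormal"` — normalised log-normal draws (meanlog 0, sdlog 1), the
#'   skewed profile typical of gut communities.
#'
#' One member sequence represents each species. Identical seeds produce
#' identical communities.
#'
#' @param db reference-database data.frame.
#' @param n_taxa number of species in the community.
#' @param n_samples samples per community (default 5).
#' @param abundance_model `"uniform"` or `"lognormal"`.
#' @param seed integer seed.
#' @param name community name.
#' @return object of class `mock_community`: `members` (data.frame `id`,
#'   `sequence`, `taxonomy`), `composition` (samples x member-ids matrix
#'   of expected relative abundances), `name`, `seed`, `abundance_model`.
#' @export
build_mock_community <- function(db, n_taxa, n_samples = 5L,
                                 abundance_model = c("uniform", "lognormal"),
                                 seed = 1L, name = "mock") {
  abundance_model <- match.arg(abundance_model)
  species <- parse_taxonomy(db$taxonomy)[, "species"]
  resolved <- which(species != "")
  first_of_species <- resolved[!duplicated(species[resolved])]
  if (length(first_of_species) < n_taxa)
    stop("database has only ", length(first_of_species),
         " species-resolved entries; n_taxa = ", n_taxa)
  .with_seed(seed, {
    pick <- sort(sample(first_of_species, n_taxa))
    members <- db[pick, c("id", "sequence", "taxonomy"), drop = FALSE]
    rownames(members) <- NULL
    draw <- switch(abundance_model,
                   uniform = function(n) runif(n),
                   lognormal = function(n) exp(rnorm(n, 0, 1)))
    comp <- t(vapply(seq_len(n_samples), function(s) {
      a <- draw(n_taxa)
      a / sum(a)
    }, numeric(n_taxa)))
    if (n_taxa == 1L) comp <- matrix(comp, ncol = 1L)
    dimnames(comp) <- list(sprintf("sample%d", seq_len(n_samples)),
                           members$id)
    structure(list(name = name, members = members, composition = comp,
                   seed = seed, abundance_model = abundance_model),
              class = "mock_community")
  })
}

#' Expected composition of a mock community at one rank
#'
#' Aggregates the per-member expected abundances by the members' label at
#' `rank`.
#'
#' @param mock a [build_mock_community()] object.
#' @param rank one of [tax_ranks()].
#' @return samples x rank-labels abundance matrix (rows sum to 1).
#' @export
expected_composition <- function(mock, rank = "species") {
  rank <- match.arg(rank, tax_ranks())
  labels <- parse_taxonomy(mock$members$taxonomy)[, rank]
  agg <- t(rowsum(t(mock$composition), group = labels))
  agg[, order(colnames(agg)), drop = FALSE]
}

#' @export
print.mock_community <- function(x, ...) {
  cat(sprintf("Mock community '%s': %d taxa, %d samples (%s abundances, seed %d)\n",
              x$name, nrow(x$members), nrow(x$composition),
              x$abundance_model, x$seed))
  invisible(x)
}

#' Write mock-community artifacts to a directory
#'
#' Emits the member FASTA, the expected-taxonomy TSV and one composition
#' TSV per rank.
#'
#' @param mock a [build_mock_community()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mock_community <- function(mock, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(mock$members, file.path(dir, "members.fasta"))
  write_taxonomy_table(setNames(mock$members$taxonomy, mock$members$id),
                       file.path(dir, "expected-taxonomy.tsv"))
  for (rank in tax_ranks())
    write_composition_table(expected_composition(mock, rank),
                            file.path(dir, sprintf("composition-%s.tsv", rank)))
  invisible(dir)
}

#' Simulate classifier output for a mock community
#'
#' A perturbed oracle: each member sequence receives its true taxonomy
#' with probability `1 - error_rate - unassigned_rate`, a uniformly drawn
#' *wrong* taxonomy from the database with probability `error_rate`, and
#' an empty (unassigned) label with probability `unassigned_rate`.
#'
#' @param mock a [build_mock_community()] object.
#' @param db the reference database the wrong labels are drawn from.
#' @param error_rate,unassigned_rate probabilities in `[0, 1]` with
#'   `error_rate + unassigned_rate <= 1`.
#' @param seed integer seed.
#' @return assignment table: data.frame `id`, `taxonomy` (empty string =
#'   unassigned).
#' @export
simulate_assignment <- function(mock, db, error_rate = 0,
                                unassigned_rate = 0, seed = 1L) {
  if (error_rate < 0 || unassigned_rate < 0 ||
      error_rate + unassigned_rate > 1)
    stop("error_rate and unassigned_rate must be non-negative and sum to <= 1")
  truth <- mock$members$taxonomy
  pool <- unique(db$taxonomy)
  .with_seed(seed, {
    u <- runif(length(truth))
    assigned <- truth
    wrong <- which(u < error_rate)
    for (i in wrong) {
      alt <- pool[pool != truth[[i]]]
      if (!length(alt))
        stop("database has no alternative taxonomy to misassign")
      assigned[[i]] <- sample(alt, 1L)
    }
    assigned[u >= error_rate & u < error_rate + unassigned_rate] <- ""
    data.frame(id = mock$members$id, taxonomy = assigned,
               stringsAsFactors = FALSE)
  })
}
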