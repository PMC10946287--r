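#' @importFrom utils read.delim write.table head tail
#' @importFrom stats setNames rnorm runif sd
NULL

#' Taxonomic ranks used throughout the package
#'
#' Seven ranks, kingdom through species, with their Greengenes-style
#' single-letter prefixes (`k__` ... `s__`).
#'
#' @format `tax_ranks()` returns a character vector of rank names;
#'   `tax_prefixes()` the matching prefixes.
#' @export
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' @rdname tax_ranks
#' @export
tax_prefixes <- function() {
  paste0(c("k", "p", "c", "o", "f", "g", "s"), "__")
}

# 15-letter IUPAC nucleotide alphabet (includes N)
.iupac_letters <- function() names(Biostrings::IUPAC_CODE_MAP)

.seq_regex <- function() paste0("^[", paste(.iupac_letters(), collapse = ""), "]+$")

#' Parse Greengenes-style taxonomy strings
#'
#' Converts semicolon-separated, prefixed lineage strings
#' (`"k__Bacteria; p__Firmicutes; ..."`) into a seven-column character
#' matrix, one row per input string, columns named after [tax_ranks()].
#' Prefixes are stripped; absent ranks become empty labels. Prefixes must
#' appear in canonical order (kingdom to species); an out-of-order or
#' unknown prefix is an error.
#'
#' @param x character vector of lineage strings.
#' @return character matrix with `length(x)` rows and 7 columns.
#' @examples
#' parse_taxonomy("k__Bacteria; p__Firmicutes; c__Bacilli")
#' @seealso [format_taxonomy()] for the inverse.
#' @export
parse_taxonomy <- function(x) {
  stopifnot(is.character(x))
  prefixes <- tax_prefixes()
  out <- matrix("", nrow = length(x), ncol = 7L,
                dimnames = list(NULL, tax_ranks()))
  for (i in seq_along(x)) {
    tokens <- strsplit(x[[i]], ";", fixed = TRUE)[[1]]
    tokens <- trimws(tokens)
    # tolerate a trailing separator
    while (length(tokens) && tokens[length(tokens)] == "")
      tokens <- tokens[-length(tokens)]
    last_rank <- 0L
    for (tok in tokens) {
      if (nchar(tok) < 3L || substr(tok, 2L, 3L) != "__")
        stop("unparseable taxonomy token '", tok, "' in '", x[[i]], "'")
      rank <- match(substr(tok, 1L, 3L), prefixes)
      if (is.na(rank))
        stop("unknown rank prefix in token '", tok, "' of '", x[[i]], "'")
      if (rank <= last_rank)
        stop("rank prefix out of order in '", x[[i]], "'")
      out[i, rank] <- substr(tok, 4L, nchar(tok))
      last_rank <- rank
    }
  }
  out
}

#' Format a taxonomy matrix back into lineage strings
#'
#' Inverse of [parse_taxonomy()]: always emits all seven prefixed ranks so
#' that `parse_taxonomy(format_taxonomy(m))` reproduces `m` exactly.
#'
#' @param m character matrix with 7 columns (or a length-7 character vector).
#' @return character vector of lineage strings.
#' @export
format_taxonomy <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  stopifnot(ncol(m) == 7L)
  apply(m, 1L, function(row) paste0(tax_prefixes(), row, collapse = "; "))
}

.scan_fasta_structure <- function(lines) {
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      seen_header <- TRUE
    } else if (!seen_header) {
      stop("malformed FASTA: sequence data before any header at line ", i)
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file into a reference-database data frame
#'
#' Headers are truncated at the first whitespace to form the record id;
#' sequences are uppercased and RNA `U` is mapped to `T`. Sequences must be
#' non-empty and drawn from the 15-letter IUPAC nucleotide alphabet; ids
#' must be unique within the file.
#'
#' @param path FASTA file.
#' @param source optional provenance label stored in the `source` column.
#' @return data.frame with columns `id`, `sequence`, `source`.
#' @export
read_fasta <- function(path, source = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  .scan_fasta_structure(readLines(path, warn = FALSE))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("Uu", "Tt", as.character(set))
  seqs <- toupper(seqs)
  bad <- !grepl(.seq_regex(), seqs)
  if (length(seqs) && any(bad))
    stop("non-IUPAC characters in sequence(s): ",
         paste(head(ids[bad], 5L), collapse = ", "))
  data.frame(id = as.character(ids), sequence = unname(seqs),
             source = rep(source, length(ids)), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = max(1L, width))
  invisible(path)
}

#' Read a two-column taxonomy table
#'
#' Tab-separated id/lineage pairs, with or without the conventional
#' `"Feature ID<TAB>Taxon"` header. Every lineage is validated with
#' [parse_taxonomy()]; a record that fails to parse is reported by id.
#'
#' @param path TSV file.
#' @return named character vector: ids as names, canonical formatted
#'   lineage strings as values.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(strsplit(lines[[1]], "\t")[[1]][1]),
                                 "feature id"))
    lines <- lines[-1L]
  if (!length(lines)) return(setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("taxonomy table rows must have two tab-separated columns")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate id(s) in taxonomy table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tax <- vapply(parts, `[[`, "", 2L)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    m <- tryCatch(parse_taxonomy(tax[[i]]),
                  error = function(e)
                    stop("unparseable taxonomy for id '", ids[[i]], "': ",
                         conditionMessage(e), call. = FALSE))
    out[[i]] <- format_taxonomy(m)
  }
  setNames(out, ids)
}

#' Write a taxonomy table
#'
#' Always emits the `"Feature ID<TAB>Taxon"` header.
#'
#' @param taxonomy named character vector (ids -> lineage strings).
#' @param path output file.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Feature ID\tTaxon", con)
  if (length(taxonomy))
    writeLines(paste(names(taxonomy), unname(taxonomy), sep = "\t"), con)
  invisible(path)
}

#' Construct a synonym map
#'
#' A synonym map resolves taxon names to canonical (NCBI-convention) names,
#' carrying the numeric taxonomy id and the kingdom of the canonical
#' lineage. Canonical names always map to themselves; self-mappings are
#' added when absent.
#'
#' @param name,canonical,taxid,kingdom parallel vectors describing one
#'   synonym entry each.
#' @return object of class `synonym_map` (a data.frame).
#' @export
synonym_map <- function(name = character(0), canonical = character(0),
                        taxid = character(0), kingdom = character(0)) {
  df <- data.frame(name = as.character(name),
                   canonical = as.character(canonical),
                   taxid = as.character(taxid),
                   kingdom = as.character(kingdom),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df$name)
  if (any(dup)) {
    clash <- vapply(unique(df$name[dup]), function(n) {
      length(unique(df$canonical[df$name == n])) > 1L
    }, logical(1))
    if (any(clash))
      stop("name(s) mapped to more than one canonical: ",
           paste(unique(df$name[dup])[clash], collapse = ", "))
    df <- df[!dup, , drop = FALSE]
  }
  missing_self <- setdiff(df$canonical, df$name)
  if (length(missing_self)) {
    idx <- match(missing_self, df$canonical)
    df <- rbind(df, data.frame(name = missing_self,
                               canonical = missing_self,
                               taxid = df$taxid[idx],
                               kingdom = df$kingdom[idx],
                               stringsAsFactors = FALSE))
  }
  bad <- df$name %in% df$canonical & df$name != df$canonical
  if (any(bad))
    stop("canonical name(s) remapped elsewhere: ",
         paste(df$name[bad], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("synonym_map", "data.frame")
  df
}

#' Read a synonym table
#'
#' Four tab-separated columns: name, canonical name, NCBI taxid, kingdom of
#' the canonical lineage. A header line starting with `name` (any case) is
#' skipped.
#'
#' @param path TSV file.
#' @return a [synonym_map()].
#' @export
read_synonym_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && tolower(strsplit(lines[[1]], "\t")[[1]][1]) == "name")
    lines <- lines[-1L]
  if (!length(lines)) return(synonym_map())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    stop("synonym table rows must have four tab-separated columns")
  synonym_map(name = vapply(parts, `[[`, "", 1L),
              canonical = vapply(parts, `[[`, "", 2L),
              taxid = vapply(parts, `[[`, "", 3L),
              kingdom = vapply(parts, `[[`, "", 4L))
}

#' Write a synonym map to TSV
#' @param map a [synonym_map()].
#' @param path output file.
#' @export
write_synonym_table <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("name\tcanonical\ttaxid\tkingdom", con)
  if (nrow(map))
    writeLines(paste(map$name, map$canonical, map$taxid, map$kingdom,
                     sep = "\t"), con)
  invisible(path)
}

#' Look up names in a synonym map
#'
#' Lookup is case-sensitive on the stored keys; names that miss are retried
#' case-insensitively (first match wins). Unknown names yield `NA`, never an
#' error.
#'
#' @param map a [synonym_map()].
#' @param names character vector of taxon names.
#' @param field which attribute of the matched entry to return.
#' @return character vector, `NA` where the name is absent.
#' @export
synonym_lookup <- function(map, names,
                           field = c("canonical", "kingdom", "taxid")) {
  field <- match.arg(field)
  idx <- match(names, map$name)
  miss <- is.na(idx) & !is.na(names)
  if (any(miss))
    idx[miss] <- match(tolower(names[miss]), tolower(map$name))
  out <- rep(NA_character_, length(names))
  hit <- !is.na(idx)
  out[hit] <- map[[field]][idx[hit]]
  out
}

#' Read / write relative-abundance composition tables
#'
#' TSV layout: first column sample id, remaining columns taxon labels,
#' cells relative abundances. Per-sample abundances must be non-negative
#' and sum to 1 within `1e-9` (checked unless `check = FALSE`).
#'
#' @param path TSV file.
#' @param check validate the sum-to-one invariant.
#' @return numeric matrix, samples in rows, taxa in columns.
#' @export
read_composition_table <- function(path, check = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1L]])
  if (check) .check_composition(m)
  m
}

.check_composition <- function(m) {
  if (any(m < 0)) stop("negative abundance in composition table")
  s <- rowSums(m)
  if (length(s) && any(abs(s - 1) > 1e-9))
    stop("sample abundances do not sum to 1: ",
         paste(rownames(m)[abs(s - 1) > 1e-9], collapse = ", "))
  invisible(m)
}

#' @rdname read_composition_table
#' @param m numeric matrix, samples in rows, taxa in columns.
#' @export
write_composition_table <- function(m, path, check = TRUE) {
  if (check) .check_composition(m)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a reference database from FASTA + taxonomy TSV
#'
#' The central in-memory container of the package: a data.frame with one
#' row per reference entry and columns `id`, `sequence`, `taxonomy`
#' (formatted 7-rank lineage) and `source`. Every sequence id must have a
#' taxonomy entry and vice versa.
#'
#' @param fasta path to the sequence FASTA.
#' @param taxonomy path to the two-column taxonomy TSV.
#' @param source provenance label.
#' @return reference-database data.frame.
#' @export
read_refdb <- function(fasta, taxonomy, source = NA_character_) {
  seqs <- read_fasta(fasta, source = source)
  tax <- read_taxonomy_table(taxonomy)
  missing_tax <- setdiff(seqs$id, names(tax))
  if (length(missing_tax))
    stop("id(s) without taxonomy: ", paste(head(missing_tax, 5L), collapse = ", "))
  seqs$taxonomy <- unname(tax[seqs$id])
  seqs[, c("id", "sequence", "taxonomy", "source")]
}

#' Write a reference database as a FASTA + taxonomy TSV pair
#'
#' @param db reference-database data.frame.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.tax.tsv`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_refdb <- function(db, prefix) {
  fa <- paste0(prefix, ".fasta")
  tx <- paste0(prefix, ".tax.tsv")
  write_fasta(db, fa)
  write_taxonomy_table(setNames(db$taxonomy, db$id), tx)
  invisible(c(fasta = fa, taxonomy = tx))
}
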