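#' Define a hypervariable-region primer pair
#'
#' The reverse primer is given 5'→3' on the reverse strand, as primers are
#' conventionally written; extraction matches its reverse complement on
#' the forward strand. Length bounds apply to the extracted insert
#' (primers excluded).
#'
#' @param region_name e.g. `"V4"`.
#' @param forward,reverse IUPAC primer strings.
#' @param min_length,max_length accepted insert length range (nt).
#' @param max_mismatch mismatches tolerated per primer site (default 0).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(region_name, forward, reverse,
                        min_length = 1L, max_length = .Machine$integer.max,
                        max_mismatch = 0L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  ok <- grepl(.seq_regex(), c(forward, reverse))
  if (!all(ok)) stop("primers must be non-empty IUPAC nucleotide strings")
  stopifnot(min_length <= max_length)
  structure(list(region_name = region_name, forward = forward,
                 reverse = reverse, min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' Built-in primer sets for the common 16S regions
#'
#' Conventional primer choices for the four regions most used in amplicon
#' studies: V4 (515F/806R), V1–V3 (27F/534R), V3–V4 (341F/805R) and V3–V5
#' (357F/926R). Length bounds bracket the typical amplicon insert sizes.
#' These are defaults, not the only valid choices — override with your
#' own [primer_pair()] or a YAML primer config where your protocol
#' differs.
#'
#' @return named list of [primer_pair()] objects.
#' @export
default_primer_sets <- function() {
  list(
    "V4" = primer_pair("V4", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT",
                       min_length = 200L, max_length = 320L),
    "V1-V3" = primer_pair("V1-V3", "AGAGTTTGATCMTGGCTCAG", "ATTACCGCGGCTGCTGG",
                          min_length = 350L, max_length = 620L),
    "V3-V4" = primer_pair("V3-V4", "CCTACGGGNGGCWGCAG", "GACTACHVGGGTATCTAATCC",
                          min_length = 300L, max_length = 560L),
    "V3-V5" = primer_pair("V3-V5", "CCTACGGGAGGCAGCAG", "CCGTCAATTCMTTTRAGT",
                          min_length = 350L, max_length = 700L))
}

#' Read primer pairs from a YAML config
#'
#' Expected layout: a mapping of region name to fields `forward`,
#' `reverse`, and optionally `min_length`, `max_length`, `max_mismatch`.
#'
#' @param path YAML file.
#' @return named list of [primer_pair()] objects.
#' @export
read_primer_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(region) {
    p <- cfg[[region]]
    primer_pair(region, p$forward, p$reverse,
                min_length = p$min_length %||% 1L,
                max_length = p$max_length %||% .Machine$integer.max,
                max_mismatch = p$max_mismatch %||% 0L)
  })
  setNames(out, names(cfg))
}

#' Reverse-complement a DNA string
#' @param x character DNA string (IUPAC letters).
#' @return reverse complement as a character string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Match a degenerate primer against an equal-length window
#'
#' A window position matches when the window base belongs to the IUPAC set
#' of the primer letter at that position (`N` matches any base). `TRUE`
#' when the number of non-matching positions is at most `max_mismatch`.
#'
#' @param primer,window equal-length IUPAC strings.
#' @param max_mismatch allowed mismatches.
#' @export
iupac_match <- function(primer, window, max_mismatch = 0L) {
  if (nchar(primer) != nchar(window))
    stop("primer and window must have equal length")
  p <- strsplit(toupper(primer), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[p], "")
  mism <- sum(!mapply(function(set, base) base %in% set, sets, w))
  mism <= max_mismatch
}

# Leftmost primer hits on one strand; NA if the pair is not found in order.
.locate_insert <- function(seq, fwd, rev_rc, max_mismatch) {
  subject <- Biostrings::DNAString(seq)
  f <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subject,
                                max.mismatch = max_mismatch, fixed = FALSE)
  if (!length(f)) return(NULL)
  f_end <- Biostrings::end(f)[[1L]]
  r <- Biostrings::matchPattern(Biostrings::DNAString(rev_rc), subject,
                                max.mismatch = max_mismatch, fixed = FALSE)
  starts <- Biostrings::start(r)
  starts <- starts[starts > f_end]
  if (!length(starts)) return(NULL)
  c(f_end + 1L, min(starts) - 1L)
}

#' Extract a hypervariable region from one sequence
#'
#' Locates the forward primer on the forward strand and the reverse
#' complement of the reverse primer downstream of it, and returns the
#' subsequence strictly between the two primer sites (primers excluded,
#' leftmost hits win). If the pair is not found, the reverse complement of
#' the record is searched. Returns `NA` when no hit is found or the insert
#' length falls outside the pair's bounds.
#'
#' @param sequence character DNA string.
#' @param pair a [primer_pair()].
#' @param max_mismatch override of the pair's mismatch tolerance.
#' @return the extracted insert, or `NA_character_` when absent.
#' @export
extract_region <- function(sequence, pair,
                           max_mismatch = pair$max_mismatch) {
  rev_rc <- reverse_complement(pair$reverse)
  hit <- .locate_insert(sequence, pair$forward, rev_rc, max_mismatch)
  seq_used <- sequence
  if (is.null(hit)) {
    seq_used <- reverse_complement(sequence)
    hit <- .locate_insert(seq_used, pair$forward, rev_rc, max_mismatch)
  }
  if (is.null(hit) || hit[[2L]] < hit[[1L]]) return(NA_character_)
  insert <- substr(seq_used, hit[[1L]], hit[[2L]])
  if (nchar(insert) < pair$min_length || nchar(insert) > pair$max_length)
    return(NA_character_)
  insert
}

#' Extract a region across a whole database
#'
#' Taxonomy and provenance are carried over unchanged; entries whose
#' extraction is absent are dropped and counted.
#'
#' @param db reference-database data.frame.
#' @param pair a [primer_pair()].
#' @param max_mismatch override of the pair's mismatch tolerance.
#' @return list with `db` (extracted entries) and `dropped` (count).
#' @export
extract_region_db <- function(db, pair, max_mismatch = pair$max_mismatch) {
  if (!nrow(db))
    return(list(db = db, dropped = 0L))
  inserts <- vapply(db$sequence, extract_region, character(1),
                    pair = pair, max_mismatch = max_mismatch,
                    USE.NAMES = FALSE)
  keep <- !is.na(inserts)
  out <- db[keep, , drop = FALSE]
  out$sequence <- inserts[keep]
  rownames(out) <- NULL
  list(db = out, dropped = sum(!keep))
}

#' Remove exactly redundant entries
#'
#' Entries with identical (sequence, taxonomy) pairs collapse to the
#' first-seen one. Identical sequences carrying *different* taxonomies are
#' all retained — resolving those is the job of [cluster_database()].
#'
#' @param db reference-database data.frame.
#' @return dereplicated database (subset of the input rows, order kept).
#' @export
dereplicate <- function(db) {
  key <- paste(db$sequence, db$taxonomy, sep = "\r")
  out <- db[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
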