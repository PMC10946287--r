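# Shared generators and independent brute-force oracles.
# Oracles deliberately use plain loops and substr() scanning so they share
# no code path with the implementation they check.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent containment check: a occurs as contiguous substring of b
oracle_contained <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la > lb || la == 0L) return(FALSE)
  for (i in seq_len(lb - la + 1L))
    if (substr(b, i, i + la - 1L) == a) return(TRUE)
  FALSE
}

# independent re-derivation of the candidate-integration algorithm
oracle_merge <- function(reference, candidate) {
  tax <- reference$taxonomy
  seqs <- reference$sequence
  added <- logical(nrow(candidate))
  for (i in seq_len(nrow(candidate))) {
    tc <- candidate$taxonomy[[i]]
    sc <- candidate$sequence[[i]]
    same <- which(tax == tc)
    dup <- FALSE
    for (j in same) if (oracle_contained(sc, seqs[[j]])) { dup <- TRUE; break }
    if (!dup) {
      tax <- c(tax, tc); seqs <- c(seqs, sc); added[[i]] <- TRUE
    }
  }
  list(size = length(tax), added = added)
}

# independent per-taxon confusion tallies via a double loop over
# scalar names_match() calls
oracle_confusion <- function(e_lab, a_lab) {
  taxa <- sort(setdiff(unique(c(e_lab, a_lab)), ""))
  rows <- lapply(taxa, function(t) {
    tp <- fp <- fn <- tn <- 0L
    for (k in seq_along(e_lab)) {
      me <- e_lab[[k]] != "" && names_match(t, e_lab[[k]])
      ma <- a_lab[[k]] != "" && names_match(t, a_lab[[k]])
      if (me && ma) tp <- tp + 1L
      else if (ma) fp <- fp + 1L
      else if (me) fn <- fn + 1L
      else tn <- tn + 1L
    }
    data.frame(taxon = t, TP = tp, FP = fp, FN = fn, TN = tn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# IUPAC nucleotide table written out independently of Biostrings
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

oracle_iupac_match <- function(primer, window, max_mismatch) {
  p <- strsplit(primer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  mism <- 0L
  for (i in seq_along(p))
    if (!(w[[i]] %in% oracle_iupac[[p[[i]]]])) mism <- mism + 1L
  mism <= max_mismatch
}

# small random databases with engineered taxonomy and sequence overlap,
# for exercising every branch of the merge algorithm
rand_merge_db <- function(n, tax_pool, seq_pool) {
  pick_seq <- function() {
    base <- sample(seq_pool, 1L)
    r <- runif(1)
    if (r < 0.4) base
    else if (r < 0.7) {
      l <- nchar(base)
      a <- sample.int(l - 5L, 1L)
      substr(base, a, min(l, a + sample(5:20, 1L)))
    } else rand_dna(sample(20:40, 1L))
  }
  data.frame(id = sprintf("r%04d", seq_len(n)),
             sequence = vapply(seq_len(n), function(i) pick_seq(), ""),
             taxonomy = sample(tax_pool, n, replace = TRUE),
             source = "rand", stringsAsFactors = FALSE)
}

rand_tax_pool <- function(k) {
  format_taxonomy(cbind("Bacteria",
                        sprintf("Phylum%02d", ((seq_len(k) - 1) %% 3) + 1),
                        sprintf("Class%02d", ((seq_len(k) - 1) %% 3) + 1),
                        sprintf("Order%02d", ((seq_len(k) - 1) %% 4) + 1),
                        sprintf("Family%02d", ((seq_len(k) - 1) %% 4) + 1),
                        sprintf("Genus%02d", ((seq_len(k) - 1) %% 5) + 1),
                        sprintf("Genus%02d_sp%03d", ((seq_len(k) - 1) %% 5) + 1,
                                seq_len(k))))
}

# random species-name sets (Genus_epithet form plus plain names) for the
# compress/expand round-trip
rand_species_set <- function(max_n = 8L) {
  genera <- c("Lactobacillus", "Limosilactobacillus", "Bifidobacterium",
              "Prevotella", "Gardnerella")
  epithets <- c("iners", "crispatus", "fermentum", "oris", "gasseri",
                "jensenii", "longum", "bivia", "vaginalis", "amylophilus")
  plain <- c("Bacilli", "Clostridia", "Bacteroidia")
  n <- sample.int(max_n, 1L)
  names <- unique(vapply(seq_len(n), function(i) {
    if (runif(1) < 0.15) sample(plain, 1L)
    else paste(sample(genera, 1L), sample(epithets, 1L), sep = "_")
  }, ""))
  names
}

# concrete realisation of a degenerate primer (first letter of each set)
concretize_primer <- function(primer) {
  p <- strsplit(primer, "")[[1]]
  paste(vapply(p, function(ch) oracle_iupac[[ch]][[1]], ""), collapse = "")
}

# PAD + FWD + insert + revcomp(REV) + PAD around a given insert
embed_insert <- function(insert, pair, pad = 50L) {
  paste0(rand_dna(pad), concretize_primer(pair$forward), insert,
         reverse_complement(concretize_primer(pair$reverse)), rand_dna(pad))
}

# the three Lactobacillaceae lineages of the clustering worked example
# (input genus spelling normalised to "Lactobacillus")
lacto_lineages <- function() c(
  "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Limosilactobacillus; s__Limosilactobacillus_fermentum",
  "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Limosilactobacillus; s__Limosilactobacillus_oris",
  "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Lactobacillus; s__Lactobacillus_crispatus")

lacto_clustered <- function() paste0(
  "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; ",
  "f__Lactobacillaceae; g__Lactobacillus-Limosilactobacillus; ",
  "s__Lactobacillus_crispatus:Limosilactobacillus_fermentum-oris")
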