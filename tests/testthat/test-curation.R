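make_entry <- function(id, tax, seq = "ACGTACGTACGT") {
  data.frame(id = id, sequence = seq, taxonomy = tax, source = "t",
             stringsAsFactors = FALSE)
}

full_tax <- function(kingdom = "Bacteria", species = "Genus_sp",
                     genus = "Genus", phylum = "Phylum", class = "Class",
                     order = "Order", family = "Family") {
  format_taxonomy(cbind(kingdom, phylum, class, order, family, genus, species))
}

test_that("kingdom filter keeps only allowed kingdoms, in order", {
  db <- rbind(make_entry("a", full_tax("Bacteria")),
              make_entry("b", full_tax("Eukaryota")),
              make_entry("c", full_tax("Archaea")))
  res <- filter_kingdoms(db)
  expect_equal(res$db$id, c("a", "c"))
  expect_equal(res$removed, 1L)
  expect_equal(filter_kingdoms(db[db$id != "b", ])$removed, 0L)
  empty <- filter_kingdoms(db[0, ])
  expect_equal(nrow(empty$db), 0L)
  expect_equal(empty$removed, 0L)
})

test_that("unknown-label flagging is a literal case-insensitive substring test", {
  expect_true(flag_unknown_labels(full_tax(species = "uncultured_bacterium")))
  expect_true(flag_unknown_labels(full_tax(species = "UNCULTURED_organism")))
  expect_true(flag_unknown_labels(full_tax(genus = "unidentified")))
  expect_false(flag_unknown_labels(full_tax(species = "Limosilactobacillus_fermentum")))
  # empty species is unknown by definition
  expect_true(flag_unknown_labels(full_tax(species = "")))
  # the default pattern list is literal: "candidate" does not hit "Candidatus"
  expect_false(flag_unknown_labels(full_tax(genus = "Candidatus_Saccharibacteria")))
  expect_true(flag_unknown_labels(
    full_tax(genus = "Candidatus_Saccharibacteria"),
    curation_rules(unknown_patterns = c("uncultured", "unidentified",
                                        "candidate", "candidatus"))))
})

test_that("rank-sparsity flags kingdom+species-only lineages", {
  sparse <- "k__Bacteria; p__; c__; o__; f__; g__; s__bacterium_Te63R"
  expect_true(flag_rank_sparse(sparse))
  expect_false(flag_rank_sparse(full_tax()))
  expect_false(flag_rank_sparse("k__Bacteria"))
  # a single populated intermediate rank rescues the entry
  expect_false(flag_rank_sparse("k__Bacteria; p__Firmicutes; c__; o__; f__; g__; s__x_y"))
})

syn_fixture <- function() synonym_map(
  name = c("Bacteroidota", "Clostridiales", "Cenchrus_americanus",
           "Lactobacillus_fermentum"),
  canonical = c("Bacteroidetes", "Eubacteriales", "Cenchrus_americanus",
                "Limosilactobacillus_fermentum"),
  taxid = c("976", "186802", "301040", "1613"),
  kingdom = c("Bacteria", "Bacteria", "Eukaryota", "Bacteria"))

test_that("synonym unification canonicalises labels, including clustered ones", {
  syn <- syn_fixture()
  res <- unify_taxonomy(full_tax(phylum = "Bacteroidota"), syn)
  expect_true(res$changed)
  expect_equal(parse_taxonomy(res$taxonomy)[1, "phylum"],
               c(phylum = "Bacteroidetes"))

  res <- unify_taxonomy(full_tax(order = "Clostridiales"), syn)
  expect_equal(parse_taxonomy(res$taxonomy)[1, "order"],
               c(order = "Eubacteriales"))

  # unmapped labels pass through; empty map is the identity
  t0 <- full_tax()
  expect_equal(unify_taxonomy(t0, synonym_map())$taxonomy, t0)
  expect_false(unify_taxonomy(t0, syn)$changed)

  # each component of a clustered label is unified independently
  clustered <- "k__Bacteria; p__; c__; o__; f__; g__; s__Gardnerella_vaginalis:Lactobacillus_fermentum"
  res <- unify_taxonomy(clustered, syn)
  expect_equal(parse_taxonomy(res$taxonomy)[1, "species"],
               c(species = "Gardnerella_vaginalis:Limosilactobacillus_fermentum"))

  # per-label purity: unification is the same everywhere a label appears
  many <- rep(full_tax(phylum = "Bacteroidota"), 5)
  out <- unify_taxonomy(many, syn)$taxonomy
  expect_length(unique(out), 1L)
})

test_that("cross-kingdom misannotations are detected via canonical kingdom", {
  syn <- syn_fixture()
  expect_true(detect_cross_kingdom(full_tax(species = "Cenchrus_americanus"), syn))
  expect_false(detect_cross_kingdom(full_tax(species = "Unmapped_species"), syn))
  expect_false(detect_cross_kingdom(full_tax(species = "Lactobacillus_fermentum"), syn))
})

test_that("curate_database applies filters in order with exact accounting", {
  syn <- syn_fixture()
  db <- rbind(
    make_entry("keep1", full_tax(species = "Genus_alpha")),
    make_entry("euk", full_tax(kingdom = "Eukaryota")),
    make_entry("unc", full_tax(species = "uncultured_bacterium")),
    make_entry("sparse", "k__Bacteria; p__; c__; o__; f__; g__; s__bacterium_Te63R"),
    make_entry("plant", full_tax(species = "Cenchrus_americanus")),
    make_entry("keep2", full_tax(phylum = "Bacteroidota", species = "Genus_beta")),
    make_entry("keep3", full_tax(species = "Genus_gamma")),
    make_entry("virus", full_tax(kingdom = "Viruses")),
    make_entry("noid", full_tax(species = "")),
    make_entry("keep4", full_tax(species = "Genus_delta")))
  res <- curate_database(db, synonyms = syn)
  rep <- res$report
  expect_equal(rep$input_count, 10L)
  expect_equal(unname(rep$removed_by_rule),
               c(2L, 2L, 1L, 1L))  # kingdom, unknown, sparse, cross-kingdom
  expect_equal(rep$output_count, 4L)
  expect_equal(rep$input_count, rep$output_count + sum(rep$removed_by_rule))
  expect_equal(res$db$id, c("keep1", "keep2", "keep3", "keep4"))
  expect_equal(rep$renamed_count, 1L)  # Bacteroidota -> Bacteroidetes

  # idempotence: curating a curated database changes nothing
  res2 <- curate_database(res$db, synonyms = syn)
  expect_equal(res2$db, res$db)
  expect_equal(sum(res2$report$removed_by_rule), 0L)

  # all filters disabled: identity transform
  off <- curation_rules(filter_unknown = FALSE, filter_kingdom = FALSE,
                        drop_rank_sparse = FALSE, filter_cross_kingdom = FALSE)
  expect_equal(curate_database(db, off, synonym_map())$db, db)
})

test_that("conservation holds on random fixture databases", {
  for (seed in 1:5) {
    db <- generate_fixture_database(40, seed = seed, with_overlaps = TRUE)
    rep <- curate_database(db)$report
    expect_equal(rep$input_count, rep$output_count + sum(rep$removed_by_rule))
  }
})
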