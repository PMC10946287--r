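test_that("label matching is containment-aware and symmetric", {
  expect_true(names_match("Lactobacillus_iners", "Lactobacillus_iners"))
  expect_false(names_match("Lactobacillus_iners", "Lactobacillus_jensenii"))
  # a clustered assignment matches any of its member names
  expect_true(names_match("Amylolactobacillus_amylophilus-Lactobacillus_iners",
                          "Lactobacillus_iners"))
  expect_true(names_match("Lactobacillus_crispatus:Limosilactobacillus_fermentum-oris",
                          "Limosilactobacillus_oris"))
  expect_false(names_match("Lactobacillus_crispatus:Limosilactobacillus_fermentum-oris",
                           "Limosilactobacillus_reuteri"))
  # the placeholder only matches itself
  expect_true(names_match("Unknown", "Unknown"))
  expect_false(names_match("Unknown", "Lactobacillus_iners"))

  set.seed(101)
  labels <- c("Lactobacillus_iners", "Lactobacillus_jensenii", "Bacilli",
              "Unknown", "Lactobacillus_iners-jensenii",
              "Gardnerella_vaginalis:Lactobacillus_iners")
  for (i in 1:50) {
    a <- sample(labels, 1); e <- sample(labels, 1)
    expect_equal(names_match(a, e), names_match(e, a), info = paste(a, e))
  }
})

test_that("confusion counts reproduce the worked single-taxon frame", {
  # three sequences, all truly L. iners; one misassigned as L. jensenii
  expected <- c(s1 = "Lactobacillus_iners", s2 = "Lactobacillus_iners",
                s3 = "Lactobacillus_crispatus")
  assigned <- c(s1 = "Lactobacillus_iners", s2 = "Lactobacillus_jensenii",
                s3 = "Lactobacillus_crispatus")
  counts <- confusion_counts(expected, assigned)
  row <- function(t) counts[counts$taxon == t, ]
  # the misassigned iners is an FN for iners, an FP for jensenii, and the
  # crispatus sequence is a TN for both
  expect_equal(unname(unlist(row("Lactobacillus_iners")[, c("TP", "FP", "FN", "TN")])),
               c(1L, 0L, 1L, 1L))
  expect_equal(unname(unlist(row("Lactobacillus_jensenii")[, c("TP", "FP", "FN", "TN")])),
               c(0L, 1L, 0L, 2L))
  expect_equal(unname(unlist(row("Lactobacillus_crispatus")[, c("TP", "FP", "FN", "TN")])),
               c(1L, 0L, 0L, 2L))
  # every taxon's tallies sum to the number of evaluated sequences
  expect_true(all(rowSums(counts[, c("TP", "FP", "FN", "TN")]) == 3L))

  perfect <- confusion_counts(expected, expected)
  expect_true(all(perfect$FP == 0L & perfect$FN == 0L))

  expect_error(confusion_counts(expected, assigned[1:2]), "same sequence ids")
})

test_that("confusion counts match the brute-force double loop on random tables", {
  set.seed(111)
  label_pool <- c("Lactobacillus_iners", "Lactobacillus_jensenii",
                  "Gardnerella_vaginalis", "Prevotella_bivia",
                  "Lactobacillus_iners-jensenii",
                  "Gardnerella_vaginalis:Prevotella_bivia")
  for (trial in 1:40) {
    n <- 20L
    ids <- sprintf("s%02d", seq_len(n))
    e <- setNames(sample(label_pool[1:4], n, TRUE), ids)
    a <- setNames(sample(c(label_pool, ""), n, TRUE,
                         prob = c(rep(1, 6), 0.5)), ids)
    got <- confusion_counts(e, a)
    got <- got[order(got$taxon), ]
    ora <- oracle_confusion(unname(e), unname(a))
    expect_equal(got$TP, ora$TP)
    expect_equal(got$FP, ora$FP)
    expect_equal(got$FN, ora$FN)
    expect_equal(got$TN, ora$TN)
    expect_true(all(rowSums(got[, c("TP", "FP", "FN", "TN")]) == n))
  }
})

test_that("metrics follow the standard confusion-matrix definitions", {
  m <- metrics_from_counts(data.frame(taxon = "t", TP = 3L, FP = 1L,
                                      FN = 1L, TN = 5L))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  expect_false(m$precision_undefined)

  perfect <- metrics_from_counts(data.frame(taxon = "t", TP = 4L, FP = 0L,
                                            FN = 0L, TN = 6L))
  expect_equal(unlist(perfect[, c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # 0/0 ratios return 0 and are flagged
  degen <- metrics_from_counts(data.frame(taxon = "t", TP = 0L, FP = 0L,
                                          FN = 2L, TN = 8L))
  expect_equal(degen$precision, 0)
  expect_true(degen$precision_undefined)
  expect_false(degen$recall_undefined)
  expect_true(degen$f1_undefined)
})

test_that("weighted means reduce correctly and stay bounded", {
  expect_equal(weighted_mean_score(c(1, 0), c(0.9, 0.1)), 0.9)
  expect_equal(weighted_mean_score(c(0.2, 0.4, 0.9), rep(1 / 3, 3)),
               mean(c(0.2, 0.4, 0.9)))
  set.seed(121)
  for (i in 1:50) {
    s <- runif(10); w <- runif(10)
    got <- weighted_mean_score(s, w)
    expect_equal(got, sum(s * w) / sum(w))   # independent dot-product form
    expect_gte(got, min(s)); expect_lte(got, max(s))
  }
  expect_true(is.na(weighted_mean_score(c(1, 1), c(0, 0))))
  expect_error(weighted_mean_score(c(1, 1), c(-1, 2)), "non-negative")
})

test_that("Bray-Curtis distance has its closed-form values and symmetry", {
  e <- c(A = 0.5, B = 0.5)
  expect_equal(bray_curtis(e, e), 0)
  expect_equal(bray_curtis(c(A = 1), c(B = 1)), 1)
  expect_equal(bray_curtis(c(A = 0.5, B = 0.5), c(A = 1.0)), 0.5)
  set.seed(131)
  for (i in 1:30) {
    x <- runif(5); y <- runif(5)
    x <- setNames(x / sum(x), LETTERS[1:5])
    y <- setNames(y / sum(y), LETTERS[3:7])
    d1 <- bray_curtis(x, y)
    expect_equal(d1, bray_curtis(y, x))
    expect_gte(d1, 0); expect_lte(d1, 1)
    # independent closed form over the union
    taxa <- union(names(x), names(y))
    xv <- setNames(numeric(7), taxa); yv <- xv
    xv[names(x)] <- x; yv[names(y)] <- y
    expect_equal(d1, 1 - 2 * sum(pmin(xv, yv)) / (sum(xv) + sum(yv)))
  }
})

test_that("a zero-error assignment evaluates as perfect", {
  db <- generate_fixture_database(60, seed = 19)
  mock <- build_mock_community(db, n_taxa = 20, seed = 4)
  res <- evaluate_dataset(mock, simulate_assignment(mock, db, 0, 0, seed = 1))
  expect_equal(nrow(res$summary), 5L * 7L)    # samples x ranks
  expect_true(all(res$summary$f1 == 1))
  expect_true(all(res$summary$bray_curtis == 0))
  expect_true(all(res$per_taxon$FP == 0L & res$per_taxon$FN == 0L))
})

test_that("evaluation recovers a known perturbation rate at the species level", {
  db <- generate_fixture_database(900, seed = 20)
  mock <- build_mock_community(db, n_taxa = 600, seed = 6)
  rate <- 0.25
  asn <- simulate_assignment(mock, db, error_rate = rate, seed = 13)
  res <- evaluate_dataset(mock, asn, ranks = "species")
  se <- sqrt(rate * (1 - rate) / 600)
  expect_lt(abs(mean(res$summary$recall) - (1 - rate)), 3 * se)
})

test_that("unassigned mass appears as its own composition label", {
  db <- generate_fixture_database(30, seed = 21)
  mock <- build_mock_community(db, n_taxa = 10, seed = 2)
  asn <- simulate_assignment(mock, db, unassigned_rate = 1, seed = 1)
  res <- evaluate_dataset(mock, asn, ranks = "species")
  # nothing assigned: recall 0 everywhere, disjoint compositions
  expect_true(all(res$summary$recall == 0))
  expect_true(all(res$summary$bray_curtis == 1))
})

test_that("synonym unification is applied to both sides before comparison", {
  syn <- synonym_map(name = "Lactobacillus_fermentum",
                     canonical = "Limosilactobacillus_fermentum",
                     taxid = "1613", kingdom = "Bacteria")
  db <- generate_fixture_database(20, seed = 22)
  mock <- build_mock_community(db, n_taxa = 5, seed = 3)
  m <- parse_taxonomy(mock$members$taxonomy)
  m[1, "species"] <- "Lactobacillus_fermentum"
  mock$members$taxonomy <- format_taxonomy(m)
  asn <- data.frame(id = mock$members$id,
                    taxonomy = mock$members$taxonomy,
                    stringsAsFactors = FALSE)
  am <- parse_taxonomy(asn$taxonomy)
  am[1, "species"] <- "Limosilactobacillus_fermentum"
  asn$taxonomy <- format_taxonomy(am)
  # without unification the first member mismatches; with it, perfect
  res_plain <- evaluate_dataset(mock, asn, ranks = "species")
  expect_true(any(res_plain$summary$f1 < 1))
  res_uni <- evaluate_dataset(mock, asn, synonyms = syn, ranks = "species")
  expect_true(all(res_uni$summary$f1 == 1))
})

test_that("configuration summaries pick the best mean F1 per rank", {
  db <- generate_fixture_database(80, seed = 23)
  mock <- build_mock_community(db, n_taxa = 40, seed = 5)
  good <- evaluate_dataset(mock, simulate_assignment(mock, db, 0.05, seed = 1),
                           ranks = c("genus", "species"))$summary
  bad <- evaluate_dataset(mock, simulate_assignment(mock, db, 0.5, seed = 1),
                          ranks = c("genus", "species"))$summary
  summ <- summarize_configurations(list(lenient = good, strict = bad))
  expect_equal(nrow(summ), 4L)
  best <- summ[summ$best_f1, ]
  expect_true(all(best$configuration == "lenient"))
  # means match an independent recomputation
  for (r in c("genus", "species"))
    expect_equal(summ$mean_f1[summ$configuration == "lenient" & summ$rank == r],
                 mean(good$f1[good$rank == r]))
  solo <- summarize_configurations(list(only = good))
  expect_true(all(solo$best_f1))
})
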