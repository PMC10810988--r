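test_that("CDS negatives are 81 nt windows inside CDS with strand orientation", {
  g <- tiny_genome()
  neg <- sample_cds_negatives(g$contigs, g$annotations, n = 100, seed = 61)
  expect_equal(nrow(neg), 100)
  expect_true(all(nchar(neg$sequence) == 81))
  expect_true(all(neg$label == 0L))
  # minus-strand sampling reverse-complements the genomic slice
  contig <- tibble::tibble(id = "m", sequence = dnalm:::random_dna(200))
  ann <- tibble::tibble(contig_id = "m", start = 10, end = 120, strand = "-",
                        feature_type = "CDS")
  one <- sample_cds_negatives(contig, ann, n = 5, seed = 62)
  for (i in 1:5) {
    raw <- revcomp(one$sequence[i])
    expect_true(grepl(raw, substr(contig$sequence, 10, 120), fixed = TRUE))
  }
  # no eligible CDS errors
  short_ann <- tibble::tibble(contig_id = "m", start = 10, end = 50, strand = "+",
                              feature_type = "CDS")
  expect_error(sample_cds_negatives(contig, short_ann, n = 5), "achievable")
})

test_that("promoter dataset has exact composition, balance, record length and splits", {
  g <- tiny_genome()
  pos <- plant_motif(random_seqs(1000, 81, gc = 0.45, seed = 63), "TTGACATAAT",
                     seed = 64)
  cfg <- promoter_build_config(seed = 65)
  rec <- build_promoter_dataset(pos, g$contigs, g$annotations, cfg)
  expect_equal(nrow(rec), 2000)
  expect_true(all(nchar(rec$sequence) == 81))
  comp <- table(rec$source_class)
  expect_equal(as.integer(comp[c("promoter", "cds_negative", "markov3_negative",
                                 "random0_negative")]),
               c(1000L, 400L, 400L, 200L))
  expect_equal(sum(rec$label == 1), sum(rec$label == 0))
  splits <- table(rec$split)
  expect_equal(as.integer(splits[c("train", "validation", "test")]),
               c(1600L, 200L, 200L))
  # label consistency with source class
  expect_true(all(rec$label[rec$source_class == "promoter"] == 1))
  expect_true(all(rec$label[rec$source_class != "promoter"] == 0))
  # deterministic under the config seed
  rec2 <- build_promoter_dataset(pos, g$contigs, g$annotations, cfg)
  expect_identical(rec, rec2)
})

test_that("largest-remainder apportionment is exact for awkward totals", {
  expect_equal(dnalm:::apportion_largest_remainder(1000, c(0.4, 0.4, 0.2)),
               c(400L, 400L, 200L))
  expect_equal(dnalm:::apportion_largest_remainder(7, c(0.4, 0.4, 0.2)),
               c(3L, 3L, 1L))
  # 13 * (0.8, 0.1, 0.1): quotas (10.4, 1.3, 1.3), the largest remainder
  # belongs to the first part
  x <- dnalm:::apportion_largest_remainder(13, c(0.8, 0.1, 0.1))
  expect_equal(x, c(11L, 1L, 1L))
})

test_that("independent-test exact matches are excluded from the modelling splits", {
  g <- tiny_genome()
  pos <- plant_motif(random_seqs(200, 81, seed = 66), "TTGACATAAT", seed = 67)
  ind <- tibble::tibble(
    id = sprintf("ind_%d", 1:20),
    sequence = c(pos[1:10], random_seqs(10, 81, seed = 68)),
    label = 1L, source_class = "promoter"
  )
  cfg <- promoter_build_config(seed = 69)
  expect_message(
    rec <- build_promoter_dataset(pos, g$contigs, g$annotations, cfg,
                                  independent_test = ind),
    "excluded"
  )
  modelling <- rec[rec$split != "independent_test", ]
  expect_equal(sum(modelling$source_class == "promoter"), 190)
  expect_equal(length(intersect(modelling$sequence,
                                rec$sequence[rec$split == "independent_test"])), 0)
  expect_equal(sum(rec$split == "independent_test"), 20)
})

test_that("wrong-length positives are rejected with a report", {
  g <- tiny_genome()
  pos <- c(random_seqs(50, 81, seed = 70), dnalm:::random_dna(60))
  expect_warning(
    rec <- build_promoter_dataset(pos, g$contigs, g$annotations,
                                  promoter_build_config(seed = 71)),
    "rejected"
  )
  expect_equal(sum(rec$source_class == "promoter"), 50)
})

test_that("exact deduplication keeps first occurrences, optionally rc-aware", {
  s <- "ACGTACGTAA"
  t <- "TTTTCCCCGG"
  rec <- tibble::tibble(id = c("a", "b", "c"), sequence = c(s, s, t), label = 1L)
  expect_equal(deduplicate_exact(rec)$id, c("a", "c"))
  rc <- tibble::tibble(id = c("a", "b"), sequence = c(s, revcomp(s)), label = 1L)
  expect_equal(nrow(deduplicate_exact(rc)), 2)
  expect_equal(deduplicate_exact(rc, revcomp_aware = TRUE)$id, "a")
  empty <- rec[0, ]
  expect_equal(nrow(deduplicate_exact(empty)), 0)
})

test_that("phage dataset enforces the bp cap, upsample bound and parent-level splits", {
  coll <- generate_synthetic_phage_collection(
    n_genera = 3, hosts_per_genus = 2, phages_per_genus = 5,
    host_length_range = c(6000, 9000), phage_length_range = c(3000, 6000),
    seed = 72
  )
  cap <- 12000
  cfg <- phage_build_config(genus_bp_cap = cap, max_upsample_coverage = 2,
                            segment_lengths = c(256, 512), include_revcomp = TRUE,
                            seed = 73)
  rec <- build_phage_dataset(coll$phages, coll$hosts, cfg)
  expect_true(all(rec$label[rec$source_class == "phage"] == 1))
  expect_true(all(rec$label[rec$source_class == "host"] == 0))
  # forward-strand emitted phage bp per genus <= min(cap, 5x source)
  fwd <- rec[!grepl("_rc$", rec$parent_id) & rec$source_class == "phage", ]
  fwd_bp <- tapply(nchar(fwd$sequence), fwd$genus, sum) / 2 # rc doubles records
  src_bp <- tapply(nchar(coll$phages$sequence), coll$phages$host_genus, sum)
  for (gn in names(fwd_bp)) {
    expect_lte(fwd_bp[[gn]], cap)
    expect_lte(fwd_bp[[gn]], 2 * src_bp[[gn]])
  }
  # no parent sequence appears in two splits
  by_parent <- tapply(rec$split, rec$parent_id, function(x) length(unique(x)))
  expect_true(all(by_parent == 1))
  # genus with no host contig is skipped with a warning
  orphan <- dplyr::mutate(coll$phages[1, ], host_genus = "Genus_99")
  expect_warning(
    build_phage_dataset(dplyr::bind_rows(coll$phages, orphan), coll$hosts, cfg),
    "skipped"
  )
  # 10 parent units at 0.8/0.1/0.1 split 8/1/1
  ten <- generate_synthetic_phage_collection(
    n_genera = 1, hosts_per_genus = 1, phages_per_genus = 10,
    host_length_range = c(4000, 5000), phage_length_range = c(2000, 3000),
    seed = 74
  )
  cfg10 <- phage_build_config(genus_bp_cap = 1e6, max_upsample_coverage = 1,
                              segment_lengths = 256, include_revcomp = FALSE,
                              seed = 75)
  rec10 <- build_phage_dataset(ten$phages, ten$hosts, cfg10)
  ph <- rec10[rec10$source_class == "phage", ]
  units <- tapply(ph$split, ph$parent_id, function(x) unique(x))
  expect_equal(sort(as.integer(table(factor(units, c("train", "validation", "test"))))),
               c(1L, 1L, 8L))
})
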