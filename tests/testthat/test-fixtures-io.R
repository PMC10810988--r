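test_that("synthetic genomes are deterministic and within spec bounds", {
  spec <- synthetic_genome_spec(n_contigs = 2, contig_length_range = c(10000, 20000),
                                seed = 7)
  g1 <- generate_synthetic_genome(spec)
  g2 <- generate_synthetic_genome(spec)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$contigs), 2)
  lens <- nchar(g1$contigs$sequence)
  expect_true(all(lens >= 10000 & lens <= 20000))
  lens_by_id <- setNames(lens, g1$contigs$id)
  a <- g1$annotations
  expect_true(all(a$start >= 1 & a$end <= lens_by_id[a$contig_id] & a$start < a$end))
  expect_true(all(a$feature_type %in% c("CDS", "ncRNA", "pseudogene")))
  expect_true(all(a$strand %in% c("+", "-")))
  # same spec -> byte-identical FASTA/GFF3
  d <- withr::local_tempdir()
  write_fasta(g1$contigs, file.path(d, "a.fa")); write_fasta(g2$contigs, file.path(d, "b.fa"))
  expect_identical(readLines(file.path(d, "a.fa")), readLines(file.path(d, "b.fa")))
  # annotated fraction lands near the requested density
  dens <- sum(a$end - a$start + 1) / sum(lens)
  spec5 <- synthetic_genome_spec(n_contigs = 1, contig_length_range = c(10000, 10000),
                                 gene_density = 0.5, seed = 11)
  g5 <- generate_synthetic_genome(spec5)
  cds_bp <- with(subset(g5$annotations, feature_type == "CDS"), sum(end - start + 1))
  expect_gt(cds_bp / 10000, 0.35)
  expect_lt(cds_bp / 10000, 0.65)
  expect_error(synthetic_genome_spec(gene_density = 0), "gene_density")
  expect_error(synthetic_genome_spec(gc_content = 1.2), "gc_content")
})

test_that("FASTA round-trips exactly, normalizes case and rejects bad symbols in strict mode", {
  d <- withr::local_tempdir()
  contigs <- tibble::tibble(
    id = c("c1", "c2", "c3"),
    sequence = c(dnalm:::random_dna(150), "ACGTN", strrep("ACGT", 50))
  )
  p <- file.path(d, "x.fa")
  write_fasta(contigs, p)
  back <- read_fasta(p)
  expect_equal(back, contigs)
  # lowercase input is uppercased
  writeLines(c(">lc", "acgt"), file.path(d, "lc.fa"))
  expect_equal(read_fasta(file.path(d, "lc.fa"))$sequence, "ACGT")
  # strict mode rejects IUPAC ambiguity codes; permissive maps them to N
  writeLines(c(">amb", "ACGR"), file.path(d, "amb.fa"))
  expect_error(read_fasta(file.path(d, "amb.fa")), "outside")
  expect_equal(read_fasta(file.path(d, "amb.fa"), on_invalid = "to_n")$sequence, "ACGN")
  expect_error(read_fasta(file.path(d, "missing.fa")))
  writeLines(character(0), file.path(d, "empty.fa"))
  expect_error(read_fasta(file.path(d, "empty.fa")), "empty")
})

test_that("GFF3 round-trips retained features and drops rare types", {
  d <- withr::local_tempdir()
  g <- tiny_genome()
  p <- file.path(d, "x.gff3")
  write_gff3(g$annotations, p)
  expect_equal(readLines(p, n = 1), "##gff-version 3")
  back <- read_gff3(p)
  expect_equal(
    dplyr::arrange(back, contig_id, start),
    dplyr::arrange(
      dplyr::mutate(g$annotations, start = as.integer(start), end = as.integer(end)),
      contig_id, start
    )
  )
  # a rare type is dropped at parse time
  extra <- tibble::tibble(contig_id = "c", start = 5, end = 50, strand = "+",
                          feature_type = "riboswitch")
  write_gff3(dplyr::bind_rows(g$annotations[1, ], extra), p)
  expect_equal(nrow(read_gff3(p)), 1)
})

test_that("intergenic derivation partitions each strand exactly", {
  # single CDS on + strand
  ann <- tibble::tibble(contig_id = "c", start = 101, end = 200, strand = "+",
                        feature_type = "CDS")
  ig <- derive_intergenic(ann, c(c = 300L))
  plus <- ig[ig$strand == "+", ]
  expect_equal(plus$start, c(1L, 201L))
  expect_equal(plus$end, c(100L, 300L))
  minus <- ig[ig$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(c(minus$start, minus$end), c(1L, 300L))
  # no annotations: one full-length interval per strand
  ig0 <- derive_intergenic(ann[0, ], c(c = 300L))
  expect_equal(nrow(ig0), 2)
  expect_true(all(ig0$start == 1 & ig0$end == 300))
  # abutting features leave no gap
  ann2 <- tibble::tibble(contig_id = "c", start = c(1, 101), end = c(100, 300),
                         strand = "+", feature_type = "CDS")
  ig2 <- derive_intergenic(ann2, c(c = 300L))
  expect_equal(nrow(ig2[ig2$strand == "+", ]), 0)
  # out-of-bounds errors
  expect_error(derive_intergenic(dplyr::mutate(ann, end = 400), c(c = 300L)), "bounds")
  # property: annotated + intergenic covers [1, L] without overlap, per strand
  g <- tiny_genome()
  lens <- setNames(nchar(g$contigs$sequence), g$contigs$id)
  ig_all <- derive_intergenic(g$annotations, lens)
  full <- dplyr::bind_rows(g$annotations, ig_all)
  for (cid in names(lens)) {
    for (strand in c("+", "-")) {
      sub <- full[full$contig_id == cid & full$strand == strand, ]
      covered <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end))
      expect_equal(sum(IRanges::width(covered)), unname(lens[cid]))
      expect_equal(sum(sub$end - sub$start + 1), unname(lens[cid])) # no overlap
    }
  }
})

test_that("region sampling respects the per-contig cap, feature bounds and strand", {
  g <- tiny_genome()
  # cap enforcement: more features than the cap
  many <- g$annotations[rep(seq_len(nrow(g$annotations)), length.out = 60), ]
  capped <- sample_region_segments(g$contigs, many, lengths = 50,
                                   max_per_contig = 10, seed = 41)
  expect_true(all(table(capped$contig_id) <= 10))
  # all samples inside a feature of their reported type
  segs <- sample_region_segments(g$contigs, g$annotations, lengths = 81, seed = 42)
  for (i in sample.int(nrow(segs), 20)) {
    r <- segs[i, ]
    inside <- any(g$annotations$contig_id == r$contig_id &
                    g$annotations$feature_type == r$feature_type &
                    g$annotations$start <= r$start & g$annotations$end >= r$end)
    expect_true(inside)
    expect_equal(nchar(r$sequence), 81)
  }
  # minus-strand segments come back reverse-complemented
  contig <- tibble::tibble(id = "m", sequence = "AAAACCCCGG")
  ann <- tibble::tibble(contig_id = "m", start = 1, end = 10, strand = "-",
                        feature_type = "CDS")
  out <- sample_region_segments(contig, ann, lengths = 10, seed = 1)
  expect_equal(out$sequence, "CCGGGGTTTT")
  out_raw <- sample_region_segments(contig, ann, lengths = 10, seed = 1,
                                    orient_minus = "raw")
  expect_equal(out_raw$sequence, "AAAACCCCGG")
  # too-short features are skipped with a warning and yield nothing
  expect_warning(
    none <- sample_region_segments(contig, ann, lengths = 81, seed = 1),
    "skipped"
  )
  expect_equal(nrow(none), 0)
  # reproducibility
  s1 <- sample_region_segments(g$contigs, g$annotations, lengths = 40, seed = 5)
  s2 <- sample_region_segments(g$contigs, g$annotations, lengths = 40, seed = 5)
  expect_identical(s1, s2)
})

test_that("labeled record TSVs round-trip", {
  d <- withr::local_tempdir()
  rec <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "TTTT"),
                        label = c(1L, 0L), source_class = c("promoter", "cds_negative"))
  p <- file.path(d, "r.tsv")
  write_labeled_tsv(rec, p)
  expect_equal(read_labeled_tsv(p), rec)
  writeLines("id\tsequence", file.path(d, "bad.tsv"))
  expect_error(read_labeled_tsv(file.path(d, "bad.tsv")), "label")
})

test_that("phage collections carry genus/species labels and the planted marker", {
  coll <- generate_synthetic_phage_collection(n_genera = 2, seed = 3)
  expect_true(all(c("id", "sequence", "genus", "species") %in% names(coll$hosts)))
  expect_true(all(c("id", "sequence", "host_genus", "species") %in% names(coll$phages)))
  expect_true(all(grepl("GGTACCTAGG", coll$phages$sequence, fixed = TRUE)))
  coll2 <- generate_synthetic_phage_collection(n_genera = 2, seed = 3)
  expect_identical(coll, coll2)
})
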