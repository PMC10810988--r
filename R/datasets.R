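#' Sample fixed-length negatives from coding regions
#'
#' Draws `n` windows of `length` nt, each fully inside a CDS feature,
#' respecting the strand (minus-strand samples are reverse-complemented).
#' Eligible CDS features are drawn uniformly with replacement, then a
#' uniform offset inside the feature.
#'
#' @param contigs Contigs tibble (`id`, `sequence`).
#' @param annotations Annotations tibble with CDS features.
#' @param n Number of records to draw.
#' @param length Record length in nt (default 81, the promoter-window
#'   convention spanning TSS interval \[-60, +20\]).
#' @param seed Optional integer seed.
#' @return Tibble of labeled records (`id`, `sequence`, `label = 0`,
#'   `source_class = "cds_negative"`).
#' @export
sample_cds_negatives <- function(contigs, annotations, n, length = 81, seed = NULL) {
  cds <- dplyr::filter(annotations, .data$feature_type == "CDS",
                       .data$end - .data$start + 1 >= length)
  if (nrow(cds) == 0) {
    abort(sprintf("no CDS features of length >= %d: 0 of %d records achievable", length, n))
  }
  seqs <- setNames(contigs$sequence, contigs$id)
  with_seed(seed, {
    pick <- cds[sample.int(nrow(cds), n, replace = TRUE), ]
    width <- pick$end - pick$start + 1L
    offs <- floor(stats::runif(n) * (width - length + 1))
    starts <- pick$start + as.integer(offs)
    raw <- substring(seqs[pick$contig_id], starts, starts + length - 1L)
    seq_out <- ifelse(pick$strand == "-", revcomp(raw), raw)
    tibble(
      id = sprintf("cds_neg_%05d", seq_len(n)),
      sequence = unname(seq_out),
      label = 0L,
      source_class = "cds_negative"
    )
  })
}

#' Configuration for the promoter benchmark builder
#'
#' @param record_length Record length in nt (81: TSS window \[-60, +20\]).
#' @param negative_mix Named fractions for the three negative classes
#'   (defaults 40% CDS, 40% order-3 Markov, 20% order-0 random).
#' @param split_fractions Train / validation / test fractions
#'   (defaults 0.8 / 0.1 / 0.1).
#' @param balance_positive_negative Make the negative count equal the
#'   positive count (default TRUE).
#' @param random0 `"compositional"` fits the order-0 chain on the positives;
#'   `"uniform"` uses equiprobable bases.
#' @param seed Integer seed for negatives and the split shuffle.
#' @return An object of class `promoter_build_config`.
#' @export
promoter_build_config <- function(record_length = 81,
                                  negative_mix = c(cds = 0.4, markov3 = 0.4, random0 = 0.2),
                                  split_fractions = c(train = 0.8, validation = 0.1, test = 0.1),
                                  balance_positive_negative = TRUE,
                                  random0 = c("compositional", "uniform"),
                                  seed = 1) {
  if (abs(sum(negative_mix) - 1) > 1e-8) abort("`negative_mix` must sum to 1")
  if (abs(sum(split_fractions) - 1) > 1e-8) abort("`split_fractions` must sum to 1")
  stopifnot(all(c("cds", "markov3", "random0") %in% names(negative_mix)))
  structure(
    list(
      record_length = as.integer(record_length),
      negative_mix = negative_mix,
      split_fractions = split_fractions,
      balance_positive_negative = balance_positive_negative,
      random0 = match.arg(random0),
      seed = as.integer(seed)
    ),
    class = "promoter_build_config"
  )
}

#' Build the promoter binary-classification dataset
#'
#' Assembles a balanced promoter/non-promoter benchmark. Negatives follow
#' the configured mix (largest-remainder rounding): windows sampled from CDS
#' annotations, sequences from an order-3 Markov chain fitted on the
#' positives plus their reverse complements, and order-0 random sequences.
#' Positives occurring verbatim in the independent test set are excluded
#' from train/validation/test. Splits are assigned at record level by a
#' seeded shuffle with largest-remainder apportionment, so the split counts
#' are exact up to integer rounding.
#'
#' @param positives Character vector of promoter sequences, all
#'   `record_length` nt (others are rejected with a report).
#' @param contigs,annotations Source genome for CDS negatives.
#' @param config A [promoter_build_config()].
#' @param independent_test Optional tibble of labeled records held out as an
#'   independent test set (its positive sequences drive the exact-match
#'   exclusion).
#' @return Labeled-records tibble: `id`, `sequence`, `label`,
#'   `source_class`, `split`; independent-test records appended with
#'   `split = "independent_test"`.
#' @export
build_promoter_dataset <- function(positives, contigs, annotations, config,
                                   independent_test = NULL) {
  stopifnot(inherits(config, "promoter_build_config"))
  if (length(positives) == 0) abort("`positives` must be non-empty")
  len_ok <- nchar(positives) == config$record_length
  if (any(!len_ok)) {
    warn(sprintf("%d positives rejected: length != %d nt", sum(!len_ok), config$record_length))
    positives <- positives[len_ok]
  }
  if (length(positives) == 0) abort("no positives of the configured record length")

  # exact-match leakage exclusion against the independent test set
  if (!is.null(independent_test) && nrow(independent_test) > 0) {
    leaked <- positives %in% independent_test$sequence
    if (any(leaked)) {
      message(sprintf("%d positives excluded: exact match in independent test set", sum(leaked)))
      positives <- positives[!leaked]
    }
  }

  n_pos <- length(positives)
  n_neg <- if (config$balance_positive_negative) n_pos else n_pos
  mix <- config$negative_mix[c("cds", "markov3", "random0")]
  n_by_class <- apportion_largest_remainder(n_neg, unname(mix))

  with_seed(config$seed, {
    cds_neg <- sample_cds_negatives(contigs, annotations, n_by_class[1],
                                    length = config$record_length)
    m3 <- fit_markov(positives, order = 3, add_revcomp = TRUE)
    markov3_seqs <- generate_markov(m3, config$record_length, n_by_class[2])
    m0 <- if (config$random0 == "uniform") {
      uniform_markov()
    } else {
      fit_markov(positives, order = 0)
    }
    random0_seqs <- generate_markov(m0, config$record_length, n_by_class[3])

    records <- bind_rows(
      tibble(id = sprintf("promoter_%05d", seq_len(n_pos)), sequence = positives,
             label = 1L, source_class = "promoter"),
      cds_neg,
      tibble(id = sprintf("markov3_neg_%05d", seq_along(markov3_seqs)),
             sequence = markov3_seqs, label = 0L, source_class = "markov3_negative"),
      tibble(id = sprintf("random0_neg_%05d", seq_along(random0_seqs)),
             sequence = random0_seqs, label = 0L, source_class = "random0_negative")
    )
    records <- assign_splits(records, config$split_fractions)
  })

  if (!is.null(independent_test) && nrow(independent_test) > 0) {
    ind <- dplyr::mutate(independent_test, split = "independent_test")
    records <- bind_rows(records, ind)
  }
  records
}

# Seeded record-level split with largest-remainder apportionment (RNG state
# is the caller's responsibility).
assign_splits <- function(records, split_fractions) {
  n <- nrow(records)
  counts <- apportion_largest_remainder(n, unname(split_fractions))
  split <- rep(names(split_fractions), counts)
  records$split <- sample(split, n)
  records
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of each exact sequence, optionally treating a
#' sequence and its reverse complement as duplicates. Order is stable. This
#' is the redundancy-removal step applied before split assignment
#' (similarity-level clustering is out of scope).
#'
#' @param records Labeled-records tibble with a `sequence` column.
#' @param revcomp_aware Also collapse reverse-complement duplicates.
#' @return The deduplicated tibble.
#' @export
deduplicate_exact <- function(records, revcomp_aware = FALSE) {
  if (nrow(records) == 0) return(records)
  key <- records$sequence
  if (revcomp_aware) {
    rc <- revcomp(key)
    key <- pmin(key, rc) # canonical orientation
  }
  records[!duplicated(key), ]
}

#' Configuration for the phage/host benchmark builder
#'
#' @param genus_bp_cap Per-genus phage base-pair cap; over-represented
#'   genera are undersampled to at most this many bp (default 20,027,298).
#' @param max_upsample_coverage Upper bound on emitted bp over source bp for
#'   under-represented genera (default 5).
#' @param segment_lengths Segment lengths to emit (default 256, 512, 1024,
#'   2048).
#' @param split_fractions Train / validation / test fractions.
#' @param include_revcomp Also emit reverse-complemented segments.
#' @param seed Integer seed.
#' @return An object of class `phage_build_config`.
#' @export
phage_build_config <- function(genus_bp_cap = 20027298,
                               max_upsample_coverage = 5,
                               segment_lengths = c(256, 512, 1024, 2048),
                               split_fractions = c(train = 0.8, validation = 0.1, test = 0.1),
                               include_revcomp = TRUE,
                               seed = 1) {
  if (genus_bp_cap <= 0) abort("`genus_bp_cap` must be positive")
  if (max_upsample_coverage < 1) abort("`max_upsample_coverage` must be >= 1")
  if (abs(sum(split_fractions) - 1) > 1e-8) abort("`split_fractions` must sum to 1")
  structure(
    list(
      genus_bp_cap = genus_bp_cap,
      max_upsample_coverage = max_upsample_coverage,
      segment_lengths = as.integer(segment_lengths),
      split_fractions = split_fractions,
      include_revcomp = include_revcomp,
      seed = as.integer(seed)
    ),
    class = "phage_build_config"
  )
}

#' Build the genus-balanced phage/host dataset
#'
#' Per host genus, total phage bp is balanced: genera above `genus_bp_cap`
#' are undersampled by random whole-contig selection to at most the cap;
#' the rest are upsampled by random fragment sampling bounded by
#' `max_upsample_coverage` times their source bp. Segments are emitted at
#' the configured lengths (label 1 = phage, 0 = host), with reverse
#' complements when flagged. Train/validation/test are assigned at the
#' whole-phage-sequence level — grouped by species when labels are present —
#' so no parent sequence (or species) spans two splits. Genera with no host
#' contig are skipped with a warning.
#'
#' @param phage_contigs Tibble: `id`, `sequence`, `host_genus`, optional
#'   `species`.
#' @param host_contigs Tibble: `id`, `sequence`, `genus`, optional
#'   `species`.
#' @param config A [phage_build_config()].
#' @return Labeled-records tibble: `id`, `sequence`, `label`,
#'   `source_class`, `split`, `parent_id`, `genus`.
#' @export
build_phage_dataset <- function(phage_contigs, host_contigs, config) {
  stopifnot(inherits(config, "phage_build_config"))
  if (!"host_genus" %in% names(phage_contigs)) {
    abort("every phage contig needs a `host_genus` label")
  }
  with_seed(config$seed, {
    genera <- unique(phage_contigs$host_genus)
    phage_segments <- list()
    host_segments <- list()
    for (g in genera) {
      hosts_g <- dplyr::filter(host_contigs, .data$genus == g)
      if (nrow(hosts_g) == 0) {
        warn(sprintf("genus '%s' skipped: no host contigs to pair with", g))
        next
      }
      phages_g <- dplyr::filter(phage_contigs, .data$host_genus == g)
      source_bp <- sum(nchar(phages_g$sequence))

      # undersample: keep a random contig subset with total bp <= cap
      keep <- integer(0)
      tot <- 0
      for (i in sample.int(nrow(phages_g))) {
        w <- nchar(phages_g$sequence[i])
        if (tot + w <= config$genus_bp_cap) {
          keep <- c(keep, i)
          tot <- tot + w
        }
      }
      if (length(keep) == 0) {
        warn(sprintf("genus '%s' skipped: smallest phage contig exceeds the bp cap", g))
        next
      }
      phages_g <- phages_g[sort(keep), ]
      retained_bp <- sum(nchar(phages_g$sequence))

      # target emitted bp: balance toward the cap, bounded by 5x source
      target_bp <- min(config$genus_bp_cap, config$max_upsample_coverage * source_bp)
      coverage <- max(1, target_bp / retained_bp)

      phage_segments[[g]] <- emit_segments(phages_g, config$segment_lengths,
                                           coverage, target_bp)
      host_segments[[g]] <- emit_segments(hosts_g, config$segment_lengths,
                                          coverage = 1, bp_budget = Inf) %>%
        mutate(genus = g)
    }
    if (length(phage_segments) == 0) abort("no genus could be built")

    phage_df <- bind_rows(phage_segments, .id = "genus") %>%
      mutate(label = 1L, source_class = "phage")
    host_df <- bind_rows(host_segments) %>%
      mutate(label = 0L, source_class = "host")

    # split at the parent-sequence level, grouping by species when available
    phage_df <- split_by_parent(phage_df, phage_contigs, config$split_fractions)
    host_df <- split_by_parent(host_df, host_contigs, config$split_fractions)

    out <- bind_rows(phage_df, host_df) %>%
      mutate(id = paste0(.data$source_class, "_", row_number()))
    if (config$include_revcomp) {
      rc <- out %>% mutate(sequence = revcomp(.data$sequence),
                           id = paste0(.data$id, "_rc"))
      out <- bind_rows(out, rc)
    }
    out %>%
      select("id", "sequence", "label", "source_class", "split",
             "parent_id", "genus")
  })
}

# Emit segments from contigs at the given lengths until the bp budget is
# spent: one contiguous pass at coverage 1, then random fragments for the
# upsampled remainder.
emit_segments <- function(contigs, lengths, coverage, bp_budget) {
  segs <- list()
  total <- 0
  for (i in seq_len(nrow(contigs))) {
    s <- contigs$sequence[i]
    n <- nchar(s)
    use_lengths <- lengths[lengths <= n]
    if (length(use_lengths) == 0) next
    len <- sample_one(use_lengths)
    base <- segment_contiguous(c(x = s), len, min_keep = min(use_lengths)) %>%
      mutate(parent_id = contigs$id[i])
    add_bp <- sum(nchar(base$sequence))
    if (total + add_bp > bp_budget) {
      keep <- cumsum(nchar(base$sequence)) <= bp_budget - total
      base <- base[keep, ]
      add_bp <- sum(nchar(base$sequence))
    }
    segs[[length(segs) + 1L]] <- base
    total <- total + add_bp
  }
  # upsampling pass: random fragments until coverage target or budget
  target <- min(bp_budget, coverage * sum(nchar(contigs$sequence)))
  guard <- 0L
  while (total < target && guard < 100000L) {
    guard <- guard + 1L
    i <- sample.int(nrow(contigs), 1, prob = nchar(contigs$sequence))
    n <- nchar(contigs$sequence[i])
    use_lengths <- lengths[lengths <= n]
    if (length(use_lengths) == 0) break
    len <- sample_one(use_lengths)
    if (total + len > target) break
    st <- sample.int(n - len + 1L, 1L)
    segs[[length(segs) + 1L]] <- tibble(
      contig_id = "x", start = st, end = st + len - 1L,
      sequence = substring(contigs$sequence[i], st, st + len - 1L),
      parent_id = contigs$id[i]
    )
    total <- total + len
  }
  bind_rows(segs) %>% select(-"contig_id")
}

# Assign train/val/test at the parent-sequence level; parents sharing a
# species travel together when species labels exist.
split_by_parent <- function(segments, contigs, split_fractions) {
  units <- if ("species" %in% names(contigs)) {
    setNames(contigs$species, contigs$id)
  } else {
    setNames(contigs$id, contigs$id)
  }
  groups <- unique(unname(units[unique(segments$parent_id)]))
  groups <- sample(groups)
  counts <- apportion_largest_remainder(length(groups), unname(split_fractions))
  assignment <- setNames(rep(names(split_fractions), counts), groups)
  segments$split <- unname(assignment[units[segments$parent_id]])
  segments
}
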