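#' Specify a synthetic genome
#'
#' Parameters for the built-in fixture generator. The generator emulates
#' multi-contig bacterial genomes: random background sequence at a target GC
#' content, strand-annotated CDS / ncRNA / pseudogene features placed without
#' overlap, and an AT-rich promoter-like motif planted in intergenic gaps
#' upstream of CDS starts. All coordinates in this package are 1-based and
#' inclusive, the Bioconductor convention.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length_range Two-element `(min, max)` contig length in nt.
#' @param gene_density Target fraction of bases covered by CDS features,
#'   strictly between 0 and 1 (total annotated density runs slightly higher
#'   because ncRNA and pseudogene features are placed too).
#' @param motif DNA string planted at promoter-like sites (default a
#'   sigma70-flavoured AT-rich 10-mer).
#' @param gc_content Background GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same spec yields byte-identical output.
#' @return An object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_contigs = 2,
                                  contig_length_range = c(10000, 20000),
                                  gene_density = 0.6,
                                  motif = "TTGACATAAT",
                                  gc_content = 0.5,
                                  seed = 1) {
  if (gene_density <= 0 || gene_density >= 1) abort("`gene_density` must be in (0, 1)")
  if (gc_content <= 0 || gc_content >= 1) abort("`gc_content` must be in (0, 1)")
  if (n_contigs < 1) abort("`n_contigs` must be >= 1")
  if (length(contig_length_range) != 2 ||
      contig_length_range[1] < 1000 ||
      contig_length_range[2] < contig_length_range[1]) {
    abort("`contig_length_range` must be (min, max) with 1000 <= min <= max")
  }
  assert_dna(motif, allow_n = FALSE, what = "motif")
  structure(
    list(
      n_contigs = as.integer(n_contigs),
      contig_length_range = as.integer(contig_length_range),
      gene_density = gene_density,
      motif = motif,
      gc_content = gc_content,
      seed = as.integer(seed)
    ),
    class = "synthetic_genome_spec"
  )
}

FEATURE_TYPES <- c("CDS", "ncRNA", "pseudogene", "intergenic")

#' Generate a synthetic annotated genome
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A list with `contigs` (tibble: `id`, `sequence`, `taxon_label`,
#'   `kind`) and `annotations` (tibble: `contig_id`, `start`, `end`,
#'   `strand`, `feature_type`), both deterministic under the spec's seed.
#' @examples
#' g <- generate_synthetic_genome(synthetic_genome_spec(n_contigs = 1, seed = 7))
#' head(g$annotations)
#' @export
generate_synthetic_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  with_seed(spec$seed, {
    contigs <- vector("list", spec$n_contigs)
    anns <- vector("list", spec$n_contigs)
    for (i in seq_len(spec$n_contigs)) {
      L <- sample.int(spec$contig_length_range[2] - spec$contig_length_range[1] + 1L, 1L) +
        spec$contig_length_range[1] - 1L
      seq_chars <- strsplit(random_dna(L, spec$gc_content), "")[[1]]
      id <- sprintf("synth_contig_%02d", i)

      # walk along the contig: gap, then feature; gaps are sized so CDS bases
      # make up about gene_density of the contig (CDS carry ~0.93 of feature
      # bp at the type mix below; tail clamping eats a little more)
      pos <- 1L
      feats <- list()
      d <- min(0.97, spec$gene_density / 0.90)
      while (pos <= L - 300L) {
        ftype <- sample(c("CDS", "ncRNA", "pseudogene"), 1L,
                        prob = c(0.84, 0.08, 0.08))
        flen <- switch(ftype,
          CDS = sample(300:1500, 1L),
          ncRNA = sample(80:250, 1L),
          pseudogene = sample(200:800, 1L)
        )
        gap <- max(20L, round(flen * (1 - d) / d * stats::runif(1, 0.7, 1.3)))
        start <- pos + gap
        end <- start + flen - 1L
        if (end > L) {
          # clamp the final feature instead of wasting the tail
          if (ftype == "CDS" && L - start + 1L >= 300L) end <- L else break
        }
        strand <- sample(c("+", "-"), 1L)
        feats[[length(feats) + 1L]] <- list(
          contig_id = id, start = start, end = end,
          strand = strand, feature_type = ftype
        )
        # plant a promoter-like motif in the gap upstream of a CDS start
        m <- nchar(spec$motif)
        if (ftype == "CDS" && gap >= m + 12L) {
          if (strand == "+") {
            mstart <- start - m - 10L
            seq_chars[mstart:(mstart + m - 1L)] <- strsplit(spec$motif, "")[[1]]
          } else {
            mstart <- end + 11L
            if (mstart + m - 1L <= L) {
              seq_chars[mstart:(mstart + m - 1L)] <- strsplit(revcomp(spec$motif), "")[[1]]
            }
          }
        }
        pos <- end + 1L
      }
      contigs[[i]] <- tibble(
        id = id,
        sequence = paste(seq_chars, collapse = ""),
        taxon_label = "Synthetica demo",
        kind = "bacterial"
      )
      anns[[i]] <- bind_rows(lapply(feats, as_tibble))
    }
    list(contigs = bind_rows(contigs), annotations = bind_rows(anns))
  })
}

#' Derive strand-aware intergenic intervals
#'
#' Intergenic regions are the non-annotated complement of the annotated
#' features with respect to the strand: per contig and strand, the returned
#' intervals are exactly the gaps between annotated features, so annotated
#' plus intergenic intervals partition `[1, contig length]` on each strand.
#'
#' @param annotations Tibble with `contig_id`, `start`, `end`, `strand`,
#'   `feature_type` (1-based inclusive coordinates).
#' @param contig_lengths Named integer vector of contig lengths.
#' @return A tibble of `feature_type = "intergenic"` rows in the same schema.
#' @export
derive_intergenic <- function(annotations, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  if (nrow(annotations) > 0) {
    bad <- annotations$start < 1 | annotations$end < annotations$start |
      annotations$end > contig_lengths[annotations$contig_id]
    if (any(is.na(bad)) || any(bad)) {
      abort("annotation interval out of contig bounds (or unknown contig_id)")
    }
  }
  out <- list()
  for (cid in names(contig_lengths)) {
    L <- contig_lengths[[cid]]
    for (strand in c("+", "-")) {
      sub <- annotations[annotations$contig_id == cid & annotations$strand == strand, ]
      covered <- IRanges::reduce(IRanges::IRanges(start = sub$start, end = sub$end))
      gaps <- IRanges::setdiff(IRanges::IRanges(1L, L), covered)
      if (length(gaps) > 0) {
        out[[length(out) + 1L]] <- tibble(
          contig_id = cid,
          start = IRanges::start(gaps),
          end = IRanges::end(gaps),
          strand = strand,
          feature_type = "intergenic"
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), feature_type = character()))
  }
  bind_rows(out)
}

#' Sample fixed-length segments from annotated regions
#'
#' For each contig at most `max_per_contig` features are used (sampled
#' without replacement when more exist), respecting the strand; for each
#' retained feature and each requested length one window fully inside the
#' feature is drawn uniformly. Minus-strand samples are returned
#' reverse-complemented by default so all segments read 5' to 3' on the
#' feature's coding strand. Windows containing `N` are redrawn up to
#' `n_retries` times, then skipped. Features too short for a requested
#' length are skipped with a warning.
#'
#' @param contigs Contigs tibble (`id`, `sequence`).
#' @param annotations Annotations tibble (see [derive_intergenic()]).
#' @param lengths Integer vector of segment lengths to draw.
#' @param max_per_contig Per-contig feature cap (default 2000).
#' @param seed Optional integer seed.
#' @param orient_minus One of `"revcomp"` (default) or `"raw"`.
#' @param n_retries Redraw budget for N-containing windows.
#' @return Tibble with `contig_id`, `start`, `end`, `strand`,
#'   `feature_type`, `length`, `sequence`.
#' @export
sample_region_segments <- function(contigs, annotations, lengths,
                                   max_per_contig = 2000, seed = NULL,
                                   orient_minus = c("revcomp", "raw"),
                                   n_retries = 10) {
  orient_minus <- match.arg(orient_minus)
  stopifnot(all(lengths >= 1))
  seqs <- setNames(contigs$sequence, contigs$id)
  with_seed(seed, {
    out <- list()
    n_skipped <- 0L
    for (cid in unique(annotations$contig_id)) {
      feats <- annotations[annotations$contig_id == cid, ]
      if (nrow(feats) > max_per_contig) {
        feats <- feats[sample.int(nrow(feats), max_per_contig), ]
      }
      for (j in seq_len(nrow(feats))) {
        f <- feats[j, ]
        width <- f$end - f$start + 1L
        for (len in lengths) {
          if (width < len) { n_skipped <- n_skipped + 1L; next }
          s <- NULL
          for (try in seq_len(n_retries + 1L)) {
            st <- f$start + sample.int(width - len + 1L, 1L) - 1L
            cand <- substring(seqs[[cid]], st, st + len - 1L)
            if (!grepl("N", cand, fixed = TRUE)) { s <- list(st = st, seq = cand); break }
          }
          if (is.null(s)) next
          seq_out <- if (f$strand == "-" && orient_minus == "revcomp") {
            revcomp(s$seq)
          } else {
            s$seq
          }
          out[[length(out) + 1L]] <- tibble(
            contig_id = cid, start = s$st, end = s$st + len - 1L,
            strand = f$strand, feature_type = f$feature_type,
            length = as.integer(len), sequence = seq_out
          )
        }
      }
    }
    if (n_skipped > 0) {
      warn(sprintf("%d (feature, length) pairs skipped: feature shorter than requested length",
                   n_skipped))
    }
    if (length(out) == 0) {
      return(tibble(contig_id = character(), start = integer(), end = integer(),
                    strand = character(), feature_type = character(),
                    length = integer(), sequence = character()))
    }
    bind_rows(out)
  })
}

#' Generate a synthetic phage/host contig collection
#'
#' Emulates a genus-labelled phage-vs-host benchmark input: each genus gets
#' host contigs with a genus-specific GC content and phage contigs that share
#' the host composition but carry a densely planted phage marker motif, so a
#' sequence classifier has signal to learn. Species labels allow split
#' control at the species level.
#'
#' @param n_genera Number of host genera.
#' @param hosts_per_genus,phages_per_genus Contigs per genus.
#' @param host_length_range,phage_length_range Contig length ranges in nt.
#' @param marker Motif planted about every `marker_every` nt in phage contigs.
#' @param marker_every Mean spacing between planted markers.
#' @param seed Integer seed.
#' @return A list of two contig tibbles, `hosts` (with `genus`, `species`)
#'   and `phages` (with `host_genus`, `species`).
#' @export
generate_synthetic_phage_collection <- function(n_genera = 4,
                                                hosts_per_genus = 2,
                                                phages_per_genus = 4,
                                                host_length_range = c(20000, 40000),
                                                phage_length_range = c(5000, 15000),
                                                marker = "GGTACCTAGG",
                                                marker_every = 150,
                                                seed = 1) {
  assert_dna(marker, allow_n = FALSE, what = "marker")
  with_seed(seed, {
    genera <- sprintf("Genus_%02d", seq_len(n_genera))
    gcs <- stats::runif(n_genera, 0.35, 0.65)
    hosts <- list(); phages <- list()
    for (g in seq_len(n_genera)) {
      for (h in seq_len(hosts_per_genus)) {
        L <- sample(host_length_range[1]:host_length_range[2], 1L)
        hosts[[length(hosts) + 1L]] <- tibble(
          id = sprintf("%s_host_%02d", genera[g], h),
          sequence = random_dna(L, gcs[g]),
          genus = genera[g],
          species = sprintf("%s species_%d", genera[g], h),
          kind = "bacterial"
        )
      }
      for (p in seq_len(phages_per_genus)) {
        L <- sample(phage_length_range[1]:phage_length_range[2], 1L)
        s <- strsplit(random_dna(L, gcs[g]), "")[[1]]
        mlen <- nchar(marker)
        sites <- seq(1L, L - mlen, by = marker_every)
        for (st in sites) {
          s[st:(st + mlen - 1L)] <- strsplit(marker, "")[[1]]
        }
        phages[[length(phages) + 1L]] <- tibble(
          id = sprintf("%s_phage_%02d", genera[g], p),
          sequence = paste(s, collapse = ""),
          host_genus = genera[g],
          species = sprintf("%s phage sp. %d", genera[g], p),
          kind = "phage"
        )
      }
    }
    list(hosts = bind_rows(hosts), phages = bind_rows(phages))
  })
}
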