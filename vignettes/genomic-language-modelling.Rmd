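---
title: "Methods: overlapping k-mer tokenization, leakage-aware masking and desk-scale training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlapping k-mer tokenization, leakage-aware masking and desk-scale training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnalm)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical choices behind them, and what the
synthetic-data experiments do and do not show.

## LCA tokenization

A DNA segment is encoded as overlapping k-mers sampled every `shift`
nucleotides. Two parameters dominate: the k-mer size `k` (how much local
sequence each token sees) and the stride `shift` (how densely tokens tile
the sequence). Tokens are `s[i..i+k-1]` for `i = 1, 1+shift, 1+2·shift, ...`;
trailing nucleotides not reachable by a full window are unused, so with
`shift = 2` and even `k` an odd-length sequence never uses its final
character.

```{r}
lca_tokenize("AAGTCCAGGATCAAGATT", k = 6, shift = 1)
lca_tokenize("AAGTCCAGGATCAAGATT", k = 6, shift = 2)
```

The vocabulary fixes five special tokens `[PAD] [UNK] [CLS] [SEP] [MASK]` at
ids 0–4 followed by the `4^k` k-mers in lexicographic order, giving 4101
entries at k = 6 and 9 at k = 1. Five specials (not three) is a deliberate
choice: padding and an unknown-token fallback are operationally necessary,
and with them the two published vocabulary sizes come out exactly.

Context arithmetic: a model with `P` token positions spends two on
`[CLS]`/`[SEP]` and covers `k + (P - 3)·shift` nucleotides
(`covered_nt()`): 1027 nt for (k = 6, shift = 1, P = 1024), 1022 nt for
(k = 1), 4096 nt for (k = 6, shift = 2, P = 2048). Where prose elsewhere
says such models "support 1024 bp", we reconcile the two figures as 1024
token *positions* versus the 1027 *nucleotides* they cover, and surface
both numbers.

Decoding reconstructs the first token fully and appends the last `shift`
characters of each subsequent token, raising an error if overlapping
regions disagree — which makes round-trip tests exact. Non-`ACGT` tokens
encode as `[UNK]` in normal operation; the single-character corruption
workflow (`corrupt_and_mask()`) instead maps every token touching the
corrupted position to `[MASK]`. Truncation of over-long segments keeps the
5' end, a deterministic rule matching left-to-right segment semantics.

## Masking without leakage

Overlapping tokens make naive token masking trivial to invert: a token's
neighbours share `k - shift` of its characters. Masking is therefore
defined at the nucleotide level. Events hide `span_nt` consecutive bases
(default 2 for k = 6); every token whose window intersects a hidden base is
masked (`expand_mask_to_overlaps()`), which guarantees the no-leak
invariant: *no unmasked token contains a hidden nucleotide*. An interior
hidden base masks `k/shift` tokens (six for k = 6, shift = 1).

Because one event masks about `(k + span_nt - 1)/shift` tokens, the
per-base event probability must be recalibrated to keep the masked-token
fraction at the target `f` (default 0.15). A token is hit exactly when one
of the `k + span_nt - 1` event start positions intersecting its window
fires, so the package solves

\[ 1 - (1 - p_{sel})^{k + span - 1} = f
   \quad\Rightarrow\quad
   p_{sel} = 1 - (1 - f)^{1/(k + span - 1)} \]

making the interior per-token masked probability *exactly* `f`; the
empirical fraction sits a hair below `f` only through edge effects (the
first and last few tokens have fewer covering events). A first-order
alternative `p_sel = f/(k + span - 1)` is provided
(`calibration = "first_order"`); it under-masks by the second-order term
(≈ 0.141 rather than 0.150 for the defaults). Overlapping events are
resolved by set union — no rejection sampling — and the residual
under-masking is covered by the property-test tolerance (±0.01 at 10⁶
tokens).

Noise then applies per masked token independently: `[MASK]` with `p1`, a
uniformly random non-special k-mer with `p2`, kept with `p3`
(defaults 0.8/0.1/0.1). The loss is the negative log likelihood summed over
masked positions; optimization uses the mean per masked token (batch-size
invariant), with the sum reported alongside. Probabilities are clamped at
1e-12 before the log. A wide-span, high-`p1` configuration mirroring a
gentler first training phase (five contiguous tokens, `p1 = 0.9`) is
expressible through the same `masking_config()`.

## Markov background models

Order-`o` nucleotide chains (`fit_markov()`) estimate
`P(x_i | x_{i-o}, ..., x_{i-1})` from sliding-window counts —
`4^(o+1)` (context, next) entries, 256 at order 3. For promoter-like
negatives the chain is fitted on the positive sequences *plus their reverse
complements*, making counts strand-symmetric. The order-0 "pure random"
generator is provided in two flavours: compositional (fitted on the
positives, the default) and uniform, since the choice of marginal is
genuinely open; the default follows the principle that negatives should
mimic the positives' composition. The pseudocount defaults to 0 (direct
estimation); Laplace smoothing is available for small corpora. Generation
draws the initial context from the empirical prefix distribution —
contexts never observed raise a named error rather than silently
renormalizing.

## Benchmark dataset construction

**Promoter set.** Records are 81 bp (the transcription-start-site window
[−60, +20]). Negatives are mixed 40% CDS windows / 40% order-3 Markov /
20% order-0 random, with counts apportioned by largest remainder — the
rounding rule is a design choice, stated here because "40% of 1001" is
otherwise ambiguous. Balancing makes the negative total equal the positive
total. Positives occurring *verbatim* in the independent test set are
excluded from train/validation/test; leakage exclusion is exact string
match (a reverse-complement-aware mode exists but is off by default, since
exact match is the stated rule). Splits are record-level, 80/10/10, by a
seeded shuffle with largest-remainder counts.

**Phage set.** Per host genus, phage base pairs are balanced: genera above
`genus_bp_cap` (default 20,027,298 bp) are undersampled by random
whole-contig selection; the rest are upsampled by random fragment sampling
bounded by `max_upsample_coverage` (default 5×) times their source bp.
Segments are emitted at the configured lengths (256/512/1024/2048 by
default), reverse complements optionally added, and splits are assigned at
the whole-phage-sequence level — grouped by species when labels exist — so
no parent sequence spans two splits. Similarity-level redundancy clustering
is out of scope; `deduplicate_exact()` removes exact (optionally
reverse-complement) duplicates instead, a deliberate narrowing that keeps
the artifact dependency-free.

## Encoder, pooling and the classification head

The four fixed poolings (mean/sum/max/min over unmasked positions) and the
weighted-pooling head are the bespoke mathematics of the package. The head
computes position weights `w = softmax(W₁Sᵀ + b₁)` — padding positions
receive −∞ before the softmax, an exactness choice so that `w` is a true
distribution over real positions — pools `P = Σ wᵢ sᵢ` (equal to mean
pooling when `w` is uniform, an identity the tests assert), applies dropout
to `P` only (not after the output map, as written), and maps to two logits.

The encoder behind these heads is a compact CPU transformer implemented in
base R matrix code: token + learned absolute position embeddings, post-norm
blocks of multi-head self-attention and a GELU feed-forward, with manual
backpropagation verified against finite differences in the test suite. The
full-size presets (`mini`, `mini_c`, `mini_long`: hidden 384, 6 layers,
6 heads, intermediate 3072) exist for configuration arithmetic — parameter
counts depend on positional-embedding details and are reported, not
asserted — while `tiny_demo` (hidden 32, 2 layers, 2 heads, 128 positions)
is the trainable desk-scale variant. AdamW defaults are recorded as
β₁ = 0.95, β₂ = 0.98, ε = 5×10⁻⁵ and weight decay 0.01; that ε is unusually
large for AdamW and is kept as the documented default, with the standard
1e-8 an explicit override.

## Evaluation

`confusion_metrics()` implements MCC, F1, precision/recall, accuracy,
sensitivity, specificity from the printed formulas; MCC returns 0 when a
denominator factor vanishes (the standard degenerate-table convention).
`roc_auc()` is the Mann–Whitney statistic with half-tie counting, equal to
trapezoidal ROC integration (the tests assert both routes agree to 1e-12).
`silhouette_score()` uses `s(i) = (b(i) − a(i))/max(a(i), b(i))` with
`s = 0` for singleton clusters.

Masked-token restoration uses a *reference rank*: the number of vocabulary
entries scored strictly above the true token, ties counting one half,
0 = perfect. Top-k is `rank < k` under the same convention; the
per-position one-vs-rest AUC of the true token's probability is
`1 − rank/(V − 1)`. These definitions are isolated behind
`masking_eval()` because the statistic's base (0- vs 1-based) and the AUC
variant are interpretation choices; the uniform baseline's expected rank
`(V_kmer − 1)/2` anchors them. `run_corruption_benchmark()` corrupts one
uniformly chosen character per trial, masks every overlapping token, and
evaluates the model's prediction at the leftmost masked token — one
evaluated position per trial, stratified by segment length and feature
type.

## The synthetic-data generator, and what passing tests show

`generate_synthetic_genome()` emulates multi-contig bacterial genomes:
i.i.d. background at a target GC, non-overlapping CDS/ncRNA/pseudogene
features on both strands (CDS 300–1500 nt, ncRNA 80–250, pseudogene
200–800, mixed 84/8/8 by count), intergenic gaps sized so CDS bases make up
`gene_density` of the contig, and an AT-rich sigma70-flavoured motif
(`TTGACATAAT` by default — a fused −35/−10 flavour) planted 10 nt upstream
of CDS starts, strand-aware. `generate_synthetic_phage_collection()` gives
each genus its own GC level and plants a marker motif densely in phage
contigs. The promoter demo task plants the motif at a uniform position in
each 81 bp positive over a GC 0.45 background.

What real data has that these fixtures do not: codon structure, repeats,
mobile elements, genuine promoter degeneracy (position weight matrices, not
exact motifs), phylogenetic correlation between records, and class overlap
(temperate phages inside host chromosomes). Passing the learnability tests
therefore demonstrates that the pipeline is wired correctly and can learn a
separable signal end to end — MCC ≥ 0.9 on the planted-motif task, checked
against an independent ridge-logistic baseline on 6-mer counts that must
also succeed — not that the tiny model would approach published benchmark
performance on real promoters or phages. Those benchmark numbers require
full-scale pretrained weights and external datasets and are intentionally
not asserted anywhere in this package.

Problem sizes chosen for the demonstrations: the promoter demo uses 2500
records (2000 train / 500 test via an 80/20 split), a 6-epoch tiny-encoder
fit; the MLM demo uses 500 segments of 128 nt for 200 steps and asserts
only the direction of learning (final mean masked-token loss below the
initial). These sizes make the whole suite reproducible in minutes on one
CPU while still exercising every component at realistic shapes.

## Numerical and design choices, collected

- Coordinates are 1-based inclusive everywhere (the Bioconductor
  convention); GFF3 I/O is therefore pass-through.
- Five special tokens fixed so vocabulary sizes come out at 4101/9.
- Exact masking recalibration (above); union semantics for event overlap.
- Largest-remainder apportionment wherever fractions meet integers.
- Log clamp 1e-12; dropout identity at inference; −∞ padding scores.
- Tokenized datasets persist to a plain TSV cache
  (`write_tokenized_tsv()`), one row of space-separated ids per segment
  with `k`/`shift` columns.
- Markov order-0 uses `"."` as the empty-context label.
- Random segmentation samples lengths uniformly over the configured range
  (the distribution is a config choice, not a law), and segments may
  overlap: coverage-1 sampling implies no exclusivity.

## Known limitations

The compact encoder is a demonstration vehicle: single-CPU, dense R matrix
algebra, no relative key-value positional embedding (learned absolute
positions instead), no mixed-length curriculum by default (the
fixed-then-variable-length schedule is expressible but not the default
path), and no checkpointing format beyond R serialization. The phage
builder assumes genus labels are trustworthy and skips genera without host
contigs rather than imputing pairs. UMAP/t-SNE projections of embeddings
are left to the user on `embed_segments()` output.
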