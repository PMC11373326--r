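---
title: "Methods: FracMinHash profiling of ortholog groups"
author: "orthosketch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FracMinHash profiling of ortholog groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosketch)
```

# The model

`orthosketch` profiles a metagenome in terms of ortholog groups —
families of evolutionarily related genes that carry out the same
function across species, of which KEGG's KOs are the canonical example.
The central object is the FracMinHash sketch: with a hash function
$h : \Omega \to [0, H]$, $H = 2^{64}-1$, and a scale factor
$s = 1/\mathrm{scaled}$, the sketch of a k-mer set $A$ is
$\{\, h(a) : a \in A,\ h(a) \le \lfloor H/\mathrm{scaled} \rfloor \,\}$.
Retention is decided by the hash value alone, so the same k-mer is
either kept in every sketch or in none, sketches of growing inputs grow
proportionally, and the containment of one set in another,
$C(A,B) = |A \cap B| / |A|$, is estimated unbiasedly by the same ratio
over the retained hashes.

Profiling composes four steps. Reference protein sequences are pooled
per group and sketched once (`buildReference`). The sample's reads are
translated in all six reading frames, each frame split at stop codons,
and the resulting amino-acid k-mers sketched with identical parameters
(`sketchSequences`). Every group whose sketch intersects the sample
sketch in at least $\lceil \mathrm{threshold\_bp}/\mathrm{scaled}
\rceil$ hashes is reported independently — there is no assignment of
shared k-mers to a single best group (`prefetchOverlaps`). Relative
abundance is the sample-abundance-weighted overlap normalized across
reported groups (`computeProfile`).

Key modeling assumptions:

* **Groups, not genes.** Individual genes are too small for a
  downsampled sketch to register; the pooled k-mer content of a family
  is not. Consequently the resolution floor is set by the family's
  pooled distinct k-mer count divided by `scaled`.
* **Shared content is double-counted.** A k-mer present in two groups
  contributes to both overlaps. This reports every plausible group
  (high recall among detectable groups) at the cost of mild abundance
  inflation for closely homologous families.
* **Quantification by weighted overlap.** Sample k-mer multiplicities
  are proportional to sequencing depth, so the weighted overlap of a
  group tracks (depth × detectable k-mer content), mirroring the
  depth-weighted ground truth.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 11 aa | amino-acid k-mer length; 7 is more sensitive/less specific, 15 the reverse |
| `scaled` | 1000 | downsampling denominator; the sketch keeps an expected 1/1000 of distinct k-mers |
| `seed` | 42 | MurmurHash3 seed, fixed for interoperability with the wider sketching ecosystem |
| `threshold_bp` | 1000 | minimum overlap in base-pair equivalents; at the defaults this is a single shared hash |

Two sketches are comparable only when `k`, `scaled` and `seed` agree.
The `alphabet` tag distinguishes sketches built from protein records
from those built from translated nucleotide reads; both denote
amino-acid k-mer space and are deliberately mutually comparable, since
comparing a translated metagenome against protein references is the
pipeline's entire point.

# Numerical and representational choices

* **64-bit hashes as decimal strings.** R has no native unsigned 64-bit
  integer and doubles lose exactness above $2^{53}$, so hash values
  cross the R boundary as decimal strings; hashing, thresholding,
  ordering and aggregation run in C++ on `uint64_t`. Set operations on
  the string representation (`%in%`, `match`) remain exact. For the
  same reason sketch JSON stores hashes as strings, sorted ascending,
  which also makes files byte-reproducible.
* **Threshold arithmetic is integral.** Retention tests
  $h \le \lfloor (2^{64}-1)/\mathrm{scaled} \rfloor$ with integer
  division; no floating point is involved.
* **Translation rules.** All six frames; frames are split at stop
  codons and k-mers never span a stop; codons containing an ambiguous
  or non-ACGT base translate to X, and k-mers containing X are dropped;
  leading start codons are *not* rewritten to M, so translation is
  position-independent. Protein k-mers are not canonicalized (no strand
  in amino-acid space). Internally, whole translated frames are passed
  to the C++ k-merizer, which skips k-mers containing `*` or `X` — this
  is provably identical to splitting first, and avoids materializing
  fragments.
* **Ties and ordering.** Overlap tables sort by weighted overlap
  descending with lexicographic group-id tie-break; collections
  serialize in group-id order; every output is therefore diffable and
  byte-stable.
* **Degenerate inputs.** Empty read files yield an empty profile with a
  warning (not an error); containment of an empty query is undefined
  and errors; groups whose sketch is empty are kept in the database but
  can never be detected, which the reference builder documents rather
  than hides.
* **Coordinates.** 1-based inclusive throughout, with a converter from
  0-based half-open (BED) intervals at the boundary.
* **Ground-truth coverage sums per-read overlaps** (depth-weighted)
  rather than taking a positional union: relative abundances must
  reflect sequencing depth, and a union would saturate at gene length.
* **Top-95% completeness** reduces the truth to the minimal prefix of
  groups, sorted by abundance descending with id tie-break, whose
  cumulative abundance reaches the quantile; profiles are normalized
  over detected groups only (no "unassigned" mass), so profile and
  truth live on the same simplex.
* **Pearson, Bray–Curtis, weighted Jaccard** are computed over the
  union of positively supported keys with missing entries as zero;
  keys at zero in both vectors are dropped so that padding a table with
  zero rows cannot change any metric.

# The synthetic benchmark

`synthConfig()` defaults define the package's reference experiment:

* 200 protein families × 64 members, gene length 1200–2400 nt (whole
  codons), members derived from a random ancestral protein by i.i.d.
  substitutions at 15% per residue — orthologous proteins routinely
  diverge at least this far, and the divergence keeps member k-mer sets
  largely distinct, which is what gives real ortholog groups their
  k-mer-rich sketches.
* 16 genomes × 200 genes drawn from the family pool without replacement
  within a genome, with weight proportional to 1/(family rank): a
  Zipf-like frequency spectrum that makes a few families ubiquitous
  (housekeeping-like) and many rare, reproducing the heavy-tailed
  abundance distribution over functional groups that real communities
  show. Genes alternate with 50–300 nt random spacers; coordinates are
  recorded 1-based inclusive and verified by extraction.
* Genome relative abundances are lognormal with log-space mean 1 and
  standard deviation 2, normalized.
* Single-end 100 nt reads totalling 20 Mb, drawn genome-proportional to
  abundance × length; fragment length is Gaussian (mean 270 nt, sd 27
  nt) truncated to the read length and genome bounds; the read is the
  fragment's first 100 nt on a uniformly chosen strand; substitution
  errors are i.i.d. at `errorRate`. The mapping table records each
  read's true forward-strand span.

All stages derive their RNG stream from the single master seed, so a
configuration reproduces every output file byte for byte.

**What the generator does and does not emulate.** It reproduces the
statistical skeleton of a community read simulation: lognormal
community structure, a heavy-tailed family frequency spectrum, within-
family sequence divergence, Gaussian fragments, substitution errors.
It does not attempt taxonomy-driven strain selection, paired-end
layout, indels, quality-score realism, GC or coverage bias, horizontal
transfer, or realistic protein composition (residues are uniform).
Passing the benchmark therefore demonstrates the pipeline's correctness
and its statistical behavior under controlled conditions — not
performance on any particular real dataset, where database
incompleteness and unmodeled homology structure dominate.

Reads are single-end because the profiler is orientation- and
pairing-agnostic after six-frame translation; the error model is
substitution-only because short-read errors are substitution-dominated
and indels would merely shift frames, a degradation the error-sweep
property already covers. Lognormal parameters are interpreted as the
underlying normal's mean and sd in log space.

# Design decisions that were genuinely open

* **Hash function**: MurmurHash3 x64_128 (low 64 bits, seed 42). Any
  uniform 64-bit hash satisfies the theory; this one is the de facto
  convention of k-mer sketching tools, so sketches are comparable with
  that ecosystem. Its implementation is validated against frozen
  vectors from an independent implementation.
* **A gene in several groups contributes to each** both in the
  reference and in the ground truth; profiles and truth then treat
  multi-function genes symmetrically.
* **Weighted overlap uses the query's abundances** (not the
  reference's): reference k-mer multiplicities say nothing about the
  sample's composition.
* **threshold_bp = 0 reports zero-overlap groups** (the minimum-hash
  rule applied literally); the profile constructor drops zero-weight
  records so abundances stay positive.
* **Linear scan, no tree index.** At the package's database scales a
  bloom-tree accelerator would add complexity without measurable
  benefit; search cost is one `match` per group.
* **FASTQ qualities are ignored**; no quality filtering is performed.

# Problem sizes in the test suite

The suite exercises the brute-force sketch oracle on multisets up to a
few thousand k-mers (50 replicates), calibrates the containment
estimator on 200 replicate pairs of 5000-k-mer sets at scaled 100,
checks the size law on 200 inputs of 10^4 distinct k-mers, runs the
full benchmark once at the default 20 Mb configuration, and sweeps
error rates {0, 0.01, 0.02, 0.04} over 5 seeds at 4 Mb per run — the
reduced depth puts mean coverage near 1×, where substitution errors
visibly erase borderline families and the degradation trend is
unambiguous. Statistical assertions use 99% confidence bands under
fixed seeds.

# Known limitations

* Completeness is bounded by the sketch resolution: a group whose
  in-sample distinct k-mer count is far below `scaled` is invisible —
  the benchmark's all-group completeness of roughly 0.7–0.8 at 10×
  mean coverage reflects exactly this, while top-95% completeness
  approaches 0.9.
* Homologous families inflate each other's abundance (no shared-k-mer
  assignment); a gather-style greedy decomposition is out of scope.
* Containment estimates at high `scaled` on small queries are noisy;
  the package reports raw overlaps alongside abundances so users can
  threshold harder when precision matters.
* The evaluator's Pearson is computed on linear abundances over the
  support union and is dominated by the most abundant groups.
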