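---
title: "Methods: resequencing analysis of an evolved cross-feeding consortium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resequencing analysis of an evolved cross-feeding consortium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consortiumseq)
```

# Scope

`consortiumseq` implements the computational core of a resequencing study of
an experimentally evolved *E. coli* community: clonal isolates (here named
CV101, CV103, CV115, CV116) and their common ancestor (JA122) are compared
genome-wide to identify the SNPs that accumulated during hundreds of
generations of glucose-limited chemostat culture, to characterise the
mutation spectrum left by defective base-excision repair, to reconstruct the
clonal genealogy from SNP sharing, and to estimate per-strain mutation rates
from fluctuation assays. Because no raw sequencing reads are available for
the original isolates, the package pairs every analysis stage with a
synthetic-data generator that produces inputs with known ground truth; the
test suite and the acceptance script exercise the full chain against that
truth.

# SNP calling from pileups

The caller compares each evolved strain against the ancestor site by site on
samtools 6-column pileups (chromosome, 1-based position, reference base,
depth, read-base string, qualities; the quality column is tolerated and
ignored). The read-base string is parsed completely: `.`/`,` are
reference matches on the forward/reverse strand, letters are mismatches with
case encoding strand, `N` is an ambiguous call, `*` a deleted base, `^X` and
`$` are read start/end markers, and `+n.../-n...` indel annotations are
skipped (they attach to the previous base and are not base calls). Malformed
strings — a dangling `^`, an indel run shorter than its declared length, or
a call count that contradicts the depth field — are hard errors naming the
line.

At each site covered in both strains the candidate variant is the most
frequent non-reference base in the evolved strain, with ties broken
alphabetically (a deterministic, haploid-sensible rule; clonal samples are
expected to be near-fixed, so ties essentially only arise in noise). The
filter accepts the site when all of the following hold, and otherwise
records *every* violated rule:

* variant fraction ≥ `min_evolved_frac` (default 0.40) in the evolved
  strain, and ≤ `max_ancestor_frac` (default 0.10) in the ancestor — both
  thresholds inclusive, reading "at least"/"at most" literally;
* raw depth ≥ `min_depth` (default 5) in both strains;
* at least one variant-carrying read on each strand of the evolved strain
  (`require_both_strands`, default on) — the ancestor carries no variant to
  confirm, so strand confirmation applies to the evolved strain only;
* at most `max_ambiguous` (default 1) `N` calls and `max_deletion`
  (default 1) `*` calls in *each* strain — the caps are enforced per strain
  and per symbol, the most conservative reading of a joint cap.

Two numerical conventions deserve note. Allele fractions are computed over
*base-called* reads, excluding `N` and `*`: an ambiguous call carries no
allele evidence, and ambiguity is already capped separately. The depth
threshold, by contrast, uses the raw depth column (reads covering the
position). Whether the original pipeline included `N`/`*` in its
denominators is not knowable from the published description; this choice is
the package's own and is stated here rather than asserted as the authors'.

Sites present in only one stream are skipped and tallied
(`ONLY_IN_ANCESTOR`/`ONLY_IN_EVOLVED`), sites with no variant base are
tallied as `NO_ALT`, and calls + rejections + no-variant sites always sum to
the number of compared sites. One variant allele is reported per site
(haploid clonal samples). Output is a minimal VCF v4.2 (FILTER = `PASS` or
the semicolon-joined reason codes under `emit_all`) plus a TSV call table.

# Annotation and the mutation spectrum

Annotation uses the standard genetic code (translation table 1; stops TAA,
TAG, TGA). For a SNP inside a CDS the affected codon is extracted on the
gene's own strand (reverse-strand genes are read on the reverse complement),
and the effect is synonymous, missense, or nonsense according to the mutant
codon; amino-acid changes are reported with 1-based residue numbering and
`*` for stop (e.g. `E26*`, `GAG->TAG`). The strains this analysis emulates
carry an amber suppressor (supE44), so a nominal nonsense call need not mean
a null allele in vivo; the annotation reports nominal effects. A start-codon
disruption is classed missense (no separate start-lost category). Substitution
classes are reported both as the 12 directed reference-strand changes
(`G->T` and `C->A` are separate rows, as spectrum tables conventionally
print them) and as the 6 strand-collapsed base-pair classes (`G:C->T:A`
covers both), whose dominance is the fingerprint of unrepaired oxidative
G:C damage in MutY/MutM-defective backgrounds.

Spectrum tables count SNP *loci*: rows duplicated across carrier strains are
collapsed on (chrom, pos, ref, alt) before tabulation, so per-strain call
tables and locus tables summarise identically. Percentages are reported to
one decimal of the SNP total. Multi-hit reports list genes — and, when a
two-column gene→TU map is supplied, transcription units — carrying two or
more SNPs, with pooled and per-strain counts; genes absent from the map fall
back to themselves as singleton units with a warning. TU membership is
always an input file, never inferred: operon structure is an annotation
resource, not something derivable from coordinates.

# Clonal phylogeny from SNP sharing

SNP calls across strains form a boolean strains × loci presence matrix
(the constructor rejects all-absent columns — a locus nobody carries is not
a SNP). The *partition* groups loci by their exact carrier set; private,
pairwise-shared and shared-by-all counts drop out directly and sum to the
locus count.

Trees are rooted at the ancestor, which defines the all-absent state at
every locus because SNPs are called relative to it; gains and losses are
therefore polarised, and a stem branch (ancestor → most recent common
ancestor of the evolved clones) carries mutations shared by every strain.
Branch scoring is Fitch small parsimony per locus with the root fixed
absent. Where a locus admits several minimal reconstructions, changes are
placed on the branch closest to the root (gains as early as possible), a
deterministic ACCTRAN-like rule implemented by exhaustive minimal-
reconstruction enumeration — exact and cheap at ≤ 7 tips, which is also the
hard limit of the exhaustive topology search ((2n−3)!! rooted shapes; 15
for four strains). Ties in the topology search are all reported, sorted by
canonical newick (children ordered by sorted tip set). On tree-compatible
data the parsimony length equals the locus count exactly — the
no-homoplasy diagnostic the tests rely on.

The original study labels its tree "maximum likelihood" without naming a
model or program. With four tips, binary characters polarised by a
sequenced ancestor, and homoplasy-free data, any common binary-character
likelihood ranks topologies identically to parsimony; Fitch parsimony is
implemented as the primary method because it is exact, assumption-light and
directly testable against brute-force enumeration. This substitution is a
deliberate design choice of the package.

# Fluctuation analysis

The Luria–Delbrück pmf is computed by the Ma–Sandri–Sarkar recursion
(`p_0 = exp(−m)`; `p_k = (m/k) Σ_{i<k} p_i/(k−i+1)`), which assumes
deterministic doubling of mutant clones, full plating, no phenotypic lag and
no fitness cost. The MLE of `m` maximises the log likelihood by bracketed
1-D search on log m (relative tolerance 1e-6); the 95% CI is the profile-
likelihood interval at a log-likelihood drop of 1.92 (χ², 1 df), chosen over
tabulated limits because it is self-contained and testable. All-zero count
vectors sit at the boundary: `m_hat = 0`, flagged, with a one-sided upper
limit. Rates convert as `mu = m / Nt` (the convention of the widely used
FALCOR calculator); `m / (Nt − N0)` is available behind a flag and differs
negligibly when `Nt ≫ N0`.

Because the recursion is O(kmax²) and the Luria–Delbrück tail is heavy
(P(K > k) ≈ m/k, so jackpot cultures are routine), the likelihood lumps
counts above a cap (default 1000) into a right-tail bin with probability
`1 − Σ_{k<cap} p_k`. The likelihood stays proper, and at the `m` values
relevant here (m ≲ 200) the lumping changes the MLE by far less than the
search tolerance while keeping jackpots from exploding the recursion.

The assay simulator implements the same classical model the estimator
assumes, in continuous form: the mutation count per culture is
Poisson(mu·(Nt−N0)); each mutation occurs at a division drawn uniformly over
the N0→Nt growth interval, and its clone grows deterministically to
`floor(Nt/N)` cells at plating. As Nt/N0 grows this clone-size law converges
to the Lea–Coulson distribution `P(j) = 1/(j(j+1))` underlying the MSS
recursion, so simulator and likelihood are mutually consistent — the test
suite checks the empirical count distribution of 5000 simulated cultures
against the recursion by χ² at the 99% level, and P(0 mutants) against
exp(−m) analytically. A synchronous discrete-doubling implementation was
rejected: it restricts clone sizes to powers of two, which is measurably not
the Lea–Coulson law and would make the MSS likelihood the wrong estimator
for the simulator's own output. Each culture draws from its own named seed
substream, so counts are independent of assay size and ordering.

The published experiment used 12 cultures per strain and does not publish
per-culture counts, inoculum or final titers (the titer protocol implies
~1e9 cells/mL). Defaults (`N0 = 1e4`, `Nt = 3e9`, 12 cultures) are
configurable, not asserted; at n = 12 the estimator is intrinsically noisy
and the tests report its spread rather than asserting it tightly. Published
per-strain rates cannot be recomputed without the raw counts — only fold
relations between the printed rates are checkable arithmetic, and those the
package reproduces exactly (27.8-fold ancestor/wild-type, 9.2-fold
hypermutator/ancestor).

# The synthetic-data generator

The generator emulates, with known truth, exactly the inputs the analysis
consumes:

* **Genomes** — uniform-random sequence with non-overlapping ORFs (ATG …
  stop on their own strand, length a multiple of 3, random strand), placed
  one per equal window so that any request satisfying
  `length ≥ 300·n_genes` succeeds. No operons, no overlapping genes, no
  realistic codon usage or GC skew: the genome is a coordinate system for
  planting mutations, not a model of *E. coli*.
* **Lineage-structured mutations** — a rooted genealogy with per-branch
  mutation counts; a branch's mutations are carried by exactly the tips
  below it, so truth sets are tree-compatible by construction and contain
  no homoplasy (matching the clean partition the real data shows; injecting
  homoplasy is out of scope). The substitution spectrum is sampled per
  mutation; `gc_ta_weight` (default 0.997, the study's value) sets the
  G:C→T:A share with the remainder spread uniformly.
* **Pileups** — per site, depth ~ Poisson(`mean_depth`), strand a fair
  coin, and each read reports `N`, `*`, a uniform miscall, or the template
  base with the configured probabilities. Errors are site- and
  strand-independent, and no base qualities are modelled; mapping artefacts,
  coverage waves and indels are deliberately absent (indel discovery is
  outside this pipeline's scope).
* **Assay counts** — the Luria–Delbrück model above.

A passing end-to-end test on this generator therefore shows the *logic* of
the pipeline is right — it does not show robustness to alignment artefacts,
strand bias, contamination or structural variation, which real pileups
contain and this noise model does not.

The **study-shaped table** (`simulate_study_mutations()`) is the synthetic
stand-in for the study's (unpublished, PDF-only) all-mutations supplement.
It plants 580 SNPs whose joint substitution-class × effect composition and
lineage partition equal the published marginal totals exactly (293 G→T,
285 C→A, 1 G→A, 1 C→T; 502 coding = 335 missense + 39 nonsense + 128
synonymous; 428 private to the hypermutator, 1 shared by all four, the
sister pair separated by 2), by sampling planting sites from pools
pre-classified with the package's own annotator. Three placements are
anchored to the narrative: the single universally shared SNP is intergenic
(the real one sits in a transporter operator), and the two sister-separating
SNPs are one synonymous and one missense change. The published figure prints
per-branch SNP totals only for those three facts; the three remaining branch
counts (60 private to CV101, 25 shared by the non-hypermutator trio, 64
shared by the sister pair) are fixed here once at plausible values summing
to 580 and are treated as package constants, never as checks. All
effect-class counts are *recomputed* downstream by annotation — the planted
labels are discarded — so the tabulation path is genuinely exercised.

# Problem sizes, determinism and degenerate inputs

The shipped analyses use a 120 kb / 120-gene genome for the study-shaped
table (ample site pools for every class × effect cell) and a 60 kb /
60-gene genome at 50× depth and 0.002 error for the full resequencing
emulation — sizes chosen so the complete workflow re-runs in about two
minutes while leaving every statistical check comfortably powered. All
randomness flows from one master seed through named substreams
(`stage_seed(seed, "pileup:CV103")`, ...), so any stage can be re-run in
isolation bit-identically; identical config + seed gives byte-identical
output bundles, which the tests assert file by file.

Degenerate inputs are defined, not accidents: zero planted mutations yield
an empty VCF, an all-zero spectrum and no tree (flagged); an empty genome
yields an empty pileup stream; an all-reference site is `NO_ALT`; an
all-zero assay is a boundary MLE. Contract violations — unsorted pileups,
mismatched positions or reference bases, topology/matrix strain mismatch,
out-of-range coordinates, infeasible gene packing or site exhaustion — are
immediate, specific errors.

# Known limitations

* Pileup parsing and calling are base-quality- and mapping-quality-blind,
  as was the emulated filter; indels are not called (the original study
  delegated them to a dedicated tool).
* The phylogeny module is exact but exhaustive: more than 7 strains would
  need a heuristic search that is deliberately not provided.
* The fluctuation model ignores plating efficiency, phenotypic lag and
  mutant fitness costs; rates from partially plated cultures would be
  biased low.
* The synthetic genome and noise models are idealised (see above); recall =
  precision = 1 under them is a logic check, not a claim about real reads.
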