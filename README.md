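# consortiumseq

Genomic analysis of evolved cross-feeding bacterial consortia.

When a clonal *E. coli* population evolves under long-term glucose limitation
in a chemostat, it can split into stably coexisting lineages: a dominant
glucose-scavenging clone that excretes overflow metabolites (acetate,
glycerol/glycerol 3-phosphate) and satellite clones that consume them.
Resolving how such a consortium is organised genetically takes four
computations over whole-genome resequencing of the clonal isolates and their
common ancestor:

1. **SNP calling** from samtools pileups by direct ancestor-versus-evolved
   comparison. A site is accepted when the candidate variant base (the most
   frequent non-reference base in the evolved strain, ties alphabetical) is
   carried by at least 40% of reads in the evolved strain and at most 10% in
   the ancestor, with at least 5 reads covering the position in both strains,
   a confirming variant read on both strands, and at most one ambiguous call
   (`N`) and one deletion (`*`) per strain at the site. Failures carry the
   full set of violated rules.
2. **Mutation annotation**: each SNP is classed by region (CDS/intergenic),
   codon effect under the standard genetic code (synonymous / missense /
   nonsense, e.g. `E26*`, `GAG->TAG`), directed substitution class on the
   reference strand (`G->T`, `C->A`, ...) and strand-collapsed base-pair
   class (`G:C->T:A`) — the diagnostic signature of MutY/MutM
   base-excision-repair defects — plus multi-hit gene/transcription-unit
   reports.
3. **Clonal phylogeny**: SNP presence/absence across strains is partitioned
   by carrier set and scored by Fitch small parsimony with the ancestor fixed
   at the all-absent root state; all rooted topologies are enumerated
   exhaustively (15 for four strains) and per-branch SNP counts reported.
4. **Fluctuation analysis**: per-culture rifampicin-resistant colony counts
   follow the Luria–Delbrück distribution; its pmf comes from the
   Ma–Sandri–Sarkar recursion
   `p_0 = exp(-m)`, `p_k = (m/k) * sum_{i<k} p_i / (k-i+1)`,
   the expected mutations per culture `m` are estimated by maximum
   likelihood with a profile-likelihood 95% CI, and the rate per cell per
   generation is `mu = m / Nt`.

Because the study's raw reads are not deposited, a first-class synthetic-data
module generates every input with known ground truth — annotated genomes,
lineage-structured planted SNPs with a configurable G:C→T:A-biased spectrum,
per-strain pileups with sequencing noise, and Luria–Delbrück mutant-count
vectors — so each stage is testable end to end.

## Worked example

```r
library(consortiumseq)

# synthetic consortium: 4 evolved strains, study-shaped lineage, 580 SNPs
st <- simulate_study_mutations(seed = 1)
pc <- partition_counts(presence_matrix(st$mutations))
partition_subset(pc, "CV103")
#> [1] 428
sp <- summarize_spectrum(annotate_mutations(st$genome, st$truth))
sp[sp$count > 0, ][1:5, ]
#>                                 row count   pct
#> 1                              SNPs   580 100.0
#> 2            SNPs in coding regions   502  86.6
#> 3 SNPs causing synonymous mutations   128  22.1
#> 4   SNPs causing missense mutations   335  57.8
#> 5   SNPs causing nonsense mutations    39   6.7

# parsimony tree rooted on the ancestor, with per-branch SNP counts
best_topology(presence_matrix(st$mutations))$best
#> <clado_tree> ((CV101,(CV115,CV116)),CV103)  (parsimony length 580 on 580 loci)
#>   {CV101,CV103,CV115,CV116}                1
#>   {CV101,CV115,CV116}                      25
#>   {CV101}                                  60
#>   {CV115,CV116}                            64
#>   {CV115}                                  1
#>   {CV116}                                  1
#>   {CV103}                                  428

# fluctuation analysis: 1000 cultures simulated at m = 2, MSS-MLE recovery
d <- assay_design(mu = 2e-8, N0 = 1e3, Nt = 1e8, n_cultures = 1000, seed = 5)
mss_mle(simulate_fluctuation_assay(d), Nt = 1e8)
#> <rate_estimate> m = 2.048 (95% CI 1.932-2.168), mu = 2.048e-08 /cell/gen, n = 1000

# fold relations between published per-strain rates
rate_and_fold(1.00e-7, 3.60e-9)   # mutator ancestor vs wild type: 27.8
rate_and_fold(9.20e-7, 1.00e-7)   # hypermutator vs ancestor: 9.2
```

The parsimony length equalling the locus count (580) is the no-homoplasy
signature: every SNP is explained by a single gain on one branch, and the
branch totals say the hypermutator lineage (CV103, 428 private SNPs)
diverged from the other three — which share only one SNP with it — early in
the experiment.

## Analysis workflow

Numbered drivers under `analysis/` rebuild the whole analysis into
`results/` (run from the repository root, in order):

```sh
Rscript analysis/01_simulate_community.R   # genome + 580-SNP mutation table
Rscript analysis/02_call_snps.R            # pileup simulation + SNP calling
Rscript analysis/03_mutation_spectrum.R    # annotation, spectrum, multi-hit
Rscript analysis/04_phylogeny.R            # partition + parsimony tree
Rscript analysis/05_mutation_rates.R       # fluctuation assays + fold table
```

## Vignette

`vignettes/consortium-genomics.Rmd` describes the models and the reasoning
behind the tunable parameters, the synthetic-data design, numerical choices
and known limitations.
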