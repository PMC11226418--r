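---
title: "Identifying and characterizing EMS-induced SNPs with emsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterizing EMS-induced SNPs with emsift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsift)
```

## The problem

EMS mutagenesis introduces point mutations — predominantly G/C→A/T
transitions — throughout a plant genome. After resequencing a panel of
mutagenized individuals (here called mutants) alongside unmutagenized
controls of the same parent line (wild types), a joint SNP call against a
reference genome mixes four signals:

* **induced mutations**, private to individual mutants — the signal;
* **parent-line divergence** from the reference, fixed in every sample;
* **control heterogeneity**, residual segregating variation or genotyping
  noise among the wild types;
* **assembly artifacts** on unplaced scaffolds.

`emsift` separates these with a genotype-pattern cascade and then
characterizes the retained mutations. This vignette documents the model,
its assumptions, the tunable parameters, and the design decisions taken
where the procedure admits more than one reasonable reading.

## The filtering cascade

A site is a biallelic SNP with one unordered genotype per sample (missing
genotypes are first-class; multiallelic records are decomposed per
alternate allele beforehand, and a genotype that refers to a different
alternate is treated as missing at the decomposed site). The five steps,
applied in order:

1. **Wild-type consensus.** Keep a site only when every control carries
   the same, non-missing genotype; that genotype becomes the consensus.
   A missing control genotype removes the site: a consensus that cannot be
   certified is treated as inconsistent, which is the conservative choice
   (it can only cost recall at sites we could not have trusted anyway).
2. **Background divergence.** Keep a site only when the consensus is
   homozygous reference. A heterozygous consensus is also removed: the
   parent line is not the reference line, and any certified deviation of
   the controls from the reference is background, not mutagenesis.
3. **Shared among mutants.** Remove sites where all mutants carry one
   identical, non-missing, non-reference genotype. Independent induced
   mutations cannot be identical in everyone. Requiring *non-reference*
   matters: an all-reference mutant pattern is not evidence of anything and
   is left for the later steps rather than silently deleted here.
4. **Placed chromosomes.** Remove sites on unplaced scaffolds; the
   per-chromosome statistics are defined over the placed set only.
5. **Uniqueness.** Keep a site only if some mutant's non-missing genotype
   differs from every other mutant's. A missing genotype in *another*
   mutant does not block uniqueness (it is unknown, and insisting it might
   match would discard every site with any missingness); a missing genotype
   in the candidate mutant itself never certifies uniqueness.

Attribution then assigns each surviving site to every mutant whose genotype
is non-missing and differs from the consensus, recording zygosity
(homozygous when both alleles equal the alternate). One site may belong to
several mutants — the uniqueness rule requires only one of them to be
unique.

Two properties are worth stating because the tests rely on them: each step
conserves sites (`in = removed + out`), and steps 3–5 are pure per-site
predicates, so they commute pairwise; the order used is simply the
canonical one. An alternative reading of steps 1–2 — "collect the SNPs
shared by the wild types and subtract them" — produces the same kept set on
clean genotypes and differs only under missingness; the certify-consensus
reading used here is the stricter of the two.

## Effect annotation

Gene models are reduced to one transcript per gene (the longest CDS).
Every attributed SNP gets one effect call per nearby gene model:

* inside a CDS → the affected codon is rebuilt from the reference
  (reverse-complemented for minus-strand genes), the alternate base is
  substituted, and both codons are translated with the standard nuclear
  code: `stop_gain` (alternate codon is a stop, reference is not),
  `synonymous` (same amino acid), otherwise `non_synonymous` — stop-loss
  and start-loss changes are folded into `non_synonymous` rather than
  given their own classes;
* inside the gene span but outside the CDS → `intron`;
* within a window 5′ of the gene start / 3′ of the gene end (strand-aware)
  → `upstream` / `downstream`. The window defaults to 5,000 bp, the
  conventional annotation default, and is configurable;
* no gene within the window → `intergenic`.

For per-SNP summaries each SNP is reduced to its single most severe call
with the documented order `stop_gain > non_synonymous > synonymous >
intron > upstream > downstream > intergenic` (upstream and downstream are
equal in rank; the tie is broken toward upstream for determinism). The
seven categories above are an explicit, documented scheme: annotation
taxonomies vary between tools, and splice-site or UTR classes are
deliberately out of scope.

## Descriptive statistics

Substitutions are pooled by strand symmetry into six classes (G→A counts
with C→T, and so on), two transitions and four transversions; the spectrum
of an empty call set is an error rather than a silent `0/0`. Per-chromosome
mutation frequency is count divided by the exact chromosome length in
bp/10⁶; summary rows append Sum, Average, Min and Max per mutant, where
**Average is the unweighted mean over chromosome rows** (`Sum / 18`), not
total SNPs over total Mb — the convention under which the packaged
frequency-table fixture reproduces its own printed summary rows. Rounding
(1 decimal) is presentation-only.

## Chromosome-length scaling

Whether mutation counts scale with chromosome length is assessed per mutant
by OLS of count on length (Mb): slope, intercept, R², and the two-sided
slope t-test p-value on n−2 degrees of freedom, reported unadjusted per
mutant. A constant response is reported as R² = 0 with p = 1; constant
lengths are an error because the slope is undefined. With the equal-length
default simulator genome the regression is therefore undefined by design —
scaling questions need a genome with varying lengths.

The ranking comparison builds average-linkage dendrograms over chromosomes
from the absolute differences of a scalar (length, or per-mutant count).
The agglomeration is implemented directly (n = 18 labels, so the cubic
algorithm is irrelevant to runtime) because a *documented deterministic tie
rule* is required for reproducible trees on tied data: among
minimum-distance pairs, merge the pair containing the earliest original
label; all-equal input yields a caterpillar in label order. On tie-free
data the result coincides with `stats::hclust(..., "average")` (asserted in
the tests via cophenetic distances). Entanglement between two trees over
the same labels is `sum(|rank1 − rank2|^L)` normalized by the same sum
under a fully reversed ranking — 0 for identical leaf orders, 1 for exactly
reversed — with L = 1.5, the default of the conventional tanglegram
implementation. Because the linkage/distance conventions behind published
tanglegrams are rarely recoverable, scores are reported both raw and after
greedy untangling (child-flips that strictly lower the score, to a local
optimum); the greedy search never increases the score and is idempotent.

## GO over-representation

Gene lists (non-synonymous or stop-gain genes per mutant) are tested
against a gene→GO table with the upper-tail hypergeometric probability,
computed in log space, and Benjamini–Hochberg adjustment (step-up with a
cumulative-minimum monotonicity pass). Both primitives are implemented in
the package and cross-checked in the tests against exact combinatorial
arithmetic, `stats::phyper`, and `stats::p.adjust`. The universe is the
set of genes with at least one annotation — the conventional ORA default —
and selected genes without annotation are dropped from the selection size
with a message. Defaults: minimum term size 3, adjusted p < 0.05; raw
p-values are always emitted as well, since published "significant" GO terms
are often quoted raw. Note the exact test is conservative under
discreteness: under random selection the fraction of terms with raw
p < 0.05 is *at most* 0.05, and the tests compare the Monte-Carlo rate to
the exactly computed expectation for the simulated universe rather than to
the nominal level. No GO-graph propagation is performed.

## The synthetic-study simulator

The simulator emulates the data structure the cascade assumes, with known
ground truth:

* **Genome** — 18 placed chromosomes (default 1 Mb each) plus unplaced
  scaffolds, i.i.d. uniform sequence except within CDS, which is rewritten
  as a valid ORF (ATG, stop-free body, terminal stop; reverse-complemented
  onto minus-strand genes) so codon-level annotation is exercised without
  spurious reference stops. Genes (default 30 per Mb, mean CDS 900 bp,
  half with one intron) are placed without overlap; synthetic GO terms
  (40 terms, ~2 per gene) attach to genes.
* **Background divergence** — per-bp rate 5 × 10⁻⁴ of sites homozygous
  alternate in *every* sample, modelling fixed parent-vs-reference
  differences (the parent line is assumed close to the reference; step 2
  removes these).
* **Control noise** — rate 5 × 10⁻⁵ of sites where one wild type deviates
  (step 1 removes these).
* **EMS mutations** — per-mutant counts drawn log-uniformly from
  500–5,000 by default, mimicking the order-of-magnitude count
  heterogeneity seen between mutagenized individuals at desk scale;
  each mutation is private to one mutant, with substitution class drawn
  from a spectrum with transition fraction 0.6 of which 0.7 are C/G>T/A
  (the EMS-preferred class) and the C/G>G/C transversion depressed;
  zygosity is Bernoulli with homozygous fraction 1/3 — the expected
  homozygote share among selfed-progeny carriers of a heterozygous induced
  allele.
* **Stress sites** — optional mutant-shared sites (exercise step 3) and
  mutant-private sites on scaffolds (exercise step 4); both are recorded
  in the truth tables separately from the EMS truth.
* **Missingness** — each genotype is independently replaced by missing at
  rate 0.01 by default.

All planted site categories occupy disjoint positions, and every planted
site appears in the emitted VCF, so exact set recovery is the expected
outcome on clean data: the recovery tests assert precision = recall = 1
with missingness disabled, and any miss is a bug, not noise. What the
simulator does **not** emulate: read-level errors and coverage-dependent
genotyping noise, linked inheritance across selfing generations, selection,
non-uniform base composition, and real gene structure (UTRs, alternative
isoforms). Passing tests therefore demonstrate the correctness of the
set logic, the annotation arithmetic and the statistics — not robustness
to upstream variant-calling artifacts, which the cascade's consensus and
uniqueness rules only partially absorb.

## Numerical choices and degenerate inputs

* Genotypes are unordered pairs; phasing is ignored.
* Empty call sets: frequency rows are defined (all zero) but spectrum
  proportions are an error; enrichment of an empty gene list warns and
  returns an empty table.
* Hypergeometric tails are summed in log space and clamped to ≤ 1;
  `k = 0` returns exactly 1.
* Entanglement uses ranks, so it is invariant to relabeling and symmetric
  in its arguments.
* Problem sizes in the test-suite simulations (3–18 chromosomes of
  0.05–1 Mb, hundreds to thousands of planted mutations per mutant) were
  chosen as the smallest sizes at which the binomial 3σ recovery bounds are
  informative.

## A worked run

```{r example}
cfg <- sim_config(seed = 7, chrom_lengths = rep(2e5, 6),
                  unplaced_lengths = 5e4,
                  ems_count_range = c(50, 200), missing_rate = 0)
study <- simulate_study(cfg)
run <- run_pipeline(study = study)
run$trace
run$truth_scores[run$truth_scores$mutant == "overall", ]
spectrum(run$callsets$calls$R2)
```

## Known limitations

* The cascade is rule-based, not probabilistic: it has no notion of
  genotype quality and treats every call at face value.
* Insertions/deletions are out of scope; non-SNP records are counted and
  skipped at import.
* The uniqueness rule's treatment of missing genotypes in *other* mutants
  (non-blocking) is one of two defensible readings; under heavy
  missingness the two readings diverge.
* Greedy untangling finds a local optimum; exact minimal entanglement is a
  hard ordering problem and is not attempted.
* Real-data mutation totals, R² values, entanglement scores and GO term
  lists depend on the upstream alignment/calling stack and the annotation
  resource, and are not reproduced by this package's desk-scale
  validation.
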