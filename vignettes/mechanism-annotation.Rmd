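---
title: "Annotating GWAS loci with molecular mechanisms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating GWAS loci with molecular mechanisms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanista)
```

# The problem

A GWAS marker SNP tags a region, not a mechanism. Somewhere in linkage
disequilibrium with the marker sits a variant whose presence changes the
activity of a gene product — through an amino-acid substitution, a change
in transcript abundance, or altered splicing — and that change propagates
to disease risk. `mechanista` formalises the annotation of such loci: which
variants *could* be the mechanism variant given the LD structure, and which
of five mechanism classes does the evidence support for each locus.

This vignette documents the model, its assumptions, every tunable
parameter, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the problem left them open.

# The two-SNP odds-ratio model

## Forward model

Consider a candidate SNP (risk allele `a`, population frequency `p_a`) and
a marker SNP (risk allele `b`, frequency `p_b`) with joint haplotype
frequencies `h_AB, h_Ab, h_aB, h_ab`. Three assumptions define the model:

1. **Multiplicative per-allele risk at the candidate.** Disease odds are
   multiplied by a constant factor per copy of `a`. The case frequency of
   `a` is then `q_a = or_c p_a / (1 - p_a + or_c p_a)`.
2. **Rare-disease approximation.** Controls are well approximated by the
   population haplotype panel; no prevalence correction is applied (the
   simulator has a prevalence knob, the analysis does not use one).
3. **The marker is associated only through the candidate.** Conditional
   probabilities `P(b|a)` and `P(b|A)` are the same in cases as in the
   population, so the case marker frequency is
   `q_b = q_a P(b|a) + (1 - q_a) P(b|A)` and the marker odds ratio follows
   as `odds(q_b)/odds(p_b)`.

## Inverse model and acceptance

Candidate screening inverts this map: given the observed marker odds ratio,
solve for `q_a`. The solution exists in closed form and is *feasible* only
when `0 < q_a < 1`. Infeasibility is an informative outcome — the SNP's LD
relationship and frequency cannot generate the observed case/control
difference, so it is not a candidate — and is deliberately not an error.
When `D = 0` the marker carries no information about the candidate and the
inversion is undefined; that *is* an error at the operation level, and a
plain rejection at the pipeline level.

Two useful identities hold and are enforced by property tests: the
forward and inverse maps are mutual inverses to 1e-9 over randomized
feasible instances, and for `D > 0`, `or_m > 1` the implied candidate odds
ratio is never smaller than the marker's (attenuation: imperfect LD dilutes
an effect, so reproducing the marker signal needs a stronger causal one).

## Orientation and odds-ratio scale

The candidate allele positively associated with the marker risk allele
(the sign of D) is taken as the putative risk allele — the only orientation
consistent with a shared mechanism. All odds ratios are treated as
per-allele (allelic); no conversion between genotypic and allelic scales is
attempted anywhere. The one genotypic value in the package — the worked
example's homozygote-vs-homozygote odds ratio of 1.84 — is used only in the
sensitivity model, where it enters as a phenotype contrast between
genotypes, not as input to the LD engine.

# Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_bp` | 200000 | bp | candidate search half-window around a marker; inclusive at the boundary |
| `maf_min` | 0.05 | — | below 5% MAF, panel LD estimates are too unreliable; inclusive |
| `p_threshold_primary` | 5.0e-7 | — | strict bound for primary-scan markers |
| `p_threshold_catalog` | 1.0e-5 | — | strict bound for catalog markers (follow-up studies, meta-analyses) |
| `r2_floor` | 0.2 | — | see below; 0 restores the feasibility-only rule |
| `eqtl_match_cm` | 0.05 | cM | maximum marker-to-eQTL distance for a shared mechanism |
| `eqtl_consensus_r2` | 0.8 | — | strict lower bound for linking two eQTL markers of one gene |
| `eqtl_linkage` | single | — | cluster linkage for eQTL markers (see below) |
| `splice_thresholds` | inert | — | per-interval score-change thresholds; must be calibrated for real use |
| `mhc_interval` | chr6:28,477,797–33,448,354 | bp | hg19 extended MHC; genes and loci here are category D |
| `prevalence` | 0.01 | — | simulator only |

**The r² floor.** The feasibility criterion alone admits weak-LD candidates
whose implied odds ratios are wildly amplified (a candidate at r² = 0.01
"explaining" a marker OR of 1.3 would need an absurd effect). A documented,
tunable floor of 0.2 screens these; setting it to 0 reproduces the literal
feasibility rule, and the test suite pins both behaviours on the same
hand-checked haplotype configuration (r² ≈ 0.127: feasible with implied
OR exactly 3.0, yet below the default floor).

**Boundary conventions.** Positions exactly at ±200 kb and MAF exactly 0.05
are included ("up to" semantics, declared explicitly and tested).
Thresholded comparisons on p-values are strict; score-change thresholds
flag at equality (≥). All coordinates are 1-based inclusive (VCF/GFF
convention) everywhere; the only places a shift happens are the BED12
reader and writer, which convert BED's 0-based half-open fields at the file
boundary — one audited conversion site rather than a dual internal
convention.

# Mechanism calls

**Missense.** Impact labels (`high`/`low`) are inputs, produced upstream by
protein-impact predictors; the package deliberately does not reimplement
them. At locus level high and low are mutually exclusive: any high-impact
call makes the locus "high". A SNP that is both missense and a splicing
candidate yields both calls — calls are evidence, not a partition.

**Direct splice sites.** At each internal exon junction, in transcription
order: the first two intron bases (donor) and last two (acceptor); the last
three bases of the upstream exon (donor side) and the first base of the
downstream exon (acceptor side). Minus-strand genes mirror the rules.
Terminal exon ends have no junction and are never hits: the rules are
stated for splice junctions, and applying the exonic rules at transcript
ends would manufacture sites with no intron to splice. Exons shorter than
three bases clamp the exonic donor window to the exon. The detector is
verified against a brute-force base-by-base scan on both strands.

**Auxiliary splicing.** Splice-scorer score changes are inputs
(the scoring algorithm itself is out of scope; the contribution here is the
interval-specific thresholding). A record is flagged when its score change
meets the threshold of the interval containing its signed distance
(negative = exonic side, |distance| ≤ 80). The shipped default is a single
all-covering interval with threshold 0 per site type — an inert placeholder
that flags any reported score change — because honest per-interval
thresholds must be calibrated on known splice-affecting mutations, and
inventing numbers would be worse than requiring them. The synthetic
scenario supplies its own scenario-level thresholds (donor [−3,6] at 0.5,
flanks at 0.8; acceptor [−3,3] at 0.5, graded flanks at 0.7/0.9) so that
thresholding logic is exercised rather than bypassed.

**Expression.** eQTL relations from multiple study tables are clustered per
gene under the relation "identical marker OR r² > 0.8"; clusters reported
by ≥ 2 distinct studies become consensus eQTLs. Single-study relations
never reach a call — this is the package's defence against the low
reproducibility of individual eQTL studies, at the cost of discarding some
true positives. A disease marker matches a consensus when it is a cluster
member or within 0.05 cM of the *nearest* member (nearest-member rather
than centroid: the cluster is a set of tags for one signal, and its spatial
centroid has no genetic meaning). Distances across chromosomes are errors,
not large numbers. Direction conflicts between studies are flagged, not
discarded: the replication criterion is study count, not concordance.

**Linkage choice.** "Markers in LD to each other" is ambiguous for three or
more markers. Single linkage (connected components) is the default —
generous, transitive tagging of one signal; a strict complete-linkage mode
(`eqtl_linkage = "complete"`) requires all pairs linked. Marker sets are
canonically sorted before clustering, making the outcome independent of
record order (property-tested).

# Aggregation and statistics

Locus profiles collapse missense to one slot, so a locus has 0–4 mechanism
types. Relevance categories are curated inputs (A: mechanism already
recognised; B: protein implicated, mechanism not established; C: no prior
link; D: MHC), never inferred; locus category takes A over B over C, with
MHC loci reported separately as D.

Enrichment of each mechanism in known disease-relevant proteins uses a
two-tailed Fisher exact test defined by the probability-mass criterion
(sum of hypergeometric probabilities ≤ the observed table's, with a 1e-7
relative guard against floating-point ties — the same convention as R's
reference implementation, stated explicitly so results are reproducible
bit-for-bit). Raw p-values are reported; no multiplicity adjustment is
applied, matching the practice of reporting against fixed thresholds. The
test is verified by exhaustive enumeration against an exact integer-count
oracle for all tables with N ≤ 56 (the largest N at which the counts are
exactly representable as doubles) and against the reference implementation
for N up to 60.

The sensitivity model is three closed forms — `δA = 1/fold − 1` (loss) or
`fold − 1` (gain); `δP = OR − 1`; `S = δP/|δA|` by default, signed on
request — plus the linear combination `δP_q = Σ S_iq δA_i` and the drift
bound `1/(2 Ne)`. The magnitude convention for S matches the way a
loss-of-function variant that increases risk is quoted as a positive
coupling strength; the signed mode is there because the sign carries
direction-of-action information some analyses need.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuned.

* **LD structure** by symmetric allele-flip: the marker column copies the
  causal column with probability `sqrt(target_r2)` and redraws otherwise.
  Expected squared correlation equals the target exactly; realised r² on a
  400-haplotype panel is within a few hundredths. This gives exact control
  of r² with no external simulator, at the price of realism: no
  recombination maps, no allele-frequency spectrum, no haplotype blocks.
* **Cohorts** by retrospective sampling (case/control-conditional), the
  actual design of a GWA study: controls are panel draws, case haplotypes
  carry the risk allele at its case frequency and inherit linked alleles
  from the panel conditionals. Prevalence is fixed at 0.01 and only
  matters for interpreting the rare-disease approximation.
* **Default scenario**: 20 loci, one per chromosome, marker at 500 kb,
  causal SNP 1 kb away (0.001 cM on the 1 cM/Mb linear map), 400
  haplotypes, causal allele frequency uniform on [0.10, 0.40], target r²
  uniform on [0.60, 0.95], causal odds ratio uniform on [1.5, 2.5], eight
  neutral SNPs per locus including one below the MAF floor and two beyond
  the window (so the filters are exercised), and one planted mechanism per
  locus cycling through the five classes. Marker odds ratios are computed
  *through the forward model* from the planted causal effect, so the
  pipeline's inversion must recover the planted value exactly. Every locus
  also carries a single-study decoy eQTL that the consensus rule must
  reject. Labels are noise-free.

These sizes keep the full suite fast at desk scale while leaving every
statistical property testable; they are stated here as the package's
validation conditions. What passing these tests shows: the algebra, the
filters, the clustering and the aggregation do exactly what they claim on
data satisfying the model's assumptions. What it does not show: robustness
to real LD structure, tagging of untyped variants, annotation error, eQTL
direction noise, or overlapping loci — real-data properties the generator
deliberately does not emulate.

# Numerical choices and degenerate inputs

* Haplotype frequencies must sum to 1 within 1e-9; monomorphic SNPs are
  errors in the LD engine and silently infeasible candidates in selection.
* `D = 0` detection uses |conditional difference| < 1e-12.
* Genetic-map interpolation clamps positions beyond the outermost anchors
  to the end anchor's cM, with a counted warning — extrapolating a genetic
  map invents recombination that was never observed.
* Markers of one disease within one window merge into a single locus keyed
  by the lowest-p ("representative") marker; ties break by marker id.
* Loci with no accepted candidate have a point extent at the marker.
* Single-gene 2×2 tables and empty mechanism sets give p = 1, not errors.
* All report writers emit deterministic text; manifests carry the full
  effective configuration and seed, and two runs with equal manifests are
  byte-identical (tested at the byte level).

# Known limitations

* One transcript per gene: splice-site enumeration needs a single exon
  chain, so the GFF3 reader accepts exactly one transcript per gene and
  the choice of transcript is the caller's.
* No imputation, no conditional multi-signal dissection of loci, no
  covariate adjustment, no colocalisation posteriors, no tissue
  specificity for eQTLs, no trans/remote (spatial-proximity) expression
  effects, no liftover between assemblies.
* The implied-OR inversion has no upper plausibility bound on the implied
  odds ratio; none is applied deliberately (the r² floor already screens
  the pathological cases, and a hard cap would hide the attenuation
  behaviour the model predicts).
* The linear sensitivity model is a first-order approximation; epistatic
  and higher-order terms are omitted as undetectable at realistic GWAS
  sample sizes, and S serves as a qualitative coupling scale rather than a
  measured constant.
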