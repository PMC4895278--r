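---
title: "Modelling allele-specific isoform expression from a diploid transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling allele-specific isoform expression from a diploid transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

RNA-Seq reads from a diploid individual carry two kinds of ambiguity at
once: a short read may fit several isoforms, and — because the paternal
and maternal copies of a transcript differ only at sparse heterozygous
sites — it usually fits both haplotypes of whichever isoform it came
from.  Counting only the reads that happen to cover a heterozygous SNP,
as best-alignment pipelines do, throws away most of the library and
yields allelic ratios with mass piled at exactly 0 and 1 whenever
coverage is low.  `asequant` instead treats the isoform choice, the
haplotype choice and the start position of every read as latent
variables of one generative model and estimates isoform abundances and
allelic preferences jointly.

## The generative model

For each of $N$ independent reads, the model draws

* an isoform $T_n = t$ with probability $\theta_t$, where
  $\sum_{t=0}^{T}\theta_t = 1$ and component $t=0$ is a reference-free
  noise component (below);
* a haplotype $H_n \in \{0,1\}$ (0 paternal, 1 maternal) with
  probability $\phi_t$ for the paternal copy;
* a start position $S_n = s$ uniformly over the
  $l_{th} - L + 1$ placements of an $L$-long read on the chosen cDNA,
  i.e. $p(S_n = s \mid t, h) = 1/(l_{th} - L + 1)$;
* the observed bases $R_n$ through a quality-dependent substitution
  model, $p(R_n \mid t,h,s) = \prod_x \mathrm{subst}(r_n[x], q_n[x],
  c_{th}[x])$.

With a Phred quality $q$ and error probability
$\varepsilon = 10^{-q/10}$, the substitution matrix is
$1-\varepsilon$ on the diagonal and $\varepsilon/3$ off it; an `N` read
base scores $1/4$.  The off-diagonal split is not dictated by the Phred
definition — `asequant` also offers an empirical matrix estimated from
the best alignments (`estimate_subst_matrix()`), binned at integer
qualities capped at 40, which captures any asymmetry the analytic form
misses.  Each inserted or deleted base in an alignment contributes a
flat `indel_open_prob` (default $10^{-3}$, matching typical sequencer
indel rates); no affine gap extension is modelled.  Soft-clipped bases
are excluded from the product and counted.  For paired-end data a
fragment is a single latent placement: both mates' emission terms are
summed and the position prior uses the observed fragment span $f$,
$1/(l_{th} - f + 1)$, with no fragment-length density term — the
minimal extension of the single-end formula.

The candidate set $\pi_n$ of a read — every $(t, h, s)$ it can align
to — comes from the BAM file of an aligner run in report-all mode, with
secondary alignments (flag 0x100) retained.

## Variational inference

Conjugate priors are a symmetric Dirichlet $\alpha_0$ over
$\boldsymbol\theta$ and a Beta$(\beta_{t,1}, \beta_{t,2})$ per isoform
over $\phi_t$, with $\beta_{t,1} = \beta_{t,2} = 1$ by default.
Assuming $q(\boldsymbol\theta,\boldsymbol\phi,\mathbf Z) =
q(\boldsymbol\theta)\,q(\boldsymbol\phi)\,q(\mathbf Z)$, coordinate
ascent alternates:

* **E-step** — responsibilities over each $\pi_n$,
  $E[Z_{nths}] \propto \exp\{E[\log\theta_t] + E[\log\phi_t]\ (\text{or }
  E[\log(1-\phi_t)]) + \log p(S_n|\cdot) + \log p(R_n|\cdot)\}$,
  normalized in log space (log-sum-exp);
* **M-step** — $\alpha^*_t = \alpha_0 + \sum E[Z_{nt\cdot\cdot}]$ and
  $\beta^*_{t,1},\beta^*_{t,2}$ accumulate the haplotype-split
  responsibility mass, so the posteriors stay Dirichlet and Beta and all
  expectations are digamma expressions.

The evidence lower bound $L(q)$ is computed after every M-step from its
six-term decomposition and is non-decreasing by construction; the trace
is kept on the fitted object.  $\alpha_0$ is chosen by running the fit
over a grid (default $\{0.01, 0.1, 1\}$) and taking the value with the
largest converged $L(q)$, ties toward the sparser prior.

The posterior mean ratio $E[\phi_t] = \beta^*_{t,1} /
(\beta^*_{t,1}+\beta^*_{t,2})$ is the method's headline output: the
Beta(1,1) prior adds one pseudo-read to each allele, so low-coverage
isoforms shrink toward 0.5 instead of snapping to 0 or 1 — the add-one
(Laplace) smoothing that removes the extreme-ratio peaks the
best-alignment baseline produces.

### Convergence

Iteration stops when no abundance $E[\theta_t] > 10^{-7}$ *and no
allelic fraction* $E[\phi_t]$ changes by more than a relative $10^{-3}$.
Tracking only $\theta$ — the textbook statement of the stopping rule —
is not enough here: $\theta$ reaches its fixed point within a few
iterations because almost every read is unambiguous about its isoform,
while $\phi$ is informed only by the minority of reads overlapping
heterozygous sites and approaches its fixed point geometrically, with a
contraction rate governed by the uninformative-read fraction.  Stopping
on $\theta$ alone leaves every $\phi_t$ roughly half-way to its value
(we measured class means of 0.59 instead of 0.78 at desk scale), so
both parameter blocks are tested.  The iteration cap is 1000.

### The noise component

Component $t=0$ has no sequence and no allelic fraction.  Reads whose
candidate set is empty (unalignable reads) contribute unit
responsibility to it, so total pseudo-count mass obeys
$\sum_t (\alpha^*_t - \alpha_0) = N$ at every iteration; its emission
probability is the constant 1, which keeps the bound monotone.
`drop_unaligned = TRUE` discards such reads instead, reproducing the
alternative bookkeeping.

### Numerical choices

Responsibilities are normalized by per-read log-sum-exp; a read whose
candidates all underflow is reassigned to the noise component with a
warning.  Pseudo-count accumulators are summed in a fixed candidate
order (read-major), so results are independent of any parallel
partitioning of reads.  Candidates whose span exceeds the cDNA length
are invalid and dropped.  With identical haplotype sequences everywhere,
candidate pairs stay exactly symmetric and every $E[\phi_t]$ remains
exactly 0.5 — a useful degeneracy check.

### Accuracy against the exact posterior

On problems small enough to enumerate, the converged bound never
exceeds the exact log marginal likelihood, equals it for unambiguous
reads, and the abundance means track the exact posterior closely.  The
factorized posterior does bias $E[\phi_t]$ outward when an isoform has
a single allele-informative read among several haplotype-ambiguous
ones — the ambiguous reads are split according to the current
$\phi$ estimate, compounding its pull; at counts of three or four reads
the bias can reach $\approx 0.04$.  It vanishes quickly as informative
coverage grows and is negligible at the ten-read reporting filter.

## ASE calling and the baseline

`call_ase()` classifies a ratio $\ge 0.75$ as paternal ASE and
$\le 0.25$ as maternal ASE (inclusive), provided the isoform has
heterozygous evidence (at least one het SNP, or a het indel) and at
least 10 assigned reads (expected counts rounded down).  Gene-level
calls use the expression-weighted mean of the gene's isoform ratios —
the aggregation is a documented choice; per-isoform calls are always
available.  `baseline_ase()` implements the comparator: each read goes
to its best-scoring alignment, ties across haplotypes are discarded as
uninformative, and only reads overlapping a het site count toward an
allele, with no pseudo-counts — so its ratio distribution shows the 0/1
peaks at low coverage.  For the baseline the ten-read filter counts the
reads best-assigned to the isoform.

## What the simulator emulates

`sim_config()` defaults encode the reference simulation design:
log-normal expression ($\mu = 4$, $\sigma = 1$ on the natural-log
scale — the distribution family is standard, the parameters are this
package's choice), 10 % paternal-ASE and 10 % maternal-ASE isoforms at
80:20, the rest 50:50 (or all 50:50 in null mode), paired 100 bp reads
with fragment length $400 \pm 40$, and 0.1 % substitution, insertion
and deletion errors each.  Isoform lengths are uniform on 400–4000 bp,
haplotypes differ by about one SNP per kb plus an occasional 1–3 bp
indel.  Isoform sampling weight is $\theta_t$ times the effective
number of fragment placements, so read counts rather than molar
fractions follow $\theta$ at equal lengths; evaluation therefore
compares expected read counts against realized fragment counts,
sidestepping the length factor.  Simulated qualities are constant
Phred 30, so the analytic substitution matrix is exactly calibrated to
the injected substitution rate.  Fragment lengths are rounded normals
truncated to `[read_len, l_th]`, re-drawn on failure.

The built-in `toy_align()` is a test-scale stand-in for a report-all
aligner: exact 20 bp seeds from both mates in both orientations,
ungapped extension, up to 3 mismatches per mate, FR mate pairing on the
same isoform/haplotype.  Because extension is ungapped, a mate carrying
a sequencer indel usually exceeds the mismatch cap and its fragment
lands in the noise component (roughly a third of fragments at the
default 0.1 % + 0.1 % indel rates).  That loss is uniform across
isoforms, so abundance correlations and allelic ratios are unaffected
beyond the reduced effective depth — but it does mean the simulation
exercises the noise sink far more than a production aligner would, and
absolute expected counts undershoot true fragment counts by a roughly
constant factor.  What passing desk-scale tests therefore demonstrate
is the recovery of *relative* abundances and allelic fractions under
realistic error and ambiguity, not the behaviour of any specific
external aligner, nor positional/GC bias, PCR duplicates or real
variant maps, none of which are simulated.

Desk-scale checks in this package use 200 isoforms and 100,000 fragment
pairs (with 3-isoform/10-read instances for the exact-posterior
cross-checks and 20–30 isoforms for degeneracy checks); these sizes were
chosen so the whole validation suite runs comfortably on a laptop while
keeping per-isoform coverage near the full-scale study's average.

## Reproducing the full-scale study (external data)

The published full-scale experiment — 30 million 100 bp read pairs
against the NA12878 diploid transcriptome, RMSE 0.778 on log expected
counts — needs external data and a real aligner, and is out of desk
scope.  The workflow is:

```sh
# 1. diploid genome for NA12878 (or build one with vcf2diploid from a
#    phased VCF); then extract per-haplotype cDNA with rSeq against
#    refFlat annotation, tagging references _paternal/_maternal
rseq generate-transcripts paternal.fa refFlat.txt   # and maternal

# 2. align against the concatenated diploid cDNA, reporting all hits
bowtie2 -k 200 -x diploid_cdna -1 reads_1.fq -2 reads_2.fq | \
  samtools view -b -o all_alignments.bam

# 3. quantify
asequant quantify --paternal paternal.fa --maternal maternal.fa \
  --alignments all_alignments.bam --alpha0 0.01,0.1,1 --out results/
```

```{r}
# equivalent in R
tx  <- read_diploid_transcriptome("paternal.fa", "maternal.fa")
aln <- read_diploid_alignments("all_alignments.bam", tx)
fit <- ase_fit(aln, tx)
summary(fit)
```

At that scale the grid search selects $\alpha_0 = 0.1$ in the published
analysis; the desk-scale simulation (`sim_config()` defaults with 200
isoforms) is the supported in-package analogue and is what the
acceptance script exercises.

## Known limitations

* Mean-field bias on $E[\phi]$ at very low informative coverage, as
  quantified above.
* The paired-end position prior ignores the fragment-length
  distribution; two placements of the same fragment differing in
  implied length are weighted only by $1/(l_{th}-f+1)$.
* The toy aligner is ungapped and exact-seeded; indel-bearing reads are
  recovered only through a real aligner's gapped alignment.
* Gene-level aggregation assumes the expression-weighted mean is the
  quantity of interest; alternative rules (all-isoforms-pass) are easy
  to apply downstream from the per-isoform table.
* One global $\alpha_0$ is shared by all isoforms, including the noise
  component.
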