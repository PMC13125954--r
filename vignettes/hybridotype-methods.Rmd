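---
title: "Genotype, ploidy and ancestry analysis for hybridogenetic water frogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype, ploidy and ancestry analysis for hybridogenetic water frogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological setting

European water frogs of the genus *Pelophylax* include a hybridogenetic
hybrid, the edible frog *P. esculentus*, formed from the pool frog
*P. lessonae* (the "L" genome) and the marsh frog *P. ridibundus* ("R").
Because the two parental genomes never recombine in the hybrid and one of
them is excluded from the germline, every hybrid is effectively an F1:
heterozygous for the two parental haplotypes at every locus where the
parental species differ. Triploid hybrids also occur, carrying one parental
genome in two copies (LLR or LRR).

This structure gives target-capture SNP data three strong, testable
signatures that the package is built around:

1. **Triangle coordinates.** On SNPs fixed between the parental species, a
   pure parental is homozygous everywhere (hybrid index 0 or 1, interclass
   heterozygosity 0) and a diploid hybrid is heterozygous everywhere
   (hybrid index 0.5, interclass heterozygosity 1).
2. **Allele-depth ratios.** At a heterozygous diagnostic site, the fraction
   of reads carrying the L allele estimates the L-genome dosage fraction:
   1/2 in diploids, 2/3 in LLR triploids, 1/3 in LRR triploids.
3. **A calling artifact.** A diploid genotype caller applied to a triploid
   occasionally sees too few reads from the single-copy genome and calls
   the site homozygous for the double-dose parent. This inflates the
   apparent ancestry of that parent, most strongly at low coverage — an
   artifact, not gene flow, and the package's simulator reproduces it by
   construction.

Every analysis stage is validated against a synthetic cohort whose ground
truth is known exactly, so each of these signatures is a checked property
rather than an assumption.

## Variant filtering

`filter_chain()` applies, in one pass: biallelic SNPs only (indels and
multi-allelic records rejected), no missing genotype in any sample,
per-sample depth >= 10 and genotype quality >= 20 in every sample, and
minor allele frequency >= 0.1 computed over all called alleles. These
thresholds are the defaults used throughout and are exposed as arguments.
The chain is idempotent and logs a per-record reason string, so a filtered
VCF can always be audited. `thin_one_per_marker()` then keeps the first SNP
(smallest position) on each target marker. Distance-based thinning is
pointless here because each reference sequence is a single short marker;
taking the first SNP makes the choice deterministic and reproducible.

The per-sample DP field, not the sum of AD, is what the depth rule tests:
callers may downsample reads for genotyping, and the DP convention matches
standard VCF filtering tools.

## The diagnostic panel

`ascertain_panel()` keeps loci at which *every* called allele in *every*
L-labelled sample is one state and every allele in every R-labelled sample
is the other ("100% diagnostic"). Hybrid and unknown samples are ignored.
The definition is deliberately strict: a single heterozygous or discordant
parental removes a locus, so panel size can only shrink as parental
samples are added. Each panel locus records which base is the L allele and
which the R allele; all downstream scores are defined in terms of this
orientation, and swapping the labels provably mirrors every statistic
(hybrid index to 1 − h, ratio r to 1 − r, LLR call to LRR).

## Triangle statistics

For a sample with called diploid genotypes at n panel loci,

- hybrid index `h` = (number of R alleles) / (2n), so 0 is pure lessonae
  and 1 pure ridibundus;
- interclass heterozygosity `het` = fraction of loci with one L and one R
  allele.

Under Hardy–Weinberg equilibrium no individual can fall below
`het = 2 h (1 − h)` (`hwe_boundary()`), the dotted curve on the triangle
plot. Triploids are scored from their diploid-called genotypes on purpose:
the package models the pipeline as it is actually run on such data, and the
resulting displacement of LLR triploids toward lessonae is one of the
properties the simulator must reproduce (see below), not an error to
correct.

## Genome dosage from allele-depth ratios

`ratio_profile()` computes, at every panel locus with summed parental-allele
depth >= `min_total_depth` (default 1), the ratio of L-allele depth to
summed L+R depth, straight from the AD field and ignoring the genotype
call — the signal is in the reads, and the call may be wrong in exactly the
cases of interest. `classify_dosage()` assigns the nearest of the centres
{1/2, 2/3, 1/3} if the mean ratio is within `margin` (default 0.07) of it,
else `ambiguous`. The margin is half the smallest gap between centres
(1/6 ≈ 0.167) minus headroom; at 300 sites and depth 40 the standard error
of the mean ratio is below 0.005, so the rule is conservative. The
nearest-centre rule mirrors how these per-sample ratio histograms are read
by eye, while remaining deterministic; the mixture model below provides the
formal test.

## Ploidy by Gaussian-mixture model selection

`select_sites()` takes, for one sample, the alt-allele balance at **all**
biallelic SNPs (not only panel loci) with summed allele depth >= 20,
genotype quality >= 20, and balance strictly inside (0.1, 0.9). The depth
cutoff of 20 matches common practice for allele-balance ploidy inference;
the open-interval balance bounds exclude homozygous sites whose balance
piles up at 0 and 1. The quality cutoff is exposed as a knob (`gq_min`)
rather than hard-coded. Parental samples pass far fewer sites than hybrids
(they are heterozygous only at shared polymorphisms), which the pipeline
reports rather than hides; a fit is still returned whenever `min_sites`
(default 100) is met.

`denoise()` fits, by EM, a uniform(0,1) noise component alongside a free
3-component Gaussian mixture and hands the per-site posterior weight of the
non-noise components to the model fits, together with the estimated noise
fraction.

`fit_ploidy_models()` then fits four models by weighted EM, all with a
single common variance:

| model | means | mixture proportions |
|---|---|---|
| free | 3 free | free |
| diploid | 1/2 | fixed (1) |
| triploid | 1/3, 2/3 | fixed (1/2, 1/2) |
| tetraploid | 1/4, 1/2, 3/4 | fixed (1/3, 1/3, 1/3) |

and selects the ploidy whose fixed model loses the least log-likelihood
against the free model (`delta = loglik_free − loglik_fixed`), ties broken
toward lower ploidy. Two parameterization choices matter:

- **Common variance** across components stabilizes EM at small site counts
  and keeps the fixed models nested in the free model's mean structure.
- **Fixed equal mixture proportions** in the fixed models. If the
  proportions were free, the tetraploid model (means 1/4, 1/2, 3/4) could
  put all its weight on the middle component and reproduce the diploid
  model exactly — the fixed models would be nested in one another, the
  tetraploid delta would never exceed the diploid delta, and the selection
  rule would degenerate. Pinning the proportions makes each hypothesis
  commit to its expected peak structure, which is what the delta
  comparison needs to discriminate.

Numerical safeguards: the common variance is floored at 1e-4 (with a
warning) so that degenerate inputs — e.g. all balances identical — cannot
collapse the likelihood; EM stops when the log-likelihood changes by less
than a *relative* 1e-8 (1e-6 for the denoiser, whose boundary optimum at
noise fraction 0 converges sublinearly in absolute terms); and the free fit
is warm-started from each fitted fixed model embedded as a 3-component
mixture with duplicated means (an embedding that leaves the density
unchanged), plus a canonical start at {1/4, 1/2, 3/4} and five
deterministic quantile-based starts. Because EM is monotone and one start
reproduces each fixed optimum, `loglik_free >= loglik_fixed[p]` holds by
construction — no seed is involved anywhere in the fit, so ploidy calls
are deterministic.

The reported R² compares the best fixed model's predicted bin masses with
the weighted empirical histogram over 100 bins on (0, 1) (the bin count is
a stated choice, not an inherited constant) and is clamped to [0, 1].

## Ancestry

Supervised estimation is the primary mode because the parental pools are
known and sampled. Under the two-pool admixture model, a sample's expected
alt-allele frequency at locus j is `f_j = q p_Lj + (1 − q) p_Rj`; the
genotype log-likelihood `Σ g_j log f_j + (2 − g_j) log(1 − f_j)` is
maximized over q in [0, 1]. On the diagnostic panel the parental
frequencies are exactly 0 and 1, the likelihood reduces to a binomial in
the sample's L-allele count, and the maximizer is the closed form
`q = (L alleles) / (2 n)` — used directly, so a noiseless F1 gives exactly
0.5. Off the panel, parental frequencies get a half-count pseudocount
`(count + 0.5) / (2n + 1)` to keep the likelihood finite at loci fixed in
one parental sample set.

`estimate_q_unsupervised()` implements the standard K = 2 admixture EM
(joint update of pool frequencies and per-sample q), restarted from seeded
random initializations with the best-likelihood replicate returned, and
pools aligned to L/R using the labels when available. It exists as a
cross-check of the supervised mode — the two agree to within ~0.01 on
simulated cohorts containing both parentals — and K is fixed at 2 because
only two nuclear lineages are present in the system.

`run_pca()` uses the standard variance-standardized dosage convention:
center each locus at `2p` and divide by `sqrt(p (1 − p))`, then SVD.
Monomorphic or constant loci are dropped; an all-constant matrix is an
error rather than a zero-variance result.

## Coverage windows

`best_window_min()` returns the maximum over all contiguous 100 bp windows
of the within-window minimum depth — a marker-quality summary that is
independent of marker length, which matters because capture markers range
from 100 bp to many kilobases. The implementation is the O(n) monotone
deque sliding-window minimum and is tested for exact equality against a
brute-force double loop. Markers shorter than the window use the
whole-marker minimum: capture markers start at 100 bp, so this is an edge
convention made explicit rather than a dropped case. `summarize_coverage()`
aggregates per-marker medians across samples, ranks markers by summed
coverage, and counts markers above/below configurable thresholds (defaults
100 and 10). Depth input is samtools-depth-style text, decoupling the
metric from alignment files.

## The synthetic cohort generator

`simulate_cohort()` realizes the generative model the dosage expectations
assume. Per sample and site: the true genotype follows the sample's genome
composition (L and R pools fixed at diagnostic loci, a shared Beta(2, 2)
allele frequency at the rest); total depth is Poisson (negative binomial
optional); the L-supporting read count is
`Binomial(depth, f (1 − ε) + (1 − f) ε)` with `f` the allelic dosage
fraction and ε the symmetric per-read error; and the emitted genotype is
the maximum-likelihood *diploid* call over hom-ref/het/hom-alt with a
phred-scaled GQ capped at 99. Triploids are therefore genotyped exactly the
way a default joint-calling pipeline genotypes them, which is what makes
the ancestry artifact emerge naturally: at depth 10 an LLR triploid's
heterozygous site produces 0 or 1 R reads often enough (~10% of sites)
that the caller prefers hom-L, and the supervised q of 20 simulated LLR
triploids averages ~0.55 at depth 10 versus ~0.50 at depth 40.

Defaults are the study conditions the generator emulates: a cohort of 11
L, 12 R, 13 diploid hybrids, 8 LLR and 1 LRR triploid; 500 markers with
one SNP each; 35% of SNPs diagnostic; mean depth 40; ε = 0.005. The Beta
(2, 2) shared-polymorphism prior gives non-diagnostic loci realistic
intermediate frequencies so that the MAF filter and the heterozygous-site
selection both have work to do.

What the generator deliberately does **not** model: reference or capture
bias toward either parental genome (so any real-data asymmetry in allele
ratios beyond dosage is outside the model), linkage and coalescent
structure within pools, mapping error, and read-level artifacts. Passing
tests therefore demonstrate that the analytic machinery recovers truth
under the stated read-sampling model — not that real libraries are free of
capture bias.

`simulate_depth_tracks()` generates the coverage fixture: per-marker
capture efficiencies (log-normal, with a 30% near-zero "failed marker"
fraction mirroring how many capture targets perform poorly in a bait set
designed without the focal genus) and moving-average-smoothed Poisson
depth series.

## Problem sizes used for validation

The shipped tests and drivers run at deliberately desk-scale sizes chosen
once: cohorts of 250–500 markers, dosage and triangle checks on one
simulated individual per class at 300+ diagnostic sites, ploidy recovery
over 40 seeded replicates per ploidy at 300+ heterozygous-like sites and
depth 40, and the ancestry artifact over 20 triploids per depth in
{10, 20, 40}. These sizes put the binomial standard errors an order of
magnitude below every tolerance tested.

## Known limitations

- Tetraploids are modelled in the ploidy test but not generated by the
  simulator (none occur in the system emulated); dosage classification has
  no tetraploid sub-classes.
- The unsupervised admixture mode returns the best of several EM
  replicates without replicate-merging heuristics; with K = 2 and both
  parentals present, label switching is resolved trivially.
- The filter chain treats a missing DP or GQ as a failure of that rule,
  which is the conservative reading of "in any individual".
- Allele-balance ploidy inference consumes VCF AD fields; it does not
  operate on alignment pileups.
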