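---
title: "Segregation GWAS: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segregation GWAS: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seggwas)
```

## The problem

Categorical traits controlled by a single biallelic locus are awkward for
a genome-wide association study when the genotype-phenotype map is
non-additive, sex-dependent, or incompletely penetrant. Horn status in
sheep is the motivating example: three mutually exclusive classes
(polled, scurs/knobs, horned), a single major locus, near-complete
penetrance in males but weak penetrance for the horned class in females.
Regressing such phenotypes on SNP allele counts either imposes a false
linearity across classes or throws information away by binarising.

`seggwas` implements a two-step alternative. Step one is a segregation
analysis: using only the pedigree and the phenotypes — never the marker
data — it computes, for every animal, posterior probabilities of the
three unordered genotypes at a putative locus, together with maximum
likelihood estimates of the penetrance matrix and of the founder allele
frequency. The posterior mean allele count,

$$\mathrm{EAC}_i \;=\; 0\,p_i(aa) + 1\,p_i(aA) + 1\,p_i(Aa) + 2\,p_i(AA)
\in [0,2],$$

is additive by construction, whatever the penetrance pattern. Step two
regresses the EAC on each SNP's allele count in an ordinary additive
GWAS. A gene-drop simulator quantifies the best correlation between EAC
and the causal mutation that any marker could achieve under a given
penetrance matrix.

## The segregation model

The locus has alleles $a$ and $A$; $A$ is the allele the EAC counts, and
its identity is fixed by the orientation of the penetrance matrix (the
convention used throughout associates genotype class 2, $AA$, with the
horned class). The model has two parameter blocks:

* $q$, the frequency of $A$ among pedigree founders, who carry an
  ordered Hardy-Weinberg prior $((1-q)^2,\,q(1-q),\,q(1-q),\,q^2)$ over
  $(aa, aA, Aa, AA)$ (paternal allele written first);
* a penetrance matrix $P(\text{phenotype } k \mid \text{genotype class }
  g)$ with $K$ phenotype rows and three genotype columns, each column
  summing to one.

Internally all computations use the four ordered genotypes, which makes
Mendelian transmission exact ($P(A \text{ transmitted}) = p(AA) +
\tfrac12 p(aA) + \tfrac12 p(Aa)$); results collapse the two heterozygote
states. Missing phenotypes contribute a likelihood factor of one, so
unphenotyped relatives still conduct pedigree information.

## Posterior genotype probabilities by iterative peeling

`peel_genotype_probabilities()` passes messages between nuclear families
(sire, dam, full-sib offspring). Each family is treated exactly: the
joint over the parents' 16 ordered genotype combinations is formed, each
offspring contributes a likelihood surface over that joint, and three
kinds of messages leave the family — an *anterior* distribution to each
offspring and a *posterior* message to each parent. Every sweep
processes all families in topological order and then in reverse; sweeps
repeat until no individual's posterior changes by more than `tol`
(default `1e-8`, capped at `max_sweeps = 200`, no damping).

On pedigrees whose family graph is loop-free this fixed point is the
exact posterior; the test suite verifies machine-precision agreement
with a brute-force enumeration oracle (`brute_force_probabilities()`,
which sums the full $4^n$ joint and is refused above $n = 12$). On
looped pedigrees — inbreeding, mates sharing ancestors, cross-matings —
the iterated messages are the standard fixed-point approximation used by
large-pedigree segregation software. The approximation error is *not*
negligible in adversarial cases: on tight loops (e.g. half-sib matings)
with extreme penetrance values, individual posterior probabilities can
deviate by 0.1 or more from the exact values, and the acceptance suite
reports this bound honestly rather than asserting exactness. Exact loop
handling (cutset conditioning, joint couple separators) is out of scope
because it cannot scale to the pedigrees the engine exists for. For the
moderate penetrance patterns this package targets, the fixed point is
well behaved and, at the population level, EAC-based results track the
simulator's ground truth closely.

The per-individual likelihood of a phenotype can optionally be evaluated
with a miscoding tolerance, $(1-\varepsilon)\,\mathrm{pen}(y\mid g) +
\varepsilon/K$. With $\varepsilon = 0$ (the default) a phenotype
configuration that is impossible under the penetrance zeros raises a
*model-data contradiction* error naming an individual involved.

## EM estimation of penetrance and allele frequency

`fit_segregation_model()` alternates the peeling E-step with two
closed-form M-steps:

* penetrance: $\widehat{\mathrm{pen}}[k][g] = \sum_{i: y_i = k}
  p_i(g) \,/\, \sum_{i \text{ phenotyped}} p_i(g)$, computed over
  phenotyped individuals; a genotype column with total posterior mass
  below `1e-8` keeps its previous values;
* allele frequency: $\hat q = \sum_{f \in \text{founders}}
  \mathrm{EAC}_f / (2\,n_\text{founders})$ — the exact M-step for the
  Hardy-Weinberg founder prior — clamped to $[10^{-6}, 1-10^{-6}]$.
  $q$ is re-estimated every iteration.

Iteration stops when the largest absolute change in any penetrance entry
and in $q$ falls below `em_tol = 1e-5` (cap `max_em_iter = 500`).
Penetrance entries are never floored. Exact zeros in the *starting*
matrix are structural statements about the inheritance model ("only AA
animals can be horned") and behave as such: with a strict fit they can
never regain posterior mass, so complete-penetrance data recover fitted
matrices with exact zeros.

Two consequences of this design deserve emphasis:

1. **Contradictions and the automatic retry.** A starting matrix with
   structural zeros can be contradicted outright by data generated under
   weaker penetrance (two "horned implies AA" parents with a polled
   offspring). When that happens the fit restarts once with the
   miscoding tolerance `retry_error = 1e-3`, while the starting zeros
   are *locked* in the M-step (columns renormalised over unlocked
   cells). The fitted matrix therefore keeps the start's structural
   zeros; entries that the lock wrongly fixes at zero (a truth of, say,
   0.01 for horned heterozygotes) are absorbed into neighbouring cells
   at the cost of a bias of that same order.
2. **Unlocked zeros are not innocent.** If the starting zeros are
   instead softened into small positive values, EM is free to climb to a
   genuinely different maximum of the likelihood, in which a fraction of
   one phenotype class leaks into a neighbouring genotype column. This
   is a property of the likelihood (spreading an abundant class over a
   probable genotype can gain more than it costs), not a numerical
   artifact; it is why the package treats starting zeros as constraints
   rather than as values to be perturbed.

EM monotonicity of the observed-data likelihood is verified in the test
suite against the enumeration oracle on loop-free pedigrees, where the
E-step is exact. Different all-positive starting matrices converge to
the same fit; starts with *different zero patterns* impose different
constraints and may legitimately converge to different matrices.

## EAC and the genotype probability index

`compute_eac()` is the linear functional above. `compute_gpi()` scores
how informative each genotype distribution is on a 0-100 scale. The
index is defined through a Shannon-entropy ratio against the
Hardy-Weinberg prior at the model's $q$:

$$\mathrm{GPI}_i = 100 \cdot \max\!\left(0,\; 1 -
\frac{H(p_i)}{H(\mathrm{HW}(q))}\right),$$

which is 100 exactly for a point mass, 0 exactly at the Hardy-Weinberg
prior, clamps to 0 for distributions more entropic than the prior, and
tracks the EAC-truth correlation approximately linearly in the
simulations. The literature-standard index this emulates is defined only
by those properties in the sources available to us, so the formula is
isolated behind this single function and documented as substitutable.

## The GWAS step

`qc_filter()` applies the usual per-SNP rules: minor allele frequency
$\ge$ 0.01, Hardy-Weinberg goodness-of-fit $\chi^2 \le 600$ (1 df,
expectations from the sample allele frequency), call rate $\ge$ 0.90,
autosomes only (chromosome codes that are positive integers).

`eac_gwas()` fits per-SNP ordinary least squares of EAC on allele count
with an intercept, pairwise deletion of missing genotypes, and reports
$-\log_{10} p$ computed from the $t$ statistic's log survival function,
so values far beyond the double-precision floor of $p \approx 10^{-321}$
remain exact (a SNP identical to the EAC reports a finite value in the
thousands, never infinity). $R^2$ equals the squared EAC-SNP Pearson
correlation. `binary_gwas()` is the comparison method: per-SNP logistic
regression of a horned/non-horned or polled/non-polled coding, tested by
likelihood ratio against the intercept-only model — the LRT is used
because Wald statistics degenerate under the (near-)complete separation
a monogenic trait produces; separation is detected and flagged.

`top_snp()` takes the maximum $-\log_{10} p$ (ties: larger $|\beta|$,
then genome order). `adjust_eac_for_top_snp()` residualises the EAC on
the lead SNP (restoring the original mean) so a second scan can look for
secondary peaks. `run_subsets()` reproduces the four analysis subsets:
females only, males only, pooled, and pooled-GWAS-on-separate-EACs; the
sex-specific subsets mask the other sex's phenotypes but keep the whole
pedigree for relationship information.

A caveat from our own measurements: with a few hundred fully phenotyped
animals, the pooled fit (iii) can match or beat the concatenated
separate fits (iv) even under strongly sex-specific penetrance, because
masking one sex discards half the phenotype information flowing through
the pedigree. The advantage of (iv) emerges when sex-specific maps
genuinely conflict or at the scale and phenotyping sparsity of real
livestock pedigrees; the test suite exercises the conflicting-map case,
where the dilution effect is guaranteed.

## The gene-drop simulator

`synthesize_pedigree()` builds a multi-generation half-sib pedigree
(each sire mated to a fixed number of dams, a fixed litter per dam;
next-generation parents sampled from the previous generation), standing
in for a real livestock pedigree. `simulate_founder_snps()` generates
unlinked candidate SNPs: half are *singletons* (one heterozygous copy in
one founder, by construction); the rest start at a uniform(0.05, 0.95)
frequency and drift through 100 Wright-Fisher generations of an
$N = 100$ founder population (binomial resampling of $2N$ gametes per
generation — equivalent in distribution to random-mating reproduction
for unlinked loci), with fixed loci redrawn. Pedigree founders then
receive Hardy-Weinberg genotypes at the post-burn-in frequencies.
`gene_drop()` phases founders once at random and transmits one uniformly
chosen allele per parent per locus. `assign_phenotypes()` draws each
individual's class from the penetrance column of its causal genotype.

`run_scenario()` chains these per replicate and records the Pearson
correlation between EAC and the causal allele count — the ceiling for
what any marker in full LD with the mutation could achieve — plus the
mean GPI, reporting means and standard errors across replicates
(default 10).

The causal locus is, by default, a uniform draw among all segregating
loci. Because half the panel is singletons, that rule yields a mean
causal MAF near 0.17, whereas the protocol this emulates reports a mean
causal MAF of 0.49; the package therefore exposes a second rule,
`maf_at_least`, and the acceptance analyses use `maf_at_least 0.4`,
which reproduces the reported mean MAF almost exactly. Singleton causal
loci also behave qualitatively differently (a near-founder carrier's
genotype is barely identifiable even under complete penetrance), which
is visible as mean GPI dropping a few points in scenario-1 runs under
the `any_segregating` rule.

## Problem sizes and numerical choices

The shipped analyses use sizes chosen to make every effect they test
unambiguous on a single CPU:

* scenario-1 exactness and the reproduction script: a 525-animal
  pedigree (3 generations, 5 sires x 8 dams x 4 offspring), 10
  replicates — mean GPI converges to 100 within about $10^{-3}$;
* the penetrance-weakening comparison: a 1,992-animal pedigree, 10
  replicates per scenario;
* penetrance recovery: a 4,910-animal pedigree under the near-complete
  male matrix (truth entries 1/0.23/0.76/0.01/1), recovered within 0.01;
* oracle equivalence: 200 random pedigrees of 4-11 individuals against
  the $4^n$ enumeration;
* null calibration: 10,000 independent SNPs at $n = 500$.

Other defaults: peeling tolerance `1e-8`; EM tolerance `1e-5`; founder
frequency clamp `1e-6`; miscoding tolerance on retry `1e-3`; QC
thresholds as above; EAC/GPI tables written at six decimals.

## Known limitations

* Looped pedigrees are handled by fixed-point message iteration, an
  approximation whose error grows with loop tightness and penetrance
  extremity (see above); the enumeration oracle bounds it only on small
  pedigrees.
* Single locus, two alleles, autosomal inheritance; sex-specific
  penetrance is handled by masking and refitting, not by a joint
  likelihood.
* Structural zeros of the starting matrix cannot be revised by the data
  (by design); a start that wrongly forbids a genotype-phenotype pair
  biases neighbouring entries by the forbidden mass.
* The simulator draws founder genotypes at Hardy-Weinberg from the
  drifted frequencies and simulates no linkage, mutation after burn-in,
  or selection; it emulates the information structure of a livestock
  pedigree, not any particular population's demography, so passing
  tests bound what the *method* can do, not what any real data set will
  yield.
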