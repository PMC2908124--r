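---
title: "Multi-rate codon substitution models and the random-model benchmark"
author: "codonbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-rate codon substitution models and the random-model benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbench)
```

## The model family

`codonbench` implements a family of continuous-time Markov models of
codon substitution on the 61 sense codons of the universal genetic
code. Instantaneous changes alter exactly one nucleotide; all other
codon pairs have rate zero. For a one-step change from codon $i$ to
codon $j$ replacing nucleotide $x$ by $y$ at codon position $k$, the
instantaneous rate is a product of three multipliers:

$$
q_{ij} \;=\; \rho_{c(\mathrm{aa}_i,\,\mathrm{aa}_j)}\;
             \theta_{xy}\;
             \pi_{k,y},
$$

where

* $\rho$ is the **exchangeability** of the unordered pair of encoded
  amino acids (non-synonymous changes only; synonymous changes use a
  fixed baseline of 1, so every $\rho$ is a non-synonymous/synonymous
  rate ratio),
* $\theta_{xy}$ is a symmetric **nucleotide mutational bias** for the
  unordered nucleotide pair $\{x, y\}$, and
* $\pi_{k,y}$ is the **position-specific frequency** of the target
  nucleotide at codon position $k$.

Exactly 75 of the 190 unordered amino-acid pairs can be exchanged by a
single nucleotide substitution (`exchangeablePairs()` enumerates them;
this count is also the package's one analytic headline number). A
model in the family is indexed by a partition of those 75 pairs into
$K$ rate classes (`RateClassAssignment`):

* **SR** ($K = 1$): one shared non-synonymous rate — the classical
  $\omega = dN/dS$;
* **random-$K$**: each pair assigned independently and uniformly at
  random to one of $K$ classes, so classes are balanced on average but
  may be empty by chance;
* **REV** ($K = 75$): every pair has its own rate — the codon general
  time-reversible model.

The assignment acts on residue *pairs*, not residues, because the
genetic code is not transitive: pairs $\{A,B\}$ and $\{B,C\}$ can each
be one nucleotide apart while $A$ and $C$ are not. Class-of-residue
schemes force equal rates onto one-step and multi-step exchanges;
pair-level assignment does not.

Because $\theta$ is symmetric and the stationary law is the product of
positional frequencies restricted to sense codons (renormalized), the
chain satisfies detailed balance
$\pi_i q_{ij} = \pi_j q_{ji}$ exactly — the model is time reversible,
so likelihoods do not depend on root placement. Both properties are
verified numerically in the test suite rather than assumed.

## Parameters, identifiability, and defaults

| parameter | dimension | free | constraint / default |
|---|---|---|---|
| $\rho$ (class rates) | $K$ | effective classes | $\ge 0$; bounded in $[10^{-6}, 100]$ during fitting |
| $\theta$ (biases) | 6 pairs | 5 (`rev`) or 1 (`hky`) | $\theta_{A:G} \equiv 1$ for identifiability |
| $\pi$ (frequencies) | $3\times4$ | 9 (`ml`) or 0 (`observed`) | rows sum to 1; positive |
| branch lengths | $2n-3$ | all | $\ge 0$; expected substitutions per codon site |

The generator is normalized so that one unit of branch length is one
expected substitution per codon site at stationarity, keeping branch
lengths comparable across models. $\theta_{A:G} = 1$ fixes the overall
mutational scale (the usual convention in nucleotide GTR models);
`hky` collapses the biases to transitions-versus-transversions.
Empty classes in a random assignment contribute no estimable rate, so
the *effective* (non-empty) class count is used everywhere degrees of
freedom matter (LRT df, BIC penalty, `countFreeParameters()`).

## Likelihood and optimization

Likelihoods are computed by Felsenstein pruning over compressed site
patterns, with the root weighted by the stationary distribution. Gaps
and ambiguous codons are treated as missing data (partial-likelihood
vectors of ones). Transition matrices come from one spectral
decomposition of the symmetrized reversible generator per rate matrix,
so each branch length costs only an exponentiation of 61 eigenvalues;
partial likelihoods are rescaled per node on trees with more than ~30
taxa to prevent underflow.

`fitCodonModel()` maximizes the likelihood by **block coordinate
ascent**:

1. *branch lengths*: exact one-dimensional coordinate descent, one
   branch at a time. The likelihood restricted to one branch reduces,
   via the spectral form, to
   $\sum_{\mathrm{pat}} w \log \sum_k e^{\lambda_k t}\, a_k b_k$ with
   $a, b$ precomputed from the partial likelihoods flanking the edge,
   so Brent iterations are essentially free;
2. *biases + frequencies*: bounded quasi-Newton (L-BFGS-B) on
   $\log\theta$ and multinomial logits of $\pi$;
3. *class rates*: L-BFGS-B on $\log\rho$.

Blocks repeat until the relative log-likelihood gain drops below
`relTol` ($10^{-8}$ by default). Each block only accepts improvements,
so the log-likelihood is non-decreasing and a fit can never end below
its initialization. A block that gains less than `freezeTol`
($10^{-3}$ log-units) in a sweep is skipped afterwards — in practice
the frequency block converges within the first couple of sweeps and
this saves most of its cost. Initialization is deterministic: branch
lengths from JC-corrected codon p-distances projected onto the
topology by least squares, frequencies at observed proportions, all
rates at 1. Optional seeded random restarts jitter $\rho$ and
$\theta$.

Rates are bounded in $[10^{-6}, 100]$; estimates on a bound (as
happens, e.g., for an alignment with no variation, where branch
lengths collapse to zero) are flagged as boundary solutions rather
than silently returned. A fit that exhausts `maxOuter` sweeps is
flagged `converged = FALSE`.

Branch lengths are re-optimized for every model by default. Freezing
them at the null-model estimates is available by dropping `"branch"`
from `updateBlocks`; per-model re-optimization is the default because
it is the setting under which the likelihood-ratio test is cleanly
valid.

## The random-model benchmark

`runRandomEnsemble()` implements the comparison protocol: fit SR once,
then fit `nReplicates` (default 100) random-$K$ models, compare each
to SR with a likelihood-ratio test ($2\Delta\mathrm{LL}$ against
$\chi^2$ with df = effective classes $-$ 1), and report the counts of
replicates significant at $\alpha$ and at the Bonferroni-corrected
level $\alpha/\mathrm{nReplicates}$, plus the mean BIC over
replicates. BIC uses $-2\mathrm{LL} + p\ln(n)$ with $n$ the number of
codon sites — the dominant convention in phylogenetics; $p$ is the
full free-parameter count. Non-converged replicates are excluded from
the counts and tallied, never silently dropped.

Replicate fits warm-start from the SR optimum (the SR rate is copied
to every class), which both guarantees the nesting inequality
$\mathrm{LL}_K \ge \mathrm{LL}_{SR}$ by construction and makes the
100-replicate protocol tractable. By default replicates re-optimize
branch lengths and class rates while keeping $\theta$ and $\pi$ at the
SR maximum-likelihood values: these nuisance blocks move negligibly
between models of this family on the same data, and skipping them can
only *understate* the random models' improvement (a conservative
shortcut — degrees-of-freedom accounting is unchanged because both
models are still counted as full-ML fits). `updateBlocks = "all"`
restores full re-optimization.

## The simulator

`simulateAlignment()` draws root states from the stationary
distribution and evolves them along each branch with the exact
transition probabilities $P(t) = e^{Qt}$ — no discretization — using
one RNG stream seeded once, so alignments are bit-reproducible given
the seed. An optional Gillespie mode generates full substitution
histories event by event for observability (the test suite checks
logged synonymous/non-synonymous event counts against the expected
stationary flows $\pi_i q_{ij} t$). `randomTree()` draws uniform
unrooted topologies with exponential branch lengths.

What the simulator deliberately does not emulate: insertions and
deletions, rate variation across sites, non-stationary or non-reversible
composition, recombination, and alignment error. Tests passing on
simulated data therefore validate the estimators under the model's own
assumptions; they do not certify behavior on real alignments that
violate them.

## Study conditions used by the test suite

The acceptance-level tests run at deliberately moderate problem sizes,
chosen once as realistic desk-scale analogs of the protocol:

* *Parameter recovery*: 2-class model with $\rho = (0.2, 2.0)$, 12
  taxa, 1,000 codons, 20 replicates; both rates recovered within
  ±25% in the median.
* *Type-I error*: data simulated under SR ($\omega = 0.5$, 12 taxa,
  500 codons), 50 random $K{=}2$ re-fits at $\alpha = 0.05$; the raw
  rejection fraction must stay inside the binomial 99% band around
  0.05.
* *Power / thesis*: data simulated under a strong 5-class model
  ($\rho = 0.05, 0.3, 1, 3, 10$; 12 taxa; 1,000 codons), 50 random
  $K{=}5$ re-fits; at least 90% must significantly beat SR, and the
  mean random-model BIC must undercut SR's.
* *Null calibration*: 200 random $K{=}2$ re-fits on SR data (6 taxa,
  300 codons); the LR statistic's QQ slope against $\chi^2_1$ must lie
  in $[0.8, 1.2]$.

Exact-identity checks (pruning versus exhaustive summation over
internal states on all topologies with $\le 4$ taxa; detailed balance;
Chapman–Kolmogorov; the 75-pair count) run at tolerances of $10^{-8}$
or tighter.

## Numerical choices and limitations

* Spectral exponentiation is exact for this reversible family; entries
  are clipped at zero where eigen-roundoff produces values like
  $-10^{-18}$.
* Site patterns are compressed before pruning; duplicated columns cost
  nothing.
* The chi-square reference for the LRT is asymptotic; on very short
  alignments the test can be conservative (the QQ check above
  quantifies this at 300 codons).
* Codon-position-specific $\omega$, site-to-site rate variation,
  multi-nucleotide instantaneous changes, empirical exchangeability
  matrices and topology search are out of scope.

## A small worked example

```{r example, eval = FALSE}
tree <- randomTree(8, seed = 1, meanBranchLength = 0.2)
truth <- randomAssignment(2, seed = 2)
aln <- simulateAlignment(tree, truth, rho = c(0.2, 2), nSites = 500, seed = 3)

sr <- fitCodonModel(tree, aln, srAssignment())
two <- fitCodonModel(tree, aln, truth, start = sr)
lrTest(sr, two)
bic(sr, nSites(aln)); bic(two, nSites(aln))

ens <- runRandomEnsemble(aln, tree, K = 2, nReplicates = 20, baseSeed = 10)
ens
```
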