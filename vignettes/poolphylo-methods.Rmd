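---
title: "Assembly-free phylogenies from pooled reads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-free phylogenies from pooled reads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolphylo)
```

## The problem

A pooled amplicon library mixes reads from `n` closely related haplotypes
without barcodes, so no read can be attributed to its source. poolphylo
estimates, from a single read alignment against one reference, three
things at once: the rooted tree topology `T` relating the haplotypes,
their relative abundances `R = (r_1, ..., r_n)`, and the sequencing error
rate `e` — without assembling any haplotype sequence. The number of
haplotypes `n` is assumed known.

The key observation is that under an infinite-sites model (every
segregating site carries exactly one historical mutation) a mutation on
edge `u` of the tree makes the derived base appear in exactly the reads
from the clade below `u`. The *SNP ratio* of a biallelic site — the
proportion of reads carrying the minor base — therefore estimates a clade
abundance sum, and the histogram of SNP ratios (*SNP frequencies*) is a
mixture analogue of the site-frequency spectrum. A single site only
constrains a clade sum; *pairs* of nearby sites carried by the same
sequencing fragments constrain the topology, because two mutations on
edges of one tree can produce at most three joint patterns (clades are
nested or disjoint), with expected pattern proportions given by clade
algebra on `(T, R)`.

## The likelihood

Sites are rank-encoded: at each position the nucleotide with most read
support becomes rank 0, the next rank 1, and ranks 2–3 are attributed to
sequencing error. For a site pair `(i, j)`, the clean 2×2 pattern table
given mutation edges `(u, v)` and root states `(r_i, r_j)` assigns each
tip the joint state (`r_i` flipped iff the tip is below `u`, `r_j`
flipped iff below `v`) and sums abundances per state. Errors act
per base independently: a base is read correctly with probability
`1 - e` and as any given other rank with probability `e/3`, giving a 4×4
noisy table by two-sided convolution. Read counts over the 16 cells are
modelled as multinomial.

The alignment is tiled with non-overlapping 100-bp windows; inside each
window a reference site `c_k` is chosen (the lowest-coordinate usable SNP
site covered by at least `max(50, 0.2 × mean coverage)` reads, else the
best-covered SNP site), and every other usable site in the window is
paired with `c_k`. The window likelihood takes, for each candidate
reference edge `v`, the sum over the reference root state of the product
over member sites of (maximum over the member's mutation edge `u` of the
root-state-averaged pair likelihood), and then maximises over `v`. Root
state probabilities are the observed rank-0/rank-1 proportions at the
site. This max-over-edges form drops the per-edge mutation probabilities
from the parameter vector, which makes the sampler's state small and
mixing fast; the exact variant that instead sums over `(u, v)` with
supplied edge weights is available through
`alignment_log_likelihood(..., method = "full")` but is not the default.
Invariable sites — those where only one nucleotide exceeds the error
ceiling `e_max` (default 0.01) — are skipped.

All probability arithmetic is in log space. The compiled kernel
exploits three structural facts: noisy cells with an error rank at one
site factor into a term depending on only one of the two edges; cells
with error ranks at both sites equal `(e/3)^2` exactly; and root states
act on the clean cells as index permutations. Zero probabilities are
clamped to `exp(-1e30)`-scale values so that dense dot products with zero
counts stay well defined; a positive count on an impossible cell still
drives the combination out of every maximisation.

## Preprocessing and filters

* Reads below mapping quality 20 and bases below quality 25 are ignored
  (configurable).
* The two mates of a fragment count once per site; if they disagree at a
  shared site, that site is dropped for the fragment. A read-level mode
  (`fragment_mode = FALSE`) is available.
* Rank ties are broken in the fixed order A < C < G < T, so preprocessing
  is deterministic under read reordering.
* Sites violating the infinite-sites assumption are removed in two steps:
  any site with more than two nucleotides each on at least `e_max` of its
  reads; and any biallelic site for which at least `d = 3` partner sites
  (sharing at least 50 sequencing units) each produce four or more joint
  patterns at the 1% support level — impossible for single-mutation site
  pairs on one tree.
* Regions where soft-clipped read ends exceed 2% of local coverage are
  masked; clipping marks reference/read dissimilarity that distorts local
  haplotype ratios.

Coordinates are 0-based half-open internally; SAM input is converted on
ingest.

## Inference

The posterior `P(T, R, e | data)` combines the likelihood with a uniform
prior over rooted topologies, a flat Dirichlet prior on `R`, and a
uniform prior on `e` over `[0, e_max]`. Sampling is Metropolis-coupled
MCMC: one cold chain and heated chains at inverse temperatures
`1 / (1 + lambda k)`, adjacent chains attempting state swaps every 10
iterations with the standard coupling ratio. Within chains six kernels
are mixed: topology NNI and rooted subtree prune-regraft (both symmetric
by move counting), pairwise abundance mass exchange, a Dirichlet proposal
centred on the current abundances (the one kernel with a non-trivial
Hastings ratio), an abundance swap between two tips, and a reflected
sliding window on `e`.

Two design points deserve emphasis:

* **Abundance multimodality.** Because each site's mutation edge is
  chosen by maximisation, sites re-assign discontinuously as clade masses
  cross, and the marginal posterior of `R` is multimodal with deep
  valleys. The exchange kernel therefore mixes a fine step (width 0.01)
  with a coarse one (width 0.3); the coarse component hops between modes
  that tempering alone cannot connect at workable temperatures. The
  abundance-swap kernel similarly jumps between tip relabellings.
* **Initialisation.** Chains start from a random topology, `e = 0.005`,
  and abundances seeded from the centres of the most populated SNP-ratio
  classes with Dirichlet jitter; terminal-edge mutations put ratio mass
  near the tip abundances, so this start lands in the right region and
  shortens burn-in.

The cold chain is recorded every `thin` iterations (log posterior,
abundances, error rate, newick topology), and the estimate reported is
the maximum-posterior state visited by the cold chain — posterior
summaries such as consensus trees are awkward here because tip identities
are anonymous and abundance-labelled. Runs are exactly reproducible from
the seed; chains are advanced serially so results are independent of
scheduling. Convergence is not auto-diagnosed: the trace is returned for
inspection (`autoplot()`), mirroring fixed-iteration practice.

## Edge lengths

Topology and abundances deliberately come first; edge lengths are
estimated afterwards (joint sampling favours long branches when tips
carry no sequences). For the fitted `(T, R, e)`, each window reference
site gets a posterior over mutation edges from its own rank counts, and
every other site gets one from its pair table, integrating over the
reference's edge with the reference posterior as weight. The length of
edge `u` is the normalised total posterior mass assigned to `u` across
sites, with index 0 reserved for "no mutation"; all components sum
to one. Invariable sites are included by default — they carry the
no-mutation mass, and excluding them would inflate every mutation edge.
To compare against a tree in substitutions/site, `true_length_proportions()`
converts branch lengths to the same proportion scale with a no-mutation
share of one minus the tree length (accurate for the short trees the
infinite-sites model assumes), and `rms_edge_lengths()` compares on
unrooted edges, pooling the two root-child edges of each tree onto their
shared split, because root placement is only weakly identified.

## The simulator and what it does (not) cover

`simulate_mixture()` reproduces the study conditions end to end: a
random labelled rooted topology (sequential random joins) with
exponential branch proportions rescaled to root-to-tip depth 0.03;
haplotypes evolved site-independently under Jukes–Cantor from a random
root sequence (the root doubles as the alignment reference); abundances
uniform on the simplex above a floor of 1/60 (the least-abundant
haplotype keeps 1/60 of the coverage) with pairwise spacing at least
0.0033, drawn exactly by a spacings construction (plain rejection has
acceptance ~1e-4 at n = 15); and paired-end 150-bp reads (fragment length
normal, mean 400, sd 40) with independent uniform per-base errors at
rate 0.002, at 15,000× total coverage by default. Because read origins
are known, a perfect alignment is emitted directly as SAM/BAM, removing
the external aligner from the loop; FASTQ output is available for use
with a real aligner.

The simulator does *not* model position-dependent error profiles, indels,
PCR chimeras, coverage waves along the genome, or alignment error. Tests
passing on these simulations therefore validate the estimator under its
own model assumptions plus uniform noise; on real libraries the masking
and violation filters absorb part — not all — of the gap.

`evaluate_estimate()` scores an estimate the way the study protocol
does: it enumerates all tip pairings under which the estimated and true
unrooted topologies are identical and reports the pairing minimising the
root-mean-square abundance difference; the estimate is *correct* when
such a pairing exists with every per-tip difference below 0.01.

## Problem sizes used by the test suite

The full-scale study conditions (50-kb genomes at 15,000×, chains of
650k+ iterations) are the simulator defaults. The package's replicated
recovery test runs a scaled-down version chosen to keep a complete
10-replicate study within minutes on one CPU: 5-kb genomes at 2,000×
coverage, error 0.002, 25,000 iterations on 4 coupled chains with
`lambda = 0.3`, seeds fixed. At this scale two effects appear that
vanish at full scale and are worth understanding:

* **Short internal edges.** A random depth-0.03 tree occasionally
  contains an internal edge of length ~5e-4, i.e. ~2 expected mutations
  in 5 kb (vs ~25 in 50 kb). The likelihood can then genuinely prefer a
  configuration with two abundances exchanged across that edge — this is
  a data limitation, not a sampler failure (the wrong mode's likelihood
  exceeds the truth's), and it accounts for the replicates that fail the
  0.01 criterion at this scale.
* **Finite read pools.** With tens of thousands of fragments, the
  realised haplotype fractions differ from the nominal abundances by
  binomial noise of SD ~0.003; the estimator tracks the realised pool.

Accuracy bounds for the scaled-down study are the full-scale ceilings
(root-mean-square abundance error 0.0012; edge-length error 0.005)
inflated by the information ratio: `sqrt(7.5 × 10) ≈ 8.7` for abundances
(coverage × sites) and `sqrt(10) ≈ 3.2` for lengths (sites).

## Numerical choices and degenerate inputs

* Multinomial coefficients are computed once per site via `lgamma` and
  factored out of all maximisations.
* Log-sum-exp is used for every root-state average; the compiled kernel
  takes the early exit `max(a, b)` when the arguments differ by more
  than 36 (below one double ulp of the result).
* Windows without SNP sites get no reference and contribute nothing;
  windows whose member sites share no fragments with the reference skip
  those sites with a count reported in the `pooldata` summary.
* A proposal leaving the prior support (a non-positive abundance, an
  error rate outside `[0, e_max]`) is rejected without a likelihood
  evaluation; the error-rate slider reflects at both boundaries, keeping
  the kernel symmetric.
* `run_mcmcmc()` re-draws its initial state up to 20 times if the
  starting posterior is not finite, then errors.

## Known limitations

* `n` must be supplied; model selection over the number of haplotypes is
  out of scope.
* Haplotypes more similar than the resolution of the data merge (their
  separating edges carry no sites), and the result is then evaluated as
  a tip-count mismatch.
* Multifurcating trees, indels, and associations of more than two sites
  are not modelled; divergent mixtures violating the infinite-sites
  assumption need a finite-sites extension.
* Identifiability of the root is weak; report and compare trees
  unrooted.
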