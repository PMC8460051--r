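# poolphylo

Assembly-free phylogenies and haplotype abundances from pooled short
reads.

## The problem

Pooled amplicon sequencing without barcodes mixes reads from `n` closely
related haplotypes — viral quasispecies, mitochondrial amplicons from
pooled individuals — so no read can be attributed to its source.
poolphylo reconstructs, from a single read alignment against one
reference sequence, the phylogeny `T` of the haplotypes, their relative
abundances `R = (r_1, …, r_n)`, and the sequencing error rate `e`,
without assembling any haplotype. The number of haplotypes is assumed
known.

Under an infinite-sites model, a mutation on edge `u` puts the derived
base into exactly the reads of the clade below `u`, so a biallelic
site's minor-base proportion (its *SNP ratio*) estimates a clade
abundance sum. Pairs of nearby sites covered by the same fragments
constrain the topology: two single-mutation sites produce at most three
joint nucleotide patterns, with expected proportions

> P̃(s(ij) = pq | u, v, rᵢ, rⱼ) = Σ over tips in joint state (p, q) of
> their abundances,

convolved with a uniform error kernel ψ(p′→p) = 1−e if p = p′, e/3
otherwise, and compared with the observed 4×4 rank-pattern counts under
a multinomial likelihood. Whole-alignment likelihoods pair every usable
SNP site with a high-coverage reference site inside non-overlapping
100-bp windows. The posterior P(T, R, e | data) ∝ L·P(T)·P(R)·P(e) is
sampled by Metropolis-coupled MCMC; edge lengths are estimated
afterwards from per-site mutation-edge posteriors, with `length(0)`
reserved for "no mutation" and all lengths summing to 1.

A self-contained simulator reproduces the study conditions
(Jukes–Cantor haplotypes from a random tree of root-to-tip depth 0.03,
paired-end 150-bp reads with uniform errors, a perfect aligner emitting
SAM/BAM), and an evaluator scores estimates by the minimum-RMS tip
pairing under unrooted topology identity.

## Worked example

```r
library(poolphylo)

sim <- simulate_mixture(n_hap = 4, genome_length = 2000, coverage = 400,
                        error_rate = 0.002, seed = 7)
paths <- write_mixture(sim, "demo")          # ref FASTA + SAM/BAM + truth
data  <- preprocess_alignment(paths$bam, ref = paths$ref)
data
#> <pooldata> 2000 bp, mean coverage 400
#>   sites: invariable=1877, snp=96, violating=27
#>   windows with reference site: 20; usable site pairs: 76; skipped (no shared units): 0

fit <- run_mcmcmc(data, n_tips = 4, iterations = 6000, n_chains = 4,
                  thin = 100, seed = 1, lambda = 0.3)
fit
#> <poolphylo_fit> 4 tips, 6000 iterations x 4 chains
#>   MAP log posterior -616.061 at iteration 766; e_hat = 0.001758
#>   MAP tree: (T4,(T3,(T1,T2)));
#>   MAP abundances: T1=0.2584 T2=0.2092 T3=0.0367 T4=0.4957

evaluate_estimate(fit$map$tree, fit$map$R, sim$tree, sim$abundances)
#> <pool_eval> correct: TRUE (topology and abundances match)
#>   RMS abundance difference: 0.005203; max |delta|: 0.008498; tip pairings considered: 8

estimate_lengths(data, fit$map$tree, fit$map$R, fit$map$e)$table
#> # A tibble: 7 × 3
#>    edge clade     length
#>   <int> <chr>      <dbl>
#> 1     0 (none)   0.927
#> 2     1 T1       0.00929
#> 3     2 T2       0.0250
#> 4     3 T3       0.0263
#> 5     4 T1,T2    0.00367
#> 6     5 T4       0.00450
#> 7     6 T1,T2,T3 0.00448
```

Reading the output: the sampler recovered the simulated unrooted
topology; the maximum-posterior abundances match the true mixture
proportions to within 0.009 per haplotype; the error-rate estimate
0.0018 sits near the simulated 0.002; and 92.7% of sites carry no
mutation, with the remaining mass spread over the six tree edges in
proportion to their lengths. Estimated tips are anonymous (`T1…Tn`) —
the evaluator's pairing attaches them to the true haplotypes.

`tidy(fit)`, `glance(fit)` and `autoplot(fit)` give broom-style
summaries and a cold-chain trace plot; `plot_snp_spectrum()` and
`plot_edge_lengths()` visualise the ratio spectrum and length profile.

A thin command-line wrapper (`inst/cli/poolphylo`) exposes the pipeline
as subcommands (`simulate`, `preprocess`, `infer`, `lengths`,
`evaluate`, `all`) with YAML configuration and provenance headers.

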