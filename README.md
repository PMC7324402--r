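# BoolGMN

Boolean gene-modular-network (GMN) analysis of morphogen-patterned tissue,
modelled on the anterior–posterior (A–P) axis of the *Drosophila* wing
imaginal disc. The package is for systems biologists who have (or simulate)
gene-by-position expression matrices along a morphogen gradient and want to
ask whether the patterning program those profiles encode is robust.

## The method

Position-resolved profiles are reduced to a synchronous Boolean network over
gene modules in four steps:

1. **Morphogen-responsive genes (MRGs)** are screened by a monotone trend:
   a gene passes when some run of four consecutive position intervals is
   direction-consistent with a per-interval fold change ≥ 2. Two independent
   sample series are screened separately and intersected.
2. Batches are **integrated**: per-gene batch-mean removal on the log scale
   (`limma::removeBatchEffect`), then the analyst's interleaving of the two
   position series into one A→P axis.
3. **Modules**: hierarchical clustering of the common MRGs into *m* modules
   (default 12); each gene is binarized against its across-position mean
   (strict `>`); module *i* is ON at position *j* (`s_i(j) = 1`) when a
   strict majority of its genes are ON. The terminal column is duplicated
   (B7\*) to encode pattern constancy inside the morphogen source.
4. **Dynamics**: reading position as pseudo-time,
   `s_i(j+1) = f_i(s_1(j), …, s_m(j))`, one AND/OR/NOT rule per module is
   inferred from the 13-state spatial sequence (minimal in-degree,
   deterministic tie-breaks). All `2^m = 4096` states are enumerated;
   fixed points `S(T+1) = S(T)` and cycles, their basins, transition trees,
   and the *major trajectory* from the anterior-most observed state are
   reported.

Robustness is then probed two ways: random two-bit flips of the observed
state table with re-inference (how often does the attractor set survive, and
do trajectory overlap-ratio distributions change?), and a morphogen
production scan that widens or shrinks the Hedgehog-responsive module's ON
run and tracks the share of states converging to the normal attractor.

A seeded synthetic generator (`make_ground_truth`) emulates the study
conditions — 12 contiguous-band modules over 13 staggered two-batch
positions, ~350 log-normally noisy genes per module, *hh*/*ci*/*dpp*-like
markers, non-monotone background genes — so that every stage is testable
without external data.

## Worked example

```r
library(BoolGMN)

gt  <- make_ground_truth(seed = 3, genes_per_module = 40, sigma = 0.3)
gt$state_table
#> Binary module state table: 12 modules x 14 positions (terminal duplicated)
#>   A1     100000000000
#>   B1     110000000000
#>   ...
#>   B7     000000000111
#>   B7*    000000000111

net <- infer_network(gt$state_table)
find_attractors(net)
#> Attractor report: 12 modules, 4096 states, 3 attractor(s)
#>   000011100111 [fixed point]  basin 2292 (55.96%)
#>   000000000111 [fixed point]  basin 1384 (33.79%)
#>   010011100111 [fixed point]  basin 420 (10.25%)

trajectory(net, gt$state_table$states[, "A1"])
#>  [1] "100000000000" "110000000000" "011000000000" ... "000000000111"
```

The major trajectory retraces the 13 observed positional states and ends in
the fixed point whose pattern equals the terminal (posterior) position —
the "normal" attractor. Perturbation and morphogen scans:

```r
perturbation_study(gt$state_table, reps = 200, n_flips = 2, seed = 7)
#> Perturbation study: 200 replicates, 2 bit flips each (seed 7)
#>   same attractor set: 2.50% of replicates
#>   mean basin sizes over matching replicates:
#>     000011100111: 2338.4
#>     000000000111: 1421.6
#>     010011100111: 336.0
#>   overlap-ratio comparison (Asymptotic two-sample Kolmogorov-Smirnov test):
#>   statistic 0.1367, p = 1.249e-12

morphogen_scan(gt$state_table, module_index = 8, shifts = -2:2)
#>   shift    m8_pattern pct_normal
#> 1    -2 0000000001100   96.67969
#> 2    -1 0000000011100   75.00000
#> 3     0 0000000111100   33.78906
#> 4     1 0000001111100   99.60938
#> 5     2 0000011111100  100.00000
```

Here `same attractor set: 2.50%` says this particular random fixture is far
more fragile than the published wing-disc table (which kept its attractors
in 99.92% of flips) — the statistic depends strongly on the observed table,
which is the scientific point of computing it. The scan's `pct_normal`
column is the percentage of all 4096 states converging to the attractor
whose pattern matches the unmodified terminal position.

`run_pipeline()` orchestrates the stages end-to-end from any entry point
(expression pair, state table, or rule file) and writes rules, state table,
transition edges, robustness TSVs and a summary JSON; see
`vignettes/BoolGMN-methods.Rmd` for the model, conventions and design
choices.

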