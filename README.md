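# stygosim

Statistical tests of speciation mode for subterranean radiations in isolated
calcrete aquifers.

Arid-zone calcretes along palaeodrainages each hold one to three endemic
species of blind, wingless (stygobitic) diving beetles. Because the aquifers
are closed "islands" colonized from a shared surface fauna, the frequency of
aquifers containing *sympatric sister species* — closest relatives sharing
one aquifer, as pairs or triplets — can discriminate between two assembly
modes:

- **repeated colonization**: sisters arise when the *same* surface ancestor
  colonizes one aquifer in separate arid periods, diverging allopatrically
  in between;
- **single colonization with within-aquifer diversification**: one founder
  per occupied niche, and empty niches are later filled by in-situ
  speciation of a resident.

`stygosim` implements both null models in closed form and by seeded Monte
Carlo, compares their 5/95-percentile randomization bands with an observed
census, detects sympatric sister clades on annotated time-calibrated
phylogenies (with surface/subterranean lineage-through-time curves), and
generates synthetic datasets with known colonization ground truth.

## The models

Each aquifer offers 1–3 niches (one species per niche, competitive
exclusion); the census `(a1, a2, a3)` counts aquifers by species number, with
`A = a1 + a2 + a3`.

**Repeated model.** In event *j* (of 2 or 3), every still-empty niche is
filled with probability *p_j* by a species drawn uniformly, without
replacement within the event, from a pool of *n* ancestral species; by
convention the last event has probability 1. Writing
*q_j = p_j ∏_{i<j}(1 − p_i)* for the chance a niche first fills at event *j*
and *e_k* for the elementary symmetric polynomials of the *q_j*:

    P_pair(2 niches)  = 2 e2 / n
    P_pair(3 niches)  = (6/n)(e2 − 3 e3) + 18 (n−1) e3 / n²
    P_triplet         = 6 e3 / n²            (zero with only two events)

**Single model.** One event with per-niche probability *p*; each empty niche
is then filled with probability *q* by a descendant of a resident:

    P_pair(2 niches)  = 2 p (1−p) q
    P_pair(3 niches)  = 3 p² (1−p) q + 6 p (1−p)² q (1−q)
    P_triplet         = 3 p (1−p)² q²         (independent of n)

Expected regional fractions weight these by `a2, a3` and divide by `A`
(one-niche aquifers contribute zero). Randomization bands are the empirical
5th/95th percentiles of the per-replicate sister-aquifer fraction over
seeded replicates of the whole census.

## Worked example

The published Yilgarn survey: 45 aquifers with one (18), two (16) or three
(11) species, and an observed 9 sister pairs plus 2 triplets (11/45 ≈ 0.244).

```r
library(stygosim)
cen <- yilgarn_census()
obs <- sister_tally(9, 2, 45)

# Repeated colonization at its most favourable setting (p1 = 0.5, p2 = 1):
expected_sister_fractions(cen, colonization_scenario("repeated", c(0.5, 1), pool_size = 10))
#> Sister-species prediction (repeated model)
#>   P(pair | 2 niches) = 0.050000
#>   P(pair | 3 niches) = 0.150000
#>   P(triplet | 3 niches) = 0.000000
#>   expected fraction of aquifers: pairs 0.0544, triplets 0.0000, combined 0.0544
```

Even at its maximum the repeated model predicts a combined fraction of
0.054 with a 10-species pool — far below the observed 0.244 — and no
triplets at all with two events. The randomization scan quantifies this:

```r
min_pool_size_outside_band(cen, obs, n_range = 3:30, replicates = 10000, seed = 1)
#> [1] 4
#> attr(,"scan")
#>   pool_size      lower     upper      mean  observed outside
#> 1         3 0.11111111 0.2666667 0.1809044 0.2444444   FALSE
#> 2         4 0.06666667 0.2222222 0.1363467 0.2444444    TRUE
```

The observation sits inside the 5–95% band only while the ancestral pool has
fewer than 4 species; phylogenies of the surface fauna indicate far more, so
repeated colonization alone is rejected. The single-colonization model,
by contrast, hits the observation exactly at a plausible founding
probability:

```r
fit_report(cen, obs, "single", q = 1)$roots
#> [1] 0.2158007 0.7841993

expected_sister_fractions(cen, colonization_scenario("single", 0.784, diversification_prob = 1))
#>   expected fraction of aquifers: pairs 0.2178, triplets 0.0268, combined 0.2446
```

An initial colonization probability of about 0.78 (with all remaining niches
filled by in-situ speciation, q = 1) reproduces the observed fraction,
including a realistic share of triplets.

Tree-based workflows (`read_annotated_tree()`,
`find_sympatric_sister_clades()`, `tally_observed()`, `ltt_counts()`) and
the ground-truth generator (`generate_colonization_dataset()`,
`recover_parameters()`) are demonstrated in the vignette
(`vignettes/colonization-models.Rmd`).

## Command line

```sh
exec/stygosim predict --model single --q 1 --p 0:1:0.01 --out curves.tsv
exec/stygosim band --model repeated --p 0.5 --pool-size 3:30 --seed 1 --out band.tsv
exec/stygosim detect --tree tree.nwk --metadata tips.tsv
exec/stygosim synth --model single --p 0.78 --q 1 --seed 1 --out synthds/
```

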