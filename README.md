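# crossreact

Simulation and analysis of cross-reactive antibody display selections.

## The problem

Finding a broadly neutralizing antibody against an antigenically diverse
toxin family — for example the long-chain three-finger α-neurotoxins
(3FTx-L) that dominate elapid snake venom lethality — means finding the
rare clones in a display library that recognize an epitope conserved
across many antigen variants. A practical route is sort-seq
deconvolution: enrich the library against one primary antigen variant
through successive MACS/FACS rounds, split the enriched pool into parallel
final sorts against several variants, deep-sequence every population, and
call the clones present in *all* parallel finals. The mirror-image screen
displays a library of toxin variants and sorts it against the antibody and
against the human nicotinic acetylcholine receptor subtypes, classifying
each variant as antibody-binding, escape (receptor-binding but
antibody-evading) or dysfunctional. `crossreact` implements both analysis
paths, the repertoire analytics around them, distance-based phylogenetics
for the functional variant set, and the survival statistics used for in
vivo protection readouts — plus a generative simulator with planted ground
truth so the whole pipeline is testable with no sequencing download.

## The model in brief

- **Selection simulator.** A clone with dissociation constant `Kd` sorted
  against a bait at concentration `c` is bound with Langmuir occupancy
  `θ = c / (c + Kd)`. Positive sorts retain clones with probability
  `η · (1 − Π_b (1 − θ_b))` over pooled baits; depletion sorts retain the
  unbound fraction `Π_b (1 − θ_b)`. Post-sort frequencies renormalize, and
  sequencing reads are either exact expectations ("lossless") or a
  multinomial draw at fixed depth.
- **Enrichment call.** `E = f_final / max(f_ref, 0.5/N_ref)`; a clone is
  enriched iff `f_final ≥ 1e-5` and `E ≥ 10` (both configurable; reference
  is the naive round 0).
- **Cross-reactivity.** A primary-reactive clone is *present* in a
  parallel final sort iff its frequency there is ≥ `1e-5` (closed bound);
  pan-reactive means present under every bait.
- **Variant categories.** antibody-present → `binding`; antibody-absent
  but receptor-present → `escape`; detected but present nowhere →
  `dysfunctional`; never detected → `absent`.
- **Phylogenetics.** p-distance with pairwise gap exclusion; Jukes-Cantor
  correction `d = −((s−1)/s)·ln(1 − s·p/(s−1))` for alphabet size `s`
  (4 or 20); from-scratch Saitou–Nei neighbor joining with a deterministic
  tie-break, returning `ape::phylo`.
- **Survival.** Kaplan-Meier product-limit curves, the Mantel-Cox log-rank
  test, Bonferroni-corrected thresholds (`0.05/2 = 0.025`).

## Worked example

Simulate the bundled two-stage discovery campaign (400,000-clone naive
library; two pooled-bait MACS rounds; four FACS rounds alternating
positive selection and polyspecificity depletion; five parallel final
sorts), call enrichment against the primary antigen and deconvolve
cross-reactivity:

```r
library(crossreact)

prof     <- fab_campaign_profile(seed = 1)
lib      <- generate_library(prof$library_spec)
campaign <- simulate_campaign(lib, prof$rounds, seed = 1)

calls <- call_enriched(bait_trajectory(campaign, prof$primary_bait))
cp    <- cross_profiles(campaign, primary_set = calls$id[calls$enriched])
cp
#> <cross_profiles> 3873 primary-reactive clones over 5 baits; 52 pan-reactive (1.3%)
#> # A tibble: 5 × 3
#>   bait  n_present pct_retained
#>   <chr>     <int>        <dbl>
#> 1 L1         1627         42
#> 2 L2         3873        100
#> 3 L3          128          3.3
#> 4 L5          240          6.2
#> 5 L6          256          6.6
```

3873 clones are enriched against the primary antigen L2; 42% of them are
also present in the final sort against L1 (the variant closest to L2),
only 3.3–6.6% against the distant variants, and 52 clones (1.3%) survive
all five — the pan-reactive candidates. Their repertoire features read out
the planted breadth signature:

```r
pan <- lib$clones[lib$clones$id %in% cp$profiles$id[cp$profiles$pan_reactive], ]
length_distribution(pan)
#> # A tibble: 2 × 4
#>   length     n  freq   pct
#> 1     19    15 0.288    29
#> 2     20    37 0.712    71
attr(motif_scan(pan, "[WY]YxxGxY"), "fraction")
#> [1] 1
```

71% of the pan-reactive clones carry a 20-residue CDRH3 and all of them
match the `[WY]YxxGxY` motif. A protection experiment reads out the same
way it would from a survival TSV:

```r
rec <- data.frame(group  = rep(c("venom_only", "venom_mab"), each = 5),
                  time_h = c(1.5, 2, 2.5, 3, 3.5, rep(24, 5)),
                  event  = c(rep(1, 5), rep(0, 5)))
logrank_test(rec, "venom_only", "venom_mab")
#> Mantel-Cox log-rank: chisq = 9.701 (df = 1), p = 0.001842
bonferroni_threshold(0.05, 2)
#> [1] 0.025
```

The antigen-side screen works the same way from
`toxin_screen_profile()` / `generate_toxin_panel()` /
`simulate_toxin_screen()`, then `presence_call()`,
`classify_variants()` and `category_summary()`; see the vignette
(`vignettes/selection-analytics.Rmd`) for the model, parameter and
convention details.

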