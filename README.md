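# decaypatterns

Genome-wide classification of mRNA degradation kinetics from
actinomycin-D (ActD) chase time courses, with de novo discovery of the 3′
UTR sequence and secondary-structure motifs that mark fast-decaying
transcripts.

The package is written for transcriptome analysts working with shutoff
time-course designs: a stimulation series (e.g. hours after LPS) crossed
with a chase series after transcription is blocked — by default 8 × 5 =
40 samples.  From gene-level count/RPKM tables it reproduces the full
analysis chain; a ground-truthed synthetic-data generator emulating the
same design makes every stage testable offline.

## The model

After shutoff each transcript decays as

```
r(t) = r1 + (r0 − r1)·exp(−δt)
```

with rate δ (h⁻¹) and half-life ln2/δ.  Four nested variants (complete /
incomplete / delayed shutoff, and both effects) are fitted to
density-peak-cluster means by box-constrained least squares and selected by
AIC (`n·ln(RSS/n) + 2p`).  Chase courses retaining more than
2^(−4/24) ≈ 89% of their initial level at 4 h (a > 24 h half-life) are
long-lived; genes long-lived at ≥ 4 of 8 stimulation times are **stable**,
and the rest split at a mean rate of 0.325 h⁻¹ into **quick** and
**slow**.  Downstream stages cluster genes by 8-slot degradation-pattern
profiles, cross-tabulate against expression dynamics
(immediate/early/late, 3-fold changes), run hypergeometric/BH
over-representation, and search binned UTRs for enriched k-mer motifs
(PWMs, pseudocount 0.8, exact scan p-values) and stem-loop structure
motifs (fold → structure-aware alignment → conserved seeds → iterative
profile search at E ≤ 1 → report at FDR < 10⁻⁴ with ≥ 10 instances).

## Worked example

```r
library(decaypatterns)

design <- study_design(n_genes = 180)           # 8 LPS x 5 ActD chase times
classes <- list(
  kinetic_class(1, half_life = 0.25),           # quick
  kinetic_class(2, delta = 0.9),                # quick
  kinetic_class(3, delta = 0.27),               # slow
  kinetic_class(4, half_life = 30, long_lived = TRUE))
sim <- simulate_counts(design, classes, rep(1:4, each = 45),
                       dispersion = 0.003, seed = 1, baseline_tags = 2000)

res <- classify_degradation(sim$counts, sim$rpkm, k = 3, dc_quantile = 0.1)
table(res$categories$category)
#>
#>  QUICK   SLOW STABLE
#>     91     47     42

fit <- res$kinetics$fits[[which(res$kinetics$ranks == 1)]]
fit
#> decay fit (model 2): delta = 2.774 /h (t1/2 = 0.25 h), r0 = 1, r1 = 0.0141,
#>   rss = 9.93e-08, AIC = -84.7
```

The quickest cluster's fitted rate (δ ≈ 2.77 h⁻¹, half-life 0.25 h)
recovers the planted 0.25 h class, and the quick/slow/stable split tracks
the 45-gene class design (two quick classes above the 0.325 h⁻¹ threshold,
one below, one long-lived) up to counting noise moving a few genes across
the 89% boundary.

Motif discovery on synthetic UTRs with a planted AU-rich element:

```r
are <- plant_spec("sequence", consensus = "UAUUUAU", carrier_fraction = 0.4)
utr <- simulate_utrs(200, plants = list(are),
                     target_genes = list(sprintf("gene%04d", 1:100)), seed = 1)
sets <- sample_bin_sets(bin_utrs(utr$seqs[1:100]), 20, seed = 1)
mot <- find_motifs_sets(sets, k = 7, background = background_freq(utr$seqs))
mot[[1]]$consensus
#> [1] "UAUUUAU"
```

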