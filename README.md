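# silacdyn

Proteome dynamics from pulse-SILAC experiments: turnover rates, label
incorporation kinetics, temporal profile clustering, heavy-channel iBAQ and
functional enrichment — with a ground-truthed synthetic-data generator so
every stage is testable without any external download.

## Who this is for

In a pulsed (dynamic) SILAC experiment a heavy amino-acid label — here
Lys8 (¹³C₆¹⁵N₂-lysine) — is added mid-experiment, so that every protein
synthesized afterwards carries the label. The per-protein heavy/light
intensity ratio *r* over time then reports protein synthesis and turnover.
This package covers the full desk-side analysis of such data for two
challenging regimes in bacterial physiology:

* **persistence** — near-growth-arrested (persister) cells, where
  incorporation stays low (single-digit percent of total ion intensity over
  a 24 h pulse) against a large unlabeled background from dead cells;
* **resuscitation** — cells resuming growth, where incorporation saturates
  high (≈95%) within hours.

It consumes MaxQuant-style `proteinGroups.txt` tables (configurable column
dialect), a protein FASTA for the in-silico digest, and GMT-like annotation
files for enrichment.

## The model

Label incorporation is first order. With turnover rate *k* (h⁻¹) the heavy
fraction is *I(t) = 1 − e^(−kt)*, the H/L ratio is *r(t) = e^(kt) − 1*, and
therefore ln(*r* + 1) = *kt*. The rate is estimated by through-origin least
squares in closed form,

    k = Σᵢ ln(r(tᵢ) + 1) · tᵢ / Σᵢ tᵢ² ,      T½ = ln 2 / k ,

with an uncentered R² as fit quality; fits need > 4 time points and
R² > 0.70 to count as reliable. Notably the estimator involves no growth
rate, which is what makes it applicable to growth-arrested cells. Upstream,
replicates are combined as a union (value kept from 1 replicate = class I,
mean of 2 = class II, of 3 = class III), time points are pooled into bins by
medians, and proteins are quartile-ranked within bins. Downstream, complete
incorporation profiles are clustered (Euclidean distance, Ward linkage,
k = 8 by default), each cluster's time to 50% incorporation is read off a
smoothed conditional mean, clusters are tested for category over- and
underrepresentation (two-sided Fisher exact test, Benjamini–Hochberg FDR),
and newly synthesized protein amounts are estimated as heavy-channel iBAQ
(heavy intensity divided by the count of observable Lys-C peptides from an
in-silico digest; Lys-C cleaves after every K, including K-P).

## Worked example

Simulate a persistence-like experiment (300 proteins, 3 replicates, 17 time
points over 24 h, 10% intensity noise, intensity-dependent dropout), then
run the core analysis:

```r
library(silacdyn)

cfg <- simulation_config("persistence", n_proteins = 300, seed = 42)
sim <- simulate_experiment(cfg)

records <- apply_quality_filters(sim$records)   # flags + ratio-count masking
merged  <- merge_replicates(records)            # class I/II/III union
fits    <- select_reliable_fits(fit_turnover_rates(merged))

cat(sprintf("reliable fits: %d of %d proteins\n", nrow(fits), cfg$n_proteins))
cat(sprintf("median k: %.4g per hour; median half-life: %.0f h\n",
            median(fits$k), median(fits$half_life_h)))

cl <- cluster_profiles(build_profile_matrix(records), K = 8)
print(cl)
```

Output:

```
reliable fits: 300 of 300 proteins
median k: 0.003087 per hour; median half-life: 225 h
median relative rate error vs truth: 2.6%
<cluster_result> 278 profiles in 8 clusters
sizes: 17, 13, 114, 15, 33, 32, 43, 11
t50_h: 14.17, 10.51, -, 21.77, -, -, -, 8.20
```

The median half-life of a few hundred hours is exactly the regime this
world emulates: a 24 h pulse window far shorter than typical half-lives
under growth arrest, so rates are small but measurable. `-` marks clusters
whose smoothed mean never reaches 50% incorporation within the sampled
window (the expected outcome for most persistence clusters). 278 of 300
proteins had complete profiles after dropout and count masking.

The same stages run as a configured pipeline from a JSON file
(`validate_config()` + `run_pipeline()`, or the CLI at
`inst/cli/silacdyn.R` with subcommands `simulate`, `run-all`, and
stage lists such as `filter,merge,turnover`), writing TSV artifacts plus a
manifest with checksums, seed and config hash.

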