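# amidering

Ring-current analysis of anomalous backbone amide ¹H chemical shifts, as a
federated shift–structure pipeline.

Amide protons resonate near 8.3 ppm; a proton close to an aromatic side
chain (PHE, TYR, TRP, HIS) is shifted by the ring current — upfield above
the ring plane, downfield in the plane. `amidering` joins the three data
streams needed to study this at corpus scale:

* **assigned chemical shifts** in an NMR-STAR dialect,
* **NOE distance restraints** (NMR-STAR `_Gen_dist_constraint` loops),
* **multi-model coordinate ensembles** in mmCIF,

linked by an entry-pair mapping and per-atom identifiers (chain id,
sequence id, residue, atom). For each amide with both a shift and
coordinates it computes

* the Z-score `Z = (δ − μ)/σ` against per-(residue, atom) reference
  statistics, with the standard corpus filters (aromatic/paramagnetic
  ligands, carbon-bound protons outside (−2.5, 10) ppm, shifts beyond 8 SD);
* the nearest aromatic ring — centroid, cross-product plane normal,
  azimuth angle folded to [0°, 90°], and the proton–ring-center distance
  **averaged over the ensemble models**;
* whether the amide carries ≥1 amide–aromatic restraint;

and summarises the fraction of restrained amides per integer Z bin, the
per-type distance/Z table below 8 Å, and per-type shift-direction counts.
A synthetic-corpus generator plants point-dipole ring-current effects
(`Δδ = i·B·(1 − 3cos²θ)/r³`) with recorded ground truth, so the entire
pipeline is testable offline.

## Worked example

```r
library(amidering)

cfg <- synthetic_config(n_entries = 5, chain_length = 24,
                        aromatic_fraction = 0.25, n_models = 3, seed = 42)
corpus <- file.path(tempdir(), "demo")
write_fixture_corpus(cfg, corpus)          # shifts/, restraints/, structures/, mapping.json
res <- run_pipeline(corpus, file.path(corpus, "out"), stats_mode = "reference")
res$zbin
```

```
  z_bin n_total n_restrained  fraction
1    -8       2            2 1.0000000
2    -3       7            6 0.8571429
3    -2      10            8 0.8000000
4    -1      19           12 0.6315789
5     0      33           21 0.6363636
6     1      29           23 0.7931034
7     2      11           11 1.0000000
8     3       3            3 1.0000000
9     4       1            1 1.0000000
```

Each row is one Z bin: `n_total` amides from eligible entries (entries
with at least one amide–aromatic restraint) fell in that bin and
`n_restrained` of them have such a restraint. Already in this 115-amide
toy corpus the fraction rises away from Z = 0: strongly shifted amides
are the ones near rings.

```r
res$type_summary
```

```
  aromatic_type n_upfield n_mid n_downfield median_extreme_z
1           HIS         1    34           1       -0.2524275
2           TRP         3    18           2       -2.4442623
3           PHE         3    13           3       -0.2290476
4           TYR         5    23           1       -2.4655917
```

Counts of amides whose nearest ring (within 8 Å) is of each type, split
at Z = ±2, with the median Z of the extreme records. On the larger
calibrated test corpus (see `tests/testthat/test-acceptance.R`) the
medians separate cleanly: ≈ −2.4 for PHE/TYR/TRP (upfield, shielding
above the ring) and ≈ +3.4 for HIS (downfield, in-plane hydrogen bonding
to the imidazole nitrogen).

Outputs are also written as TSV: `merged.tsv` (one row per federated
amide), `zbin_fractions.tsv`, `distance_z.tsv`, `type_summary.tsv`,
`run_report.tsv` (per-entry accounting), `run.log`.

## Command line

```sh
Rscript inst/cli/amide-ring-miner.R synth --out corpus --entries 10 --seed 1
Rscript inst/cli/amide-ring-miner.R run --corpus corpus --out corpus/out \
    --stats-mode filtered --cutoff 8.0
```

## Package layout

* `R/synthetic.R` — corpus generator with planted effects and ground truth
* `R/star-io.R`, `R/cif-io.R` — NMR-STAR and mmCIF readers/writers
* `R/shift-stats.R` — reference statistics, filters, Z-scores and bins
* `R/ring-geometry.R` — ring definitions, center/normal/azimuth,
  ensemble-averaged nearest-ring search
* `R/federate.R` — entry-pair mapping, restraint classification, merge
* `R/analysis.R` — Z-bin fractions, distance/Z tables, pipeline driver
* `vignettes/amide-ring-analysis.Rmd` — the methods account: model,
  assumptions, parameter choices, what the synthetic world does and does
  not establish
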