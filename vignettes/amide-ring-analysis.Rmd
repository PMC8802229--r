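---
title: "Methods: federated analysis of anomalous amide proton shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated analysis of anomalous amide proton shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Backbone amide protons (atom `H`) resonate near 8.3 ppm, but a proton
sitting close to an aromatic side chain is shifted by the ring current of
the delocalised pi system: shielded (upfield, lower ppm) above the ring
plane, deshielded (downfield) in the plane. Whether an unusually shifted
amide really sits near a ring can be checked against structure: chemical
shift archives store the assigned shifts and NOE distance restraints,
structure archives store multi-model coordinate ensembles, and the two are
linked by entry-pair mappings and per-atom identifiers (chain id, sequence
id, residue, atom). `amidering` implements that federation as a reusable
pipeline and ships a synthetic-corpus generator with planted effects so
every stage can be validated without downloading any archive.

## The statistic

For each amide with shift $\delta$ and reference class (residue type,
atom) with mean $\mu$ and standard deviation $\sigma$,

$$Z = \frac{\delta - \mu}{\sigma},$$

so upfield shifts give negative $Z$. Integer bins are $Z$ rounded half
away from zero and clamped to $[-8, 8]$ ($Z = 2.5 \mapsto 3$,
$Z = -2.5 \mapsto -3$). The headline summary is, per bin, the fraction of
amides with at least one amide--aromatic NOE restraint, with denominators
restricted to amides from entries that have at least one such restraint
(the entry-level eligibility reading; a global-denominator and an
all-amides variant sit behind switches in `bin_fractions()`).

## Reference statistics and filtering

`compute_reference_stats()` aggregates a shift corpus per (residue type,
atom name): count, mean, population-denominator SD (the convention of
large-corpus statistics pages; `sd_denominator = "sample"` switches to
n-1), and a 0.1-ppm histogram. Filtered mode applies, in order:

* entry-level exclusion for aromatic or paramagnetic ligand flags;
* entry-level exclusion when any *carbon-bound* proton has a shift above
  10 ppm or below -2.5 ppm (a signature of unusual referencing) --
  classification by an embedded proton topology of the 20 standard
  amino acids, since files do not state the bound element; protons of
  non-standard residues are treated as non-carbon-bound with a warning;
* shift-level removal of values strictly outside eight SDs of the
  full-corpus mean for their class (a value at exactly 8.000 SD is kept).

Whether the eight-SD rule drops shifts or whole entries is genuinely
ambiguous; we drop shifts, reserving entry-level exclusion for the
referencing signature, and the bookkeeping (filtered + excluded = full) is
tested exactly. Z-scoring of study amides defaults to filtered statistics;
`run_pipeline(stats_mode=)` selects `"full"`, `"filtered"`, or
`"reference"` (an external TSV). For planted-effect recovery tests the
`"reference"` mode is the right choice: statistics recomputed from a
corpus that contains the planted outliers have an inflated SD and a
shifted mean, which would attenuate the very effect being measured.

## Ring geometry

Rings are defined per residue type: PHE/TYR
{CG, CD1, CD2, CE1, CE2, CZ}; HIS {CG, ND1, CD2, CE1, NE2}; TRP as two
independent rings, {CD2, CE2, CE3, CZ2, CZ3, CH2} and
{CG, CD1, NE1, CE2, CD2}, competing separately in the nearest-ring
search ("nearest aromatic ring" is geometric and the indole has two
aromatic cycles). Per model:

* center = centroid of the member atoms (ring undefined in models
  missing a member);
* normal = cross product of the vectors from the center to the first and
  second member, normalised -- the constructive definition, not a
  least-squares fit; its sign depends on operand order, so
* azimuth = angle between the normal and the center-to-proton vector,
  folded to $[0^\circ, 90^\circ]$ ($0^\circ$ on the axis, $90^\circ$
  in plane).

The proton--ring distance of record is the plain Euclidean distance to
the center, *averaged over the ensemble models* in which both proton and
complete ring exist. Nearest-ring selection minimises this ensemble
average (not a per-model nearest), because the reported quantity is the
average itself; ties below $10^{-6}$ A resolve to the lexicographically
smallest (chain, seq, ring id). Distances are superposition-invariant, so
models are used as deposited, without alignment. Rings from any chain are
candidates. Ring protons (for restraint classification) include the
nitrogen-bound HIS HD1/HE2 and TRP HE1 by default -- "aromatic ring
proton" carries no element restriction -- with `carbon_only` to restrict.

## Federation

`merge_entry()` joins on (chain id, sequence id) for the canonical amide
proton name `H` (the `HN` dialect is canonicalised at parse time). A
merged record requires a reported shift *and* a coordinate in at least
one model; shift-only and coordinate-only amides are counted, not merged,
and the accounting `merged + shift_only + coord_only + skipped =
candidates` is exact. Restraints are classified as amide--aromatic
(order-insensitively) and matched to amides by the (chain, seq) of their
amide member within the same entry; the aromatic member is *not* required
to be the nearest ring, and no geometric cutoff is applied to restraints
-- the downstream summary conditions on restraint existence only.
Entries whose files fail to parse are dropped with a report line;
corpus-scale surveys should not abort on one bad entry.

## The synthetic world

`write_fixture_corpus()` emulates all four inputs. Its structures are
deliberately not physical polymers: residues sit on a 5-A 3D grid
(producing a realistic range of amide--ring contacts of 2.5--8 A), each
non-terminal residue carries an amide proton at a random unit offset from
its nitrogen, and each aromatic residue carries a geometrically exact
planar ring (1.39-A bonds, TRP as a fused planar indole with shared
CD2--CE2 edge) at a random orientation, 2.5--4 A from the residue anchor.
Models differ by 0.05-A Gaussian jitter of non-ring atoms; ring members
are shared across models, so planarity holds in every model and the exact
ring centers are recorded as ground truth. Realism that is *not*
emulated: covalent backbone connectivity, rotamers, packing, secondary
structure, distance-dependent restraint probability, and any published
ring-current parameterisation. A green end-to-end test therefore
establishes the correctness of the bookkeeping, geometry, statistics and
federation -- not fidelity to real archive content.

Shifts are planted as $\delta = \mu + \Delta\delta + \epsilon$,
$\epsilon \sim N(0, (\texttt{noise\_sd\_scale}\cdot\sigma)^2)$ i.i.d. per
atom (matching the Z-score model's implicit assumption), with reference
$\mu,\sigma$ from a built-in amide table of 19 residue types with
realistic archive-scale values (e.g. ALA 8.20 +/- 0.60 ppm). The
perturbation from the nearest ring within 8 A uses the point-dipole
form

$$\Delta\delta = i\,B\,\frac{1 - 3\cos^2\theta}{r^3},$$

averaged over models, with $B = 30.42$ ppm A$^3$ and intensities 1.00
(PHE/TYR), 1.04/0.90 (TRP six/five), 0.53 (HIS). These constants are
generator defaults only -- ground truth records every perturbation, so no
downstream check depends on them; the point-dipole choice is a stand-in
with the right signs and decay, not a reproduction of any published
ring-current model.

**Calibrated planting.** The recovery tests need a subset of amides whose
planted effect is exactly $k\sigma$. With `calibrate_target_z = k`,
amides within 4 A of a ring get an override: $-k\sigma$ when on-axis
(azimuth <= 30 deg) near PHE/TYR/TRP, $+k\sigma$ when in-plane (azimuth
>= 60 deg) near HIS -- the physically correct signs, and the reason the
extreme-Z medians are negative for PHE/TYR/TRP and positive for HIS. All
other amides keep the graded point-dipole background rather than zero:
restrained amides as a class then have over-dispersed Z at every
magnitude, which is what makes the restrained fraction rise monotonically
with $|Z|$ bin, as in real data, instead of only at the planted spike.
Calibrated amides are flagged in the ground-truth sidecar.

Restraints are emitted for every (amide H, ring proton) pair with
model-averaged distance <= 5 A (the model-averaged analogue of an NOE
upper bound), plus HA--HA decoys at 20% of the emitted set to exercise
classifier rejection.

## Numerical choices

* All printed boundaries are strict: distance/Z records require
  `avg_distance < 8` (exactly 8.000 excluded); the eight-SD filter drops
  only strictly-outside shifts; the +/-2 Z thresholds in the direction
  summary use `<= -2` / `>= 2`.
* Half-integer Z bins round away from zero; bins clamp to [-8, 8].
* SD with count 1 is recorded as 0 with a flag, and Z-scoring against an
  sd of 0 is an error naming the class, never an Inf.
* Writers emit 3 decimals (ppm and A); round-trip tests assert at that
  precision.
* Determinism: every generator consumes an explicit seed (entry-indexed
  so entries are decorrelated), and `run_pipeline()` on fixed inputs is
  byte-identical across runs.
* Altloc resolution in mmCIF: highest occupancy, first on ties. Chain
  identity prefers author fields over label fields, since merging uses
  author-style identifiers.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `noise_sd_scale` | 1 | -- | per-shift noise as a multiple of the class SD |
| `effect_amplitude_B` | 30.42 | ppm A^3 | point-dipole constant; 0 = negative control |
| `ring_intensity` | 1.00/1.04/0.90/0.53 | -- | per ring type, relative to a benzene-like ring |
| `effect_radius` | 8 | A | no perturbation beyond this ensemble-averaged distance |
| `restraint_cutoff` | 5 | A | model-averaged pair distance for emitting a restraint |
| `calibrate_r_max`, `calibrate_theta_max` | 4, 30 | A, deg | calibrated-planting gates |
| `stats.hist_bin` | 0.1 | ppm | histogram bin width |
| pipeline `cutoff` | 8 | A | strict bound for the distance/Z table |

## Known limitations

* Sequence numbering is taken as given; author-vs-deposition renumbering
  mismatches are reported as unmatched atoms, never reconciled by
  alignment.
* Only the four standard aromatic amino acids contribute rings; aromatic
  ligands are not ring candidates (ligand sites are parsed and flagged
  but excluded).
* One shift loop and one restraint loop per file (first match wins with
  a warning); full dictionary validation is out of scope.
* The Z standardisation property (per-class mean 0, SD 1 over the
  stats-building corpus) holds with the population-SD convention used
  throughout; with sample SDs it holds only up to $\sqrt{n/(n-1)}$.
* Archive-scale counts from any particular database snapshot are not
  reproducible here and are not claimed; every number the package
  reports is computed at run time from its inputs.
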