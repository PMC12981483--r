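# phtitra

Post-processing toolkit for **constant-pH molecular dynamics (CpHMD)**
simulations of peptides and small proteins, written for structural
bioinformaticians who run λ-dynamics titrations and want reproducible,
scriptable analysis of the output: residue pKa values, pH-dependent
hydrogen-bond networks, and backbone-flexibility profiles.

## What it computes

**Titration analysis.** In λ-dynamics CpHMD each titratable site carries a
continuous coordinate λ (1 = deprotonated, 0 = protonated); two-site
residues (carboxylates, histidine) add a tautomer coordinate χ. Frames are
classified as pure deprotonated (λ ≥ 0.8), pure protonated (λ ≤ 0.2), or
discarded (mid-band λ, or mixed tautomer 0.2 < χ < 0.8). At each simulated
pH the deprotonated fraction is

    S = N_deprot / (N_deprot + N_prot)

and the titration curve is fitted with the generalized
Henderson–Hasselbalch (Hill) model

    S(pH) = 1 / (1 + 10^{n (pKa − pH)})

by bounded nonlinear least squares in (pKa, n); the pKa is the pH at which
S = 0.5, exactly, by construction. ΔpKa values are reported against an
editable model-pentapeptide reference table. Partial charges interpolate
linearly along λ, q(λ) = λ·q_deprot + (1 − λ)·q_prot.

**H-bond network graphs.** Geometric criteria (donor–acceptor heteroatom
distance ≤ 3.5 Å; deviation from donor–H···acceptor linearity below 20° or
60°) detect direct H-bonds and water-mediated bridges through 1–3 mutually
H-bonded waters. Edge *occupancy* is the percentage of analysed frames in
which an interaction is present. Three residue-level graph sets are built —
(1) backbone + side chains + water bridges, (2) side-chain only with
bridges, (3) direct side-chain bonds — with canonical minimum-occupancy
thresholds (10% at 20°; 50/25/15% at 60° for sets 1/2/3). Graphs export as
CSV edge lists and GraphML.

**Backbone conformation.** Per-residue φ/ψ series feed a circular
dispersion metric (PAD): with R̄ the mean resultant length of the combined
(φ, ψ) unit-vector representation, PAD = (180/π)·√(−2 ln R̄), 0 for a rigid
residue and up to 180° in the uniform limit. A dihedral-window assignment
(φ ∈ [−100°, −30°], ψ ∈ [−67°, −7°], runs ≥ 4) yields α-helical content.

**Synthetic ground truth.** Seeded generators produce λ/χ records obeying
the Hill law at chosen (pKa, n) and toy peptide/water ensembles with
engineered contacts at prescribed occupancy — the package's round-trip test
bed.

## Worked example

```r
library(phtitra)
spec <- synthetic_spec(pka_true = 3.6, hill_true = 1.0, ph_grid = 3:7,
                       n_samples_per_ph = 20000, mixed_chi_fraction = 0.05,
                       seed = 11, residue_id = "ASP6")
records <- simulate_titration_records(spec)
points  <- titration_points(records)
points
#>   ph fraction_deprot n_deprot n_prot n_discarded n_total
#> 1  3       0.1985708     3779  15252         969   20000
#> 2  4       0.7130600    13546   5451        1003   20000
#> 3  5       0.9629240    18310    705         985   20000
#> 4  6       0.9969004    18976     59         965   20000
#> 5  7       0.9996308    18951      7        1042   20000

fit <- fit_titration_curve(points, "ASP6")
fit
#> Titration fit for ASP6: pKa = 3.605, Hill n = 1.003 (residual norm 1.61e-03, converged)
pka_shift(fit, reference_pka_table())
#> [1] -0.4048337
```

The ~5% discarded frames per pH are the injected mixed-tautomer states the
classifier must reject; the fit recovers the generator's ground truth
(pKa 3.6, n 1.0) from 100,000 sampled frames, and the negative ΔpKa says
this site titrates 0.4 units below the Asp model-compound reference — the
signature of an environment stabilising the deprotonated form.

A command-line wrapper is included for shell pipelines:

```sh
Rscript inst/cli/phtitra.R simulate --pka 4.5 --n 10000 --seed 1 --out runs/
Rscript inst/cli/phtitra.R titrate --inputs runs/ph3.tsv,runs/ph4.tsv,runs/ph5.tsv,runs/ph6.tsv,runs/ph7.tsv --out runs/fit
Rscript inst/cli/phtitra.R hbonds --pdb ensemble.pdb --set 3 --angle 60 --out runs/hb
Rscript inst/cli/phtitra.R measure --pdb ensemble.pdb --a 22:OG --b 19:O
```

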