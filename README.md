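# nmrcryst

Chemical-shift-driven NMR crystallography of amorphous molecular solids.

Amorphous drug formulations have no single structure: the experiment sees an
ensemble of molecular conformations and packing environments, and solid-state
NMR records that disorder as broad chemical-shift *distributions* rather than
sharp peaks. `nmrcryst` implements the ensemble-selection workflow that turns
these distributions into an atomic-level structural model:

1. **Candidate pool (MD set).** Millions of local molecular environments — a
   central molecule plus every molecule with at least one atom within a
   cutoff (7 Å by default) — extracted from molecular-dynamics snapshots.
2. **Experimental distributions.** Gaussians (μₖ, sₖ in ppm) fitted to the 1D
   ¹³C CPMAS spectrum, seeded by the crystalline assignment, with ¹H
   distributions assigned from HETCOR cross-peaks.
3. **Scoring.** Predicted shieldings are converted to shifts
   (δ = c_nuc − σ_iso, with c = 30.78 ppm for ¹H and 170.04 ppm for ¹³C);
   each predicted shift δᵢ gets a two-sided Gaussian tail probability
   pᵢ = erfc(|δᵢ − μᵢ|/(sᵢ√2)), and an environment's agreement is the
   geometric mean p_global = (∏ pᵢ)^(1/N). Restricting the product to the
   atoms within *n* bonds of a chosen center (plus their hydrogens) gives
   the local "W-n" probability used for partial assignments.
4. **Selection (NMR set).** The environments with the highest p_global — by
   threshold, count, or fraction — form the experimentally preferred subset.
5. **Characterization.** Hydrogen-bond motif statistics (promotion/demotion
   of acceptor classes between NMR and MD sets), torsion-angle histograms,
   element-resolved 3D atomic density maps (amplitude-1 Gaussians of width
   0.5 Å on a 12 Å cubic grid, aligned on reference atoms), and
   formation energies E_form = E(environment) − E(environment − central)
   under a pluggable energy backend.

A synthetic-data generator with planted ground truth (H-bond prevalence,
torsion modes, a forward shift model with a 4 ppm downfield donor-proton
increment) makes the full pipeline testable without MD or spectrometer data.

## Worked example

```r
library(nmrcryst)

# a small synthetic ensemble with known ground truth:
# 5,000 environments, 30% with a planted N-H...O/water hydrogen bond
cfg <- synth_config(n_runs = 2, n_frames = 50, n_molecules = 50, seed = 1)
ens <- generate_environments(cfg)
pred <- forward_shifts(ens$truth, cfg)

# "experimental" shift distributions (here taken from the H-bonded
# subpopulation; with real data they come from fit_gaussian_mixture())
dists <- empirical_distributions(pred, ens$truth$env_id[ens$truth$hbond])

# local (W3) selection around the donor nitrogen: shifts within 3 bonds
shell <- bond_shell(ens$graph, "N1", 3)
print(shell)
#> <shell_selection> W3 around N1: 8 atoms, 7 of 11 shifts used

sel <- select_environments(local_probability(pred, dists, shell),
                           "top_fraction", fraction = 0.01)
cat(sprintf("selected %d of %d environments (p >= %.3f)\n",
            attr(sel, "n_selected"), nrow(sel), attr(sel, "threshold")))
#> selected 50 of 5000 environments (p >= 0.652)

# hydrogen-bond promotion: NMR set vs a random MD baseline
nmr_ids  <- sel$env_id[sel$selected]
base_ids <- sample_baseline(ens$truth$env_id, ens$truth$run_id,
                            n_per_run = 100, seed = 99)
rec_nmr  <- detect_hbonds(get_environments(ens, nmr_ids),  "H1")
rec_base <- detect_hbonds(get_environments(ens, base_ids), "H1")
print(compare_categories(rec_base, rec_nmr), digits = 3)
#>   category count_MD count_NMR percent_MD percent_NMR delta
#> 1     none      145         3       72.5           6 -66.5
#> 2       O1       24        24       12.0          48  36.0
#> 3       O2       20        11       10.0          22  12.0
#> 4    water       11        12        5.5          24  18.5

# formation energies under the toy backend
be <- toy_backend()
fe_nmr  <- formation_energies(get_environments(ens, nmr_ids),  be)
fe_base <- formation_energies(get_environments(ens, base_ids), be)
print(compare_energy_sets(fe_nmr, fe_base), digits = 3)
#>   bin mean_NMR median_NMR n_NMR mean_baseline median_baseline n_baseline
#> 1 all       -7      -7.29    50         -3.52           -2.15        200
#>   diff_mean diff_median flagged
#> 1     -3.49       -5.15   FALSE
```

Reading the output: selection is driven only by agreement with the shift
distributions, yet it promotes the hydrogen-bonded acceptor classes (`O1`,
`O2`, `water`) from 27.5% of the baseline to 94% of the NMR set and demotes
`none` from 72.5% to 6% — and the selected set is on average ~3.5 kJ/mol
more stable, purely as a by-product, because the planted H-bond carries a
5 kJ/mol well in the toy potential and the baseline itself is 30%
H-bonded.

With real inputs, replace the generator with `read_extxyz()` +
`extract_environments()` for the MD set, `fit_gaussian_mixture()` /
`assign_proton_distributions()` for the distributions, and a
`read_predicted_shifts()` table (shifts or shieldings) from your shift
predictor. Density maps come from `align_environment()` +
`accumulate_density()` and export to Gaussian cube via `export_cube()`;
external energy codes plug in through `command_backend()`.

A ready-to-run synthetic workspace (molecule JSON, extended-XYZ frames,
predicted shifts, ground truth) can be written from the command line:

```sh
Rscript inst/cli/nmrcryst-synth --out ws --n-runs 2 --n-frames 10 \
    --n-molecules 10 --seed 1
```

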