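# mesochrom

Mesoscale heterochromatin domains from polymer simulation and soft-X-ray
tomography quantification.

Condensed (hetero)chromatin in intact nuclei organizes into dense
mesoscale domains — roughly spherical regions ~30–250 nm across with a
mean effective diameter near 80 nm and typical centre-to-centre
nearest-neighbour separations near 120 nm. `mesochrom` provides, in one
tested package, the two computational engines needed to study that
organization:

1. **A Brownian-dynamics polymer model.** A chain of `N` beads —
   euchromatin-like (EC/A, 18 nm) and heterochromatin-like (HC/B,
   25 nm) beads mixed 55:45 — confined to a spherical cavity with
   repulsive WCA walls. Beads interact through a soft Gaussian
   exclusion `ε_vex e^(−α_vex r²)`, a FENE bond
   `−12 k r₀² ln[1 − (r/r₀)²]` between chain neighbours, and a
   heterochromatin affinity between B beads,
   `−ε_HC r² e^(−α_HC[d_B − 1/(α_HC d_B) + r²])`, whose minimum sits at
   the optimal separation `d_B`. The overdamped Langevin equation with
   Stokes drag `3πησ_i` is integrated by Euler–Maruyama
   (`dt = 10⁻⁴ τ`). At strong affinity (`ε_HC = 3 k_BT`) the B beads
   condense into mesoscale clusters; the package measures their sizes
   (volume-equivalent diameters), nearest-neighbour separations,
   chain-link coordination numbers `z_c`, per-type mean squared
   displacements and overlap functions, and the pair correlation
   function with an exact spherical-confinement normalization.

2. **A LAC-volume quantification pipeline.** For 3D linear-absorption-
   coefficient volumes (1/µm, 13 nm voxels): domain thresholding at
   `Θ = min + 0.6 (max − min)` of the heterochromatin region, 3D
   distance-transform watershed segmentation, missing-wedge-corrected
   effective diameters `D_eff = (6 f_mw V_seg/π)^{1/3}`, k-NN distance
   distributions, domain pair correlation and coordination number
   `z = 4πρ ∫ r² g(r) dr` over the first peak, skew-normal size-
   distribution fits, per-region LAC statistics, a toy parallel-beam
   tilt-series / SIRT reconstruction with even/odd Fourier-shell-
   correlation resolution estimation, 2D mask registration, and a
   PCA→LDA / random-forest multiparametric classification stage.
   Synthetic-data generators (LAC phantoms with ground truth, labelled
   feature tables, registration mask pairs) make every stage testable
   offline.

## A worked example

Simulate a scaled control-condition chain and quantify its clusters
(a few minutes at these sizes):

```r
library(mesochrom)

cfg <- sim_config(n_beads = 500, cavity_radius = 15.3,  # ~275 nm
                  params = interaction_params(eps_HC = 3),
                  n_steps = 4e5, stride = 4000, seed = 3)
traj <- run_simulation(cfg)
cs <- cluster_statistics(traj, snapshots = 76:101)  # trailing quarter
mean(cs$diameter_nm); mean(cs$nn_sep_nm); mean(cs$z_c)
#> [1] 80.93499
#> [1] 146.6176
#> [1] 1.6
```

Read: at strong affinity the heterochromatin beads have condensed into
five domains (stable over the measurement window) whose mean
volume-equivalent diameter (~81 nm) and nearest-neighbour separation
(~147 nm) sit at the experimentally observed mesoscale; the mean
coordination number is bounded by the small number of domains a
500-bead system can sustain (see the methods vignette on finite-size
effects).

Segment a synthetic LAC phantom and recover its ground truth:

```r
ph <- generate_phantom(phantom_config(shape = c(96, 96, 96),
                                      n_domains = 30,
                                      dense_range = c(0.22, 0.27)),
                       seed = 5)
seg <- segment_domains(ph$volume)
nrow(seg$domains); mean(seg$domains$d_eff_nm); mean(ph$truth$diameter_nm)
#> [1] 30
#> [1] 80.03181
#> [1] 80.05419
```

All 30 planted domains are found and the mean effective diameter is
recovered to within 0.1 nm.

## Package layout

| Area | Functions |
| --- | --- |
| Units & interactions | `unit_system`, `interaction_params`, `pair_energy`, `hc_optimal_separation` |
| Simulation | `build_initial_chain`, `run_simulation`, `step_euler_maruyama`, `compute_forces`, `export_xyz` |
| Simulation analysis | `msd`, `overlap_function`, `confined_rdf`, `identify_clusters`, `cluster_coordination`, `cluster_statistics`, `bond_cutoff_from_rdf` |
| Tomography | `lac_volume`, `hmd_threshold`, `segment_domains`, `effective_diameter`, `knn_distances`, `domain_rdf_and_zc`, `fit_skew_normal`, `lac_statistics` |
| Reconstruction | `project_tilt_series`, `sirt_reconstruct`, `split_even_odd`, `fsc_resolution` |
| Registration | `register_masks`, `affine2d`, `mask_boundary` |
| Statistics | `extract_features`, `lda_pipeline`, `rf_validate_and_select`, `mvt_ellipse`, `mann_whitney_u` |
| Synthetic data | `generate_phantom`, `generate_feature_table`, `generate_mask_pair`, `rskewnorm` |

The methods vignette (`vignettes/mesoscale-domains.Rmd`) documents the
model, the parameter defaults and every numerical design decision.
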