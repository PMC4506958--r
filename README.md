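# bindmode

Protein–ligand binding-mode analysis across crystal structures and MD
trajectories, in R.

When a small molecule mediates crystal packing — touching a symmetry-related
copy of the protein as well as the chain it binds — the pose seen in the
crystal may be atypical of solution. `bindmode` implements the full analysis
used to investigate that question for a carboxylate-bearing ligand of the
Keap1 Kelch domain (the β-propeller that binds the Nrf2 ETGE/DLG motifs),
as a general, configurable toolkit:

* **Structure I/O** — single- and multi-model PDB reading/writing with unit
  cell and space-group capture (P1, P2₁2₁2₁, P6₅22 operators tabulated
  in-package), deterministic atom selection, verbatim author numbering.
* **Contact classification** — each protein–ligand heavy-atom pair gets one
  type with precedence HB > NP > ES: hydrogen bond at *d* ≤ 3.4 Å between
  donor/acceptor-complementary N/O atoms passing a heavy-atom angle check
  (antecedent–donor–acceptor ≥ 90°); nonpolar at *d* ≤ 3.4 Å otherwise;
  electrostatic for charged pairs at 3.4 < *d* ≤ 4.0 Å. Water bridges
  (protein–water–ligand, two HB legs) count once. All thresholds and the
  per-ligand donor/acceptor typing live in `interaction_rules()` / YAML.
* **Packing audit** — `count_packing_contacts()` splits ligand contacts at
  ≤ 3.4 Å between the asymmetric unit and symmetry images generated by
  space-group expansion, with a per-mate breakdown.
* **MD analysis** — per-frame contact counts, analysis-window extraction,
  superposition-atom selection from persistent pairs (minimum distance over
  the window ≤ 3.4 Å, minus flip-ambiguous Tyr/Phe ring carbons and ligand
  carboxylate oxygens), per-pair occupancy/frequency statistics.
* **Clustering** — all-pair Kabsch-fitted RMSD matrix; greedy
  neighbour-count (Daura) clustering with strict `< cutoff` neighbours;
  cutoff heuristic = 0.70 × mean intratrajectory RMSD snapped to 0.1 Å
  (e.g. mean 1.232 Å → cutoff 0.9 Å); per-cluster reports including whether
  the crystal pose would join any cluster.
* **Mimicry** — anchored superposition plus centroid distances between
  probe groups (e.g. ligand carboxylate vs substrate glutamate).
* **Synthetic data** — seeded generators for planted-binding-mode
  trajectories (stated occupancies, Gaussian noise, dissociation frames),
  toy crystals realising requested packing counts, and interaction-geometry
  fixtures realising requested classification profiles.

## Worked example

Recognition summary from a published contact table shipped with the package
(the machine-readable form of the soaking-form crystal contacts):

```r
library(bindmode)
soak <- read_contact_table(
  system.file("extdata", "keap1_ligand1_contacts_soaking.tsv",
              package = "bindmode"), form_label = "soaking")
soak
#> <interaction_table> [soaking] 23 contacts (1 HB, 19 NP, 3 ES), 1 water bridges
summarize_recognition(soak)
#> <recognition_summary> 10 residues; 1 HB, 1 water-mediated HB, 19 NP, 3 ES
```

Ten residues recognise the ligand, dominated by nonpolar contacts — with
one direct and one water-mediated hydrogen bond and three electrostatic
interactions from the arginine guanidinium groups to the carboxylate.

A full synthetic round trip — simulate a trajectory with three planted
binding modes, take the second half as the analysis window, select
superposition atoms from persistent contacts, cluster, and report:

```r
sim  <- simulate_trajectory(trajectory_sim_spec(n_frames = 200, seed = 1))
tr   <- sim$trajectory
psel <- select_atoms(tr, het = FALSE)
lsel <- select_atoms(tr, het = TRUE)
w    <- window(tr, 101, 200)
ss   <- derive_superposition_atoms(w, psel, lsel)
m    <- pairwise_rmsd(w, ss)
co   <- cutoff_from_mean(m)
cl   <- daura_cluster(m, co$cutoff)
cluster_report(cl, w, ss, psel, lsel, m, params = cluster_params(co$cutoff))
#> <cluster_report> 100 structures, 1126 contacts (11.26/structure), <Rmsd> 1.812 A, cutoff 1.3 A
#>   cluster 1: 63 structures (63%), center frame 101 at 2020 ps, <Rmsd> 0.288 A
#>   cluster 2: 26 structures (26%), center frame 103 at 2060 ps, <Rmsd> 0.273 A
#>   cluster 3: 11 structures (11%), center frame 122 at 2440 ps, <Rmsd> 0.283 A
```

The three planted modes (occupancies 0.60/0.25/0.15) come back as three
clusters at 63/26/11 of the 100-frame window, each internally tight
(≈ 0.28 Å) against a window-wide mean RMSD of 1.81 Å.

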