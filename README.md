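# integrinmech

Analysis toolkit for the mechanics of integrin transmembrane-domain
clustering: can two transmembrane-cytoplasmic (TMC) helices of an
adhesion receptor reach each other inside a lipid bilayer, given the
dense lipid shell that packs around each helix, and can the cytoskeleton
supply the energy to push them through it?

The package implements the full analysis layer of that question as
tested, reusable R components:

* **Cα elastic-network normal modes** — Hookean springs between Cα nodes
  within an 8 Å cutoff; Hessian `H` assembled from pairwise
  super-elements `k·ûûᵀ`; modes from the symmetric eigendecomposition,
  numbered so mode 7 is the first internal mode. Includes covalent-link
  metadata for spliced chains, per-mode deformation energies `½λᵢ`, and
  hinge/domain detection from a mode's displacement field
  (`find_hinge_mode()` scans for the first clean anti-phase two-domain
  mode).
* **Jarzynski free-energy estimation** — from repeated steered-pull
  force traces: work by trapezoidal integration over the guide
  coordinate (stiff-spring convention), then either the exponential
  average `ΔF = −β⁻¹ log⟨e^{−βW}⟩` (log-sum-exp guarded) or the default
  second-order cumulant expansion `ΔF ≈ ⟨W⟩ − (β/2)·Var W` (exact for
  Gaussian work, far less biased at the protocol's M = 10 repeats), plus
  peak-minus-preceding-valley barrier extraction.
* **Membrane profilers** — lipid number density and bilayer thickness
  along the inter-monomer axis, lipid-shell tracking, and truncated
  Lennard-Jones/Coulomb group–group energies (1.2 nm cutoff,
  Lorentz–Berthelot).
* **Diffusion / feasibility arithmetic** — 2-D random-walk displacement
  scale `σ = √(4Dt)`, instantaneous step speed `V = √(4D/Δt)`, steering
  speed selection, actin stretch `d = ΔF·k_BT/F`, and lipid-cylinder
  geometry.
* **Seeded synthetic generators** — hinged two-domain dumbbells,
  membrane patches with a known density contrast and thinning channel,
  and an overdamped-Langevin puller on a prescribed free-energy profile,
  so every estimator is validated against exact ground truth.

## Worked example

```r
library(integrinmech)

## 1. A hinged two-domain structure and its soft modes
db <- make_dumbbell(n1 = 40, n2 = 20, linker = 12, seed = 1)
modes <- compute_modes(db$structure, cutoff = 8)
modes
#> ModeSet: 72 nodes, cutoff 8 A, k = 1; 6 zero modes (1 component)
find_hinge_mode(modes, db$structure)
#> HingeReport: mode 13, 1 hinge residues, anticorrelation -0.997
# the detected hinge (residue 42) sits inside the labelled linker 41..52

## 2. Free-energy profile from 10 simulated pulls
spec <- pmf_spec(barrier_kBT = 4)
barrier_height(pmf_true_profile(spec))$barrier_kBT
#> [1] 3.506531          # prescribed barrier net of the downhill ramp
traces <- simulate_pull(spec, M = 10, speed_nm_ns = 0.1, seed = 7)
barrier_height(estimate_pmf(traces))$barrier_kBT
#> [1] 3.833659          # recovered within 1 kBT at slow steering

## 3. Diffusion-derived steering speeds and feasibility
p <- diffusion_params(D_nm2_per_us = 0.25, t_ns = 2, dt_fs = 2)
position_std(p)          #> 0.04472136   sigma, nm
characteristic_speed(p)  #> 0.06708204   3*sigma/t, nm/ns
instantaneous_speed(p)   #> 22.36068     sqrt(4D/dt), nm/ns
required_stretch(400, temperature_K = 310, force_pN = 50)
#> [1] 34.2401           # nm of actin stretch to supply a 400 kBT barrier
geometric_radii(5.1, 2)$envelope_radius_nm
#> [1] 2.55              # lipid-cylinder radius per monomer
```

The numbers mean: a membrane protein diffusing at 0.25 nm²/µs barely
moves (σ ≈ 0.045 nm) on the 2 ns simulation time scale, but its
per-time-step speed is ~22 nm/ns, so a steering speed an order of
magnitude below that (~2.2–2.5 nm/ns) is the fastest physically
defensible pull; a 400 kBT association barrier is within reach of a
~34 nm stretch of an actin filament bearing 50 pN, which is available to
β-subunits (cytoskeleton-linked) but not to α-subunits.

Same analyses from a shell:

```sh
integrinmech speeds --D 0.25 --t 2 --dt 2 --out speeds.tsv
integrinmech synth pull --outdir traces --seed 7 --M 10 --speed 0.1
integrinmech pmf --traces traces --estimator second_order --out pmf.tsv
```

Every run writes a `<out>.run.json` log of its parameters and versions.

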