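# paleomech

Musculoskeletal biomechanics of extinct archosaurs from bone meshes, in R.

`paleomech` is aimed at vertebrate palaeobiologists who build "digital
marionette" style rigid-body models of fossil taxa — the workflow behind
recent analyses of locomotion in Triassic pseudosuchians such as
*Riojasuchus tenuisceps* — and want the numerical core of that workflow as
reusable, tested functions rather than a chain of GUI operations. It covers
the whole chain from triangle meshes to a posture verdict:

- **Rigid-body mass properties.** For a watertight triangle mesh with
  uniform density ρ, volume, centre of mass and inertia are computed by
  exact divergence-theorem integration over signed origin tetrahedra
  (`mass_properties()`), composed across posed segments
  (`composite_properties()`) and mirrored for bilateral symmetry
  (`mirror_body()`).
- **Segment reconstruction by hoop lofting.** Body segments are built from
  serial octagonal cross-sections (`loft_hoops()`), with internal air
  cavities (pharynx, trachea, lungs) subtracted as negative-density terms:
  m = ρ V_outer + Σ (ρ_cav − ρ) V_cav (`segment_mass()`).
- **Joint frames from articular surfaces.** Least-squares sphere, cylinder,
  ellipsoid and plane fits (`fit_primitive()`) feed right-handed anatomical
  coordinate systems (`build_acs()`). Joints rotate in x→y→z order about
  the shared JCS, z being flexion–extension; hips and shoulders get three
  DOFs, all other limb joints one (`forward_kinematics()`).
- **Range of motion.** Published judgment-based limits ship as a fixture;
  `rom_scan()` automates a proxy using triangle–triangle collision and an
  articular-gap disarticulation threshold, and `rom_check()` validates
  poses against limits.
- **Muscle moment arms by tendon excursion.** Muscle–tendon paths with via
  points and sphere/cylinder wrapping surfaces (`muscle_path()`,
  `wrap_surface()`) give lengths L(θ) in any pose; the signed moment arm is
  r = −dL/dθ by central difference (`moment_arm()`, `mma_sweep()`,
  `classify_action()`).
- **Whole-body analysis.** COM offsets from the acetabula
  (`whole_body_com()`), a craniocaudal static bipedal-support test
  (`bipedal_feasibility()`), limb-chain lengths (`limb_lengths()`), and
  allometric body mass from stylopodial circumferences,
  log₁₀ BM[g] = 2.749 log₁₀(C_h + C_f [mm]) − 1.104
  (`allometric_mass()`).
- **Posture classification.** Two-class pooled-covariance LDA written from
  the formulas (w = Σ⁻¹(μ₁ − μ₀); `fit_lda()`, `predict()`), with a
  repeated-training-set voting harness (`vote_over_trainings()`).
- **Synthetic skeletons with known answers.** Seeded generators
  (`make_skeleton()`, `make_hoop_body()`, `make_articular_patch()`,
  `make_posture_features()`) emulate every input class with closed-form
  ground truth, so the full pipeline is testable without CT data.

## Worked example

```r
library(paleomech)

# allometric mass from humeral + femoral circumferences (mm)
allometric_mass(39, 66)$mass_kg
#> [1] 28.33018

# a seeded synthetic skeleton scaled to the published dimensions
sk <- make_skeleton(7)
limb_lengths(sk$model)
#> $hindlimb [1] 0.32   $forelimb [1] 0.222   $ga_m [1] 0.355

# whole-body COM in the "realistic" preset pose (-10 deg hip/knee/ankle
# flexion), measured from the acetabula
whole_body_com(sk$model, sk$model$poses$realistic)
#> whole-body mass 4.657 kg
#> COM offset from acetabula: 0.1712 m craniad, -0.05236 m ventrad
#> dimensionless craniad offset (per GA 0.355 m): 0.4822

# a knee muscle's moment-arm sweep vs its recorded closed form
cv <- mma_sweep(sk$model, "IT1", "knee", "z", seq(-60, 0, 5))
max(abs(cv$moment_arm_m - hinge_truth_moment_arm(sk, "IT1", cv$angle_deg)))
#> [1] 3.583018e-08

# published ROM fixture
model <- load_model(paleomech_example("riojasuchus_rom.yaml"))
rom_span(model, "ankle")
#> [1] 80
```

The synthetic skeleton's box-proxy segments are much lighter than a
fleshed-out reconstruction, so its 4.7 kg total is a property of the proxy
geometry, not an estimate for the animal; the shipped
`riojasuchus_summary.yaml` fixture carries the published whole-body values
(24.56 kg, COM 0.0986 m craniad / 0.0594 m ventrad of the acetabula).

A command-line wrapper ships in `inst/cli/paleomech`
(`paleomech allometric-mass --ch 39 --cf 66`, `mma-sweep`, `rom-scan`,
`com`, `biped-check`, `classify`, `mass-props`, `make-synthetic`).

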