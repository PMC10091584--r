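# ldrbm — Laplace-Dirichlet rule-based myocardial fiber generation

Organ-scale cardiac electrophysiology and mechanics simulations need the
myofiber architecture — the fiber **f**, sheet **s** and sheet-normal **n**
unit directions — at every point of the myocardial mesh, but fiber imaging is
rarely available for a given geometry. `ldrbm` generates these fields with
Laplace-Dirichlet Rule-Based Methods (LDRBMs) on labeled volumetric meshes of
ventricular and spherical slabs, based and complete left ventricles, and left
atria. It is aimed at cardiac-modeling practitioners who need a reproducible,
scriptable fiber-generation step in front of an electrophysiology or
mechanics solver.

## The method

On the myocardium Ω with labeled boundary Γ_endo ∪ Γ_epi ∪ Γ_base ∪ Γ_apex
(plus valve/vein rings where relevant):

1. solve −Δφ = 0 with φ = 1 on Γ_epi, φ = 0 on Γ_endo (homogeneous Neumann
   elsewhere); the unit transmural direction is ê_t = ∇φ/‖∇φ‖;
2. build an apico-basal field **k** by one of: the constant basal normal
   (Rossi-Lassila), the gradient of a base/apex harmonic potential ψ
   (Bayer-Trayanova), the Doste blend k = w∇ψ_ab + (1−w)∇ψ_ot for complete
   ventricles, or threshold-selected atrial bundle potentials;
3. form the orthonormal frame ê_n = (k − (k·ê_t)ê_t)/‖·‖, ê_l = ê_n × ê_t;
4. rotate ê_l about ê_t by the helical angle α(φ) = α_endo(1−φ) + α_epi φ
   and the transmural direction about the longitudinal axis by the sheetlet
   angle β(φ) (Rodrigues rotations, right-hand rule), yielding (f, n, s).
   Atrial runs use the unrotated frame directly.

Discretization is by degree-1 finite elements (P1 tetrahedra / Q1 hexahedra)
with a Jacobi-preconditioned conjugate-gradient solver; the pipeline is fully
deterministic. See the methods vignette
(`vignettes/ldrbm-methods.Rmd`) for the numerics and design choices.

## Worked example

Generate a structured ventricular slab (24 mm wall), run the slab LDRBM with
the physiological helical range, and inspect the transmural angle profile:

```r
library(ldrbm)

mesh <- make_slab(Lx = 0.024, Ly = 0.04, Lz = 0.04,
                  nx = 4, ny = 7, nz = 7, element_type = "hex")
cfg <- ldrbm_config("Slab",
                    tags = list(endo = 1L, epi = 2L, base_up = 3L, base_down = 4L),
                    alpha_endo = -60, alpha_epi = 60)
res <- generate_fibers(mesh, cfg)
res
#> LDRBM fiber field (Slab) on 320 vertices
#>   fields: phi, psi, f, s, n

range(helical_angle(res$fields$vectors$f, res$frame))
#> [1] -60  60
```

The helical angle runs from −60° on the endocardial face (φ = 0) to +60° on
the epicardial face (φ = 1), linearly in the transmural potential; on this
structured slab the discrete result matches the closed form to machine
precision. `write_fields(mesh, res$fields, "fibers.vtu")` writes a
ParaView-loadable file for streamline visualization.

Mesh sensitivity of the fiber field over a four-level refinement family:

```r
family <- mapply(function(nx, nyz) make_slab(0.024, 0.04, 0.04, nx, nyz, nyz, "hex"),
                 c(4, 7, 15, 31), c(7, 13, 27, 53), SIMPLIFY = FALSE)
sensitivity_study(family, cfg)
#> Mesh sensitivity of the fiber field (reference: finest level)
#>   i     h [mm]      #dofs avg dth [deg] max dth [deg]
#>   1      5.804        320       0.0840       0.1334
#>   2      3.190       1568       0.0155       0.0246
#>   3      1.520      12544       0.0016       0.0025
#>   4      0.761      93312           --           --
```

Each row compares that level's fiber field with the finest-level reference
through the angular error Δθ = |arccos(f_i · f_ref)|; both the average and
the maximum shrink monotonically under refinement and stay far below the
physiological fiber-dispersion scale even on the ~6 mm mesh.

## Command-line use

The parameter-file driven interface mirrors the functions:

```sh
Rscript exec/ldrbm_fibers -g full -f fibers.prm   # write defaults (prm or json)
Rscript exec/ldrbm_fibers -f fibers.prm -o out    # run; writes out/log_params.prm + out/<name>.vtu
Rscript exec/ldrbm_fibers -f fibers.prm -l conv.json -d   # validate + convert formats, no solve
```

Geometry-specific parameters live in a subsection named after the
`Geometry type` value; anything omitted takes its hard-coded default, and
every value is pattern-checked before any solve.

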