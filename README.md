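# gagstack

Trajectory-level analysis of methylene blue (MB) association with
glycosaminoglycans (GAGs), for structural bioinformaticians studying how a
cationic planar dye recognizes anionic polysaccharides.

MB is a tricyclic phenothiazine cation whose terminal dimethylamino
nitrogens carry the most positive charge; GAGs (heparin, heparan sulfates,
chondroitin sulfates) are linear polyanions whose sulfate and carboxylate
groups anchor electrostatic contacts. Simulation studies of these systems
rest on a handful of trajectory observables, all implemented here:

* detection of face-to-face **π–π stacks** (~3.7 Å inter-plane spacing,
  parallel/antiparallel long-axis orientations) and oligomer enumeration;
* **contact fractions** per anionic-site type at an 8 Å nitrogen–anchor
  cutoff, plus per-frame simultaneous-binder counts;
* the **sulfation-dependence statistic**

  $$D = \frac{n_\mathrm{MB} \times t}{n_{\mathrm{SO}_3}}$$

  (simultaneously bound dyes × time fraction per sulfate group; undefined
  for a desulfated chain);
* **MM-GBSA component bookkeeping**: frame filtering by bound count,
  per-drug normalization, and the additivity check
  ΔG = ΔG_vdW + ΔG_esurf + (ΔG_eel + ΔG_egb).

Because the underlying all-atom MD trajectories of such studies are rarely
deposited, the package ships a synthetic trajectory generator with two
modes: **scripted** (exact, per-frame ground truth for stacks, orientations
and bound states — every analysis stage is verified against it) and
**Monte Carlo** (rigid-body Metropolis with a minimal stacking-well +
screened-Coulomb potential, for mechanistic contrasts). Seven GAG
decasaccharide presets with exact anionic-site inventories are built in
(`HP`, `deHP`, `CS4`, `CS6`, `HS1`, `HS2`, `HS3`).

## Worked example

Generate the reference scripted scenario for heparin — two persistent
stacks of four and six dyes in contact with the chain for 42% of frames —
and recover its observables:

```r
library(gagstack)

scen <- reference_scenario("HP", n_frames = 100)
run  <- generate_scripted(scen)

stack_statistics(run$trajectory)
#> <stack_stats> 100 frames, 10 dyes
#>   mean adjacent spacing: 3.7 A (dimers only: NA A)
#>   modal component size: 4

glance(binding_summary(run$trajectory))
#> # A tibble: 1 × 6
#>    n_mb     t no_binding mb_count n_frames cutoff
#>   <int> <dbl> <lgl>         <int>    <int>  <dbl>
#> 1    10  0.42 FALSE            10      100      8

d_table(list(HP = binding_summary(run$trajectory)))
#> # A tibble: 1 × 7
#>   preset  n_mb     t n_so3     D D_rounded defined
#>   <chr>  <int> <dbl> <int> <dbl>     <dbl> <lgl>
#> 1 HP        10  0.42    15  0.28      0.28 TRUE
```

The stack detector reports the scripted sizes {4, 6} at exactly the 3.7 Å
spacing; the contact analysis finds all ten dyes bound simultaneously in
42% of frames; and the resulting D = 10 × 0.42 / 15 = 0.28 per sulfate.
`autoplot()` methods exist for the stack, contact and binding summaries,
and `run_pipeline(run_config("HP"))` writes the full TSV report bundle
(stacks, contacts, D table, surrogate energies, chain bending, manifest)
for one configuration. A thin command-line wrapper with `simulate`,
`stacks`, `contacts`, `dmetric`, `energetics`, `bending` and `run`
subcommands is installed at `inst/cli/gagstack.R`.

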