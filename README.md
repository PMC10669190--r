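# contactdof

Contact-based analysis of conformational ensembles of short capped
peptides — built for studying how covalent ligands reshape intrinsically
disordered regions (IDRs), such as the 21-residue segments around the
reactive cysteines (C406, C327, C240) of the androgen-receptor AF1 region.

IDRs have no single structure; what a ligand changes is the *ensemble*.
`contactdof` quantifies those changes with per-frame, per-residue
statistics:

* **Contact maps.** Residues j, k are in contact when any atom of j lies
  within a cutoff (4.2 Å, boundary inclusive) of any atom of k. A capped
  21-mer has 23 indexed units (ACE cap = internal index 1, central Cys =
  index 12), so each frame's symmetric binary map contributes
  n(n−1)/2 = 253 non-redundant **contact degrees of freedom**; ensemble
  means give contact heat maps.
* **Secondary structure.** A Kabsch–Sander style eight-state assignment
  (H, G, I, E, B, T, S, none) from the backbone H-bond electrostatic
  energy model (threshold −0.5 kcal/mol), aggregated to per-residue state
  fractions (the stacked-bar statistic).
* **Fragment-resolved ligand contacts.** For a cysteine-linked dual-ring
  ligand split into A-ring / B-ring / stem fragments, the percentage of
  frames each fragment contacts each residue — the per-residue
  specificity profile.
* **Embeddings.** Covariance PCA of contact vectors (deterministic sign
  convention, full variance bookkeeping) and a nonlinear projection
  (non-metric MDS) for cross-system conformation maps, fitted jointly on
  pooled ensembles.
* **Synthetic generator.** A seeded helix–coil sampler (two-state Markov
  chain with nearest-neighbour cooperativity, ideal-geometry backbone
  builder, optional fragment-labelled pseudo-ligand with a tunable
  contact bias) stands in for MD trajectories and provides ground truth
  for every statistic.

Everything is tibble-first and pipe-friendly, with `autoplot()` methods
for maps, stacked bars, profiles and embeddings, and `tidy()`/`glance()`
for fitted embeddings.

## Worked example

Analyse a helix-stable native system against a destabilised, B-ring-biased
liganded system (synthetic study conditions, 300 frames each):

```r
library(contactdof)

spec <- segment_spec(406)
spec
#> <segment_spec> 21-mer centred on position 406 (flank 10)
#>   sequence: AAAWAAAAAACAAAAAAAAAA
#>   indexed units incl. ACE/NME caps: 23
internal_index(c(399, 403, 406), spec)   # W399, A403, C406
#> [1]  5  9 12

cfg <- run_config(n_frames = 300, seed = 42, outdir = "readme_out")
cmp <- run_comparison(cfg, c("NTD_4H", "XNN_4H"))
cmp$report
#> # A tibble: 2 × 6
#>   notation n_frames helical_interior mean_contacts top_fragment_contact top_fragment_pct
#>   <chr>       <int>            <dbl>         <dbl> <chr>                           <dbl>
#> 1 NTD_4H        300            0.854          74.5 <NA>                               NA
#> 2 XNN_4H        300            0.430          52.7 B-ring@5                           59
```

The report reads directly: the unliganded control keeps a mean interior
helical fraction of 0.85, while the liganded system drops to 0.43 and
loses ~22 mean contacts per frame (the i,i+4 helical band thinning out);
its strongest ring-fragment contact is the B-ring at residue #5 — the
tryptophan position — in 59% of frames, matching the designed bias of
0.6. The per-residue profile shows the signature localised around the
target:

```r
res <- run_system(cfg, "XNN_4H")
dplyr::filter(res$profile, fragment == "B-ring", res_index %in% 4:6)
#> # A tibble: 3 × 4
#>   res_index seq_pos fragment contact_pct
#>       <int>   <int> <chr>          <dbl>
#> 1         4     398 B-ring          42.7
#> 2         5     399 B-ring          59
#> 3         6     400 B-ring          58.3

glance(attr(cmp$embedding, "fit"))   # pooled contact-vector PCA
#> # A tibble: 1 × 5
#>   total_var n_frames n_dof prop_var_PC1 prop_var_PC2
#>       <dbl>    <int> <int>        <dbl>        <dbl>
#> 1      13.0      600   253        0.576        0.122
```

All CSV artifacts (mean maps, state fractions, contact vectors, per-block
variants, profiles, embeddings) land in `outdir`, stamped with the seed
and a configuration hash. `autoplot(res$mean_map)`,
`autoplot(res$fractions)`, `autoplot(res$profile)` and
`plot_embedding(cmp$embedding)` draw the corresponding figures. A thin
command-line front end over the same functions is installed at
`inst/cli/contactdof-cli.R` (subcommands `generate`, `contacts`,
`secstruct`, `embed`, `fragments`, `run`, `compare`).

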