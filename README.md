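# pblipidr

Carbon–carbon double-bond (C=C) localization in unsaturated
glycerophospholipids from LC–MS/MS data acquired after online
Paternò–Büchi (PB) derivatization — with relative quantitation of C=C
location isomers and the statistics layer needed to screen isomer ratios as
biomarkers.

## The problem

Conventional shotgun or LC–MS/MS lipidomics identifies a phospholipid down to
its fatty acyl chains (e.g. PE 16:0_18:1) but is blind to *where* the double
bonds sit on those chains. Lipids identical in subclass and chain composition
but differing in C=C position — *C=C location isomers*, e.g. the Δ9 and Δ11
isomers of the 18:1 chain — are merged into one peak, yet their ratio can
shift with disease state even when total abundance does not.

The PB reaction solves this chemically: UV irradiation in acetone adds one
acetone (+58.0419 Da, C₃H₆O) across each C=C. Collision-induced dissociation
of the PB product cleaves at the former double-bond position and yields a
**pair** of diagnostic fragments — an aldehyde ion F_A and an olefin ion F_O,
always separated by 26.0157 Da (C₂H₂). For a bond at Δn on a chain with `c`
carbons,

    F_A = precursor − mass(C_m H_{2m−2k}) + mass(O) − NL,   m = c − n
    F_O = F_A + mass(C2H2)

where `k` counts the chain's other double bonds methyl-side of the cleavage
and `NL` is the subclass/polarity headgroup neutral loss (141.0191 Da
phosphoethanolamine loss for PE in positive mode; 0 for PC positive and the
negative-mode fatty-acyl bases). Observing both members of the pair pins the
position; the summed pair intensities of coexisting isomers give their
relative ratio, e.g.

    Rel. C_Δ9 / C_Δ11 = (I_467 + I_493) / (I_495 + I_521)

for PE 16:0_18:1.

`pblipidr` implements the complete data-analysis side of this workflow:

1. **Subclass profiling** from headgroup-linked scans (NLS 141 for PE,
   PIS 184 for PC in positive mode; PIS 153 for PG, PIS 241 for PI in
   negative mode), with retention-time windows separating isobars such as
   PE 39:4 / PC 36:4 (identical formula C₄₄H₈₀NO₈P).
2. **Chain assignment** from negative-mode MS/MS via fatty acyl carboxylate
   anions (m/z 255 for 16:0, 281 for 18:1, ...).
3. **PB target lists** using the signature +58 shift (intact `[M+H]+` basis
   for PE/PC; fatty-acyl-anion basis for PG/PI; `[M−H]−` for free acids).
4. **De novo C=C assignment** with pair-completeness, S/N, intensity-symmetry
   and ion-collision rules, and isomer relative quantitation.
5. **Biomarker statistics**: Student/Welch group comparisons with
   Benjamini–Hochberg FDR control, technical vs inter-individual RSD
   decomposition, and hierarchical clustering of sample × isomer-ratio
   matrices (Rand-index scored).
6. A **seeded simulator** of all three scan layers and of cohort tables,
   used by the test suite and the examples below.

Everything is tibble-in/tibble-out and pipe-friendly; results carry
`tidy()` / `glance()` methods and `autoplot()` displays. MGF (Mascot Generic
Format) is read and written natively.

## Worked example

```r
library(pblipidr)

# Theoretical diagnostic pair for the Delta-9 bond of PE 16:0_18:1
diagnostic_pairs("PE 16:0_18:1", "18:1", 9, "[M+H]+")
#>   position fa_mz    fo_mz    precursor_mz
#> 1        9 467.3731 493.3888     776.5799

# Simulate a bovine-liver-like lipidome and its three scan layers, then run
# the full pipeline
truth   <- generate_lipidome(24, seed = 7)
spectra <- simulate_run(truth, sim_params_noise_free(), seed = 7)
reports <- run_pipeline(spectra, fa_species = "FA 18:1")
reports$summary
#>   stage                value
#> 1 profile_hits            18
#> 2 species_annotated       18
#> 3 chains_resolved         17
#> 4 pb_targets              15
#> 5 species_cc_attempted    15
#> 6 species_cc_localized    15
#> 7 pct_localized          100

head(reports$ratio_summary[, c("lipid", "isomer_a", "isomer_b", "mean_ratio")], 4)
#>   lipid        isomer_a isomer_b mean_ratio
#> 1 FA 18:1      9        11           13.3
#> 2 PC 15:0_18:2 6,9      9,12          0.178
#> 3 PC 16:0_18:1 9        11            5.97
#> 4 PC 16:0_18:3 6,9,12   9,12,15       0.642
```

`pct_localized` is the percentage of species (with resolved chains and at
least one double bond) for which at least one chain received a C=C call; on
noise-free input it is 100 by construction. Each `mean_ratio` row is the
summed-diagnostic-ion ratio of two coexisting isomers (lower Δ set over
higher), e.g. FA 18:1 was simulated at a 9:1 Δ9:Δ11 mixture plus abundance
jitter.

The statistics layer shows the measurement-precision contrast that makes
isomer ratios attractive biomarkers:

```r
cohort <- simulate_cohort(seed = 20)   # 6 vs 6, 3 technical repeats
glance(hcluster(cohort, kind = "ratio"))$rand_index      # 1.00  (groups recovered)
glance(hcluster(cohort, kind = "subclass"))$rand_index   # 0.47  (not recovered)

tidy(compare_groups(cohort)) |> dplyr::arrange(p_value) |> head(3)
#>   lipid          kind  mean_1 mean_2  p_value    p_adjusted stars
#> 1 ratio_lipid_03 ratio   5.87   2.97  1.06e-06   4.12e-05   ***
#> 2 ratio_lipid_02 ratio   4.66   2.54  1.40e-05   2.74e-04   ***
#> 3 ratio_lipid_05 ratio   4.27   2.84  3.27e-05   4.26e-04   ***
```

Isomer-ratio measurements (biological CV ~10%) separate the groups cleanly;
subclass-level I/I_IS quantitation (biological CV ~40%) does not, at the same
sample size.

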