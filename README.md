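# regflux

Hierarchy-aware ranking of transcriptional regulators (TRs) as
overexpression or downregulation targets for overproducing a chosen
metabolite.

Strain design usually edits metabolic genes directly, but a single
transcriptional regulator can move a whole regulon at once. `regflux` is
for metabolic engineers who have (a) a genome-scale metabolic model
(SBML), (b) a signed transcriptional regulatory network (TRN; edge list of
regulator → target with activator/repressor sign), and (c) expression
intensities for a *producer* and a *non-producer* condition, and who want
a ranked list of TRs whose up- or downregulation should push flux toward a
product of interest.

## The method

1. **nRAP — reaction slopes.** For every gene-associated reaction *r*,
   flux variability analysis (under a growth constraint
   v<sub>biomass</sub> ≥ 0.5·v<sub>biomass</sub><sup>max</sup>) gives a
   feasible range [v<sub>min</sub>, v<sub>max</sub>]. The reaction flux is
   fixed at v<sub>min</sub> + k·(v<sub>max</sub> − v<sub>min</sub>) for
   k = 0, 0.1, …, 1 and the product flux v<sub>target</sub> is maximised
   at each point; nRAP<sub>r</sub> is the least-squares slope of
   v<sub>target</sub> against k. Positive slopes mark product-favouring
   reactions, negative slopes product-competing ones. An optional
   extension re-sweeps zero-scored reactions with one optimal-route
   reaction disabled, exposing alternative product routes.
2. **nGAP — gene scores.** Each slope is distributed over the reaction's
   genes through its GPR rule: nGAP<sub>jr</sub> = nRAP<sub>r</sub> /
   GPRf<sub>j</sub>, where the GPR factor of a gene doubles with each
   additional subunit of a complex (`and`) and is unchanged across
   isozymes (`or`).
3. **nRS — regulatory strengths.** For each TRN edge *i → j*,
   nRS<sub>ij</sub> = ((Gene<sub>j,prod</sub> − Gene<sub>j,n-prod</sub>) /
   (TR<sub>i,prod</sub> − TR<sub>i,n-prod</sub>)) ·
   (TR<sub>i,n-prod</sub> / Gene<sub>j,n-prod</sub>) — the ratio of
   relative expression changes. Edges whose sign contradicts the curated
   activator/repressor annotation are removed.
4. **TRE and the randomization filter.** TRE<sub>i</sub> = Σ
   nRS<sub>ij</sub>·nGAP<sub>jr</sub> over the TR's metabolic regulon.
   Each TRE is screened against ~1000 random nRAP assignments drawn
   uniformly from the observed range; a TR passes when fewer than 5% of
   random scores land within ±10% of its actual TRE.
5. **gTRE — hierarchical propagation.** TR–TR edges (self-loops and
   feedback cycles excluded) define a layered hierarchy; scores propagate
   bottom-up: gTRE<sub>i</sub> = TRE<sub>i</sub> + Σ
   nRS<sub>ic</sub>·gTRE<sub>c</sub> over regulated TRs *c*. TRs are
   ranked by gTRE: high positive → overexpress, high negative →
   downregulate.

## Worked example

The package ships a self-contained nine-reaction toy instance (uptake, a
three-step product pathway, a two-step biomass pathway, a competing
drain) with a seven-TR TRN and consistent synthetic expression:

```r
library(regflux)

paths <- write_toy_instance(toy_instance(1), "demo")
cfg <- run_config(model = paths$model, trn = paths$trn,
                  expression = paths$expression,
                  biomass_id = "R_bio", target_id = "EX_P", seed = 1)
res <- run_pipeline(cfg)
tidy(res)
#> # A tibble: 7 × 8
#>   tr    level    tre     q significant   gtre  rank direction
#>   <chr> <int>  <dbl> <dbl> <lgl>        <dbl> <int> <chr>
#> 1 tA        3  10.00 0.004 TRUE         10.00     1 upregulate
#> 2 tM        2   0    1     FALSE         7.50     2 upregulate
#> 3 tG        1   0    1     FALSE         3.75     3 upregulate
#> 4 tC1       1   1.25 0.049 TRUE          1.25     4 upregulate
#> 5 tR        1  -2.50 0.057 FALSE         0        5 neutral
#> 6 tC2       1   0    1     FALSE         0        6 neutral
#> 7 tD        3 -10.00 0.002 TRUE        -10.00     7 downregulate
```

The planted product-pathway activator `tA` ranks first (gTRE +10: its
three regulon genes carry positive product-flux slopes), and the
drain/biomass activator `tD` ranks last (−10). `tM` and `tG` have no
metabolic regulon of their own (TRE = 0) but inherit scores from `tA`
and `tD` through the hierarchy — the point of the gTRE propagation. The
repressor `tR` fails the randomization filter here (q = 0.057 ≥ 0.05), so
its own effect is zeroed. `autoplot(res)` draws the ranking;
`plot_nrap_sweep(res$rap, "R_p2")` shows the 11-point sweep behind one
slope.

GPR factor arithmetic, on the classic isozyme/complex rule:

```r
gpr_factors(parse_gpr("(A and (B or (C and D))) or E"))
#> A B C D E
#> 2 2 4 4 1
```

Prediction-evaluation metrics from literature-mined TP/FP/FN counts:

```r
classification_metrics(17, 2, 10)
#> # A tibble: 1 × 9
#>      tp    fp    fn   tpr   ppv   fnr   fdr    f1 fp_fn
#> 1    17     2    10  0.63 0.895  0.37 0.105 0.739   0.2
```

A command-line front end with `run` and `fixtures` subcommands is
installed at `inst/cli/regflux.R`.

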