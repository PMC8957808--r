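# socialfear

Social avoidance in rodents emerges from an interplay between cortical and
subcortical structures: the ventrolateral ventromedial hypothalamus (VMHvl)
houses antagonistic threat and social-interaction populations, the dorsal
periaqueductal gray (dPAG) triggers the avoidance behaviour itself, and the
medial prefrontal cortex (mPFC) acts as a brake on that output while the
mediodorsal thalamus (MDT) supplies its plastic drive. `socialfear` is a
deterministic firing-rate simulator of this circuit for computational and
behavioural neuroscientists: it implements the published system-level model
of social fear conditioning and extinction, the in-silico
lesion/stimulation experiments that validate it, and the testable
predictions it generates.

Each unit is a leaky rate node

    tau * dV/dt = -V + I + sum_pre w(post,pre) * F(V_pre),   F(V) = [tanh(V)]+

integrated by the Euler method (500 steps per trial), with selected
connections learning under a simplified Bienenstock–Cooper–Munro rule

    dW = alpha * (F_post - theta) * F_pre

clipped to per-edge `[w_min, w_max]` bounds. Activity of the output unit
`dPag1` is the model's social-avoidance index. The three-phase protocol —
one baseline trial, three conditioning trials pairing conspecific + context
with a defeat input, eleven extinction trials — reproduces conditioning,
gradual extinction, and the fear / extinction / persistent unit classes
known from fear-conditioning physiology.

Two circuit variants ship with the package: the 16-unit main model and an
alternative 17-unit model in which the lateral septum (LS) sends inhibition
onto the VMHvl threat unit, moving part of extinction into the
hypothalamus.

## Worked example

```r
library(socialfear)

net <- build_basic_model()
net
#> <sfc_network> 16 units, 24 connections (9 plastic)
#> areas: MeA, vHIP, lPBN, MDT, VMHvl, mPFC, dPAG
#> input channels: conspecific -> MeA; context1 -> Hip1; context2 -> Hip2; defeat -> lPBN+Som1
#> plasticity: alpha = 5e-04, theta = 0.5

res <- run_protocol(net)   # baseline -> conditioning -> extinction
res
#> <sfc_result> 15 trials x 500 steps, 16 units
#> phases: baseline -> conditioning -> extinction
#> avoidance index (dPag1 trial means):
#>     baseline conditioning conditioning conditioning   extinction   extinction
#>        0.000        0.800        0.807        0.811        0.559        0.560
#>   extinction   extinction   extinction   extinction   extinction   extinction
#>        0.561        0.560        0.433        0.142        0.031        0.006
#>   extinction   extinction   extinction
#>        0.003        0.001        0.001
```

The baseline is quiet (avoidance index 0.000 < 0.1), the defeat trials
recruit the dPAG (≈ 0.80), and re-exposure extinguishes avoidance
gradually — the index first drops below the 0.1 threshold on extinction
trial 7 (`trials_to_extinction(res)`). Responsiveness at the first versus
last extinction trial sorts the populations into the published classes:

```r
classify_units(res, c("Pyr1", "Pyr2", "Hyp1"))
#>   unit      class responsive_post_conditioning responsive_post_extinction
#> 1 Pyr1       fear                         TRUE                      FALSE
#> 2 Pyr2 extinction                        FALSE                       TRUE
#> 3 Hyp1 persistent                         TRUE                       TRUE
```

In-silico experiments are one call each. Blocking the prefrontal
projection to the dPAG induces avoidance in a never-conditioned animal:

```r
reproduce_experiment("franklin_pyr2_block")
#> $name   : "franklin_pyr2_block"
#> $pass   : TRUE
#> $metrics$dpag_blocked : 0.194     # avoidance with the brake removed
#> $metrics$dpag_control : 0.000175  # same exposure, brake intact
```

`reproduce_experiment()` also covers VMHvl silencing, Pv stimulation, Som
inhibition and context re-exposure; `run_prediction()` covers the
plasticity-freeze, lPBN-silencing, Pyr2-stimulation, MDT HFS/LFS and
LS-scaling experiments; `sensitivity_sweep()` rescales every connection
over a 0–2 grid and reports the tolerated range per edge.

A command-line interface wraps the same entry points
(`inst/cli/socialfear`):

```sh
Rscript inst/cli/socialfear simulate --model basic --out out/
Rscript inst/cli/socialfear reproduce franklin_pyr2_block
Rscript inst/cli/socialfear check
```

Network and run configurations are plain YAML (`inst/extdata/*.yaml`,
`load_network()`, `load_config()`); results export to long-format CSV and
a JSON summary stamped with a configuration digest (`write_result()`).

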