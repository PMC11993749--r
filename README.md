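# stoichbench

Benchmarking tools for **site-level RNA modification stoichiometry calling**
from direct RNA sequencing.

Nanopore direct RNA sequencing detects chemically modified nucleosides (m6A,
m5C, pseudouridine) as current anomalies, and a growing family of callers
estimates, per reference position, the *stoichiometry* — the fraction of
reads carrying the modification. Comparing such callers requires three
things this package provides:

* **challenge references** containing every k-mer with a fixed central
  target base (for k = 5: 256 5-mers concatenated gap-free into a 1280 nt
  core), so every sequence context of the modification is represented;
* **datasets with known truth**: simulated mixtures of fully modified and
  unmodified read pools with known per-position rates, controlled binomial
  count simulation, an 80/20 train/test read split, and a perturbation model
  that turns truth into method-like predictions;
* **a common format and metric suite**: parsing/writing/validation of the
  bedRMod site-level format (BED9+2 dialect, 0-based half-open coordinates),
  ground-truth rate estimation `n_mod / (n_mod + n_unmod)` from two mapped
  read pools, and scoring with RMSE, MAE, median absolute error, the
  min/max deviation range on modified positions, and accuracy/F1 under a
  tolerance rule (true positive = prediction within ±1 base and within
  Y ± 0.6·Y of the target frequency Y):

  RMSE = sqrt(1/N · Σ (Y − Ŷ)²)  MAE = 1/N · Σ |Y − Ŷ|
  Acc = (TP + TN)/N              F1 = 2·TP / (2·TP + FP + FN)

Three packaged challenge profiles place 243 modified positions on a 2438 nt
reference: `challenge1` (m5C, rates 0.12–0.33), `challenge2` (m6A,
0.01–0.1), `challenge3` (psi, 0.31–0.5).

## Worked example

Simulate a challenge-1 truth, degrade it into a method-like prediction, and
score the pair:

```r
library(stoichbench)

prof  <- challenge_rate_profile("challenge1", seed = 1)
truth <- profile_truth_records(prof, coverage = 100L)
pred  <- perturb_truth(truth, pos_jitter_prob = 0.05, freq_noise_sd = 0.02,
                       fp_rate = 0.002, fn_rate = 0.02, seed = 2,
                       reference_length = prof$length)
evaluate_predictions(truth, pred, reference_length = prof$length)
#> Evaluation over 2438 positions (243 truth, 241 predicted sites)
#>   RMSE 0.03703 | MAE 0.006195 | median AE 0
#>   deviation range [6.426e-05, 0.3285]
#>   accuracy 0.9967 | F1 0.9835  (TP 238 TN 2192 FP 3 FN 5)
```

Reading the output: RMSE and MAE average the frequency error over all 2438
positions (zeros filled in where nothing is modified or predicted), so the
handful of dropped/jittered sites dominates them; the deviation range is the
absolute-error span on the 243 modified positions; 238 of 243 truth sites
were matched within the ±1 base / ±60 % frequency tolerance (TP), 5 were
missed (FN), and 3 spurious sites landed at unmodified positions (FP),
giving accuracy 0.9967 and F1 0.9835.

A shell entry point wrapping the same functions ships in
`inst/cli/stoichbench` (subcommands `design-ref`, `simulate`, `rates`,
`split`, `perturb`, `evaluate`, `validate`; run it without arguments for
usage).

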