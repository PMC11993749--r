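---
title: "Benchmarking site-level RNA modification stoichiometry calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking site-level RNA modification stoichiometry calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichbench)
```

## The problem

Direct RNA sequencing on nanopore devices reads native RNA, so chemically
modified nucleosides (N6-methyladenosine, 5-methylcytosine, pseudouridine)
leave detectable anomalies in the raw current. A growing family of callers
turns those anomalies into *site-level stoichiometry* estimates: for each
reference position, the fraction of reads carrying the modification. Methods
differ wildly in pipeline structure, and their outputs are only comparable if
(a) they are run against data with *known* per-position modification rates
and (b) they are scored with one agreed metric suite on one agreed file
format.

`stoichbench` provides the benchmarking side of that arrangement:

* **reference design** — synthetic references containing every k-mer around
  the target base, so that every sequence context of the modification is
  represented exactly once;
* **dataset simulation** — mixtures of fully modified and unmodified reads
  with known per-position rates, a train/test split, and controlled noise
  models for generating method-like predictions;
* **rate estimation** — the ground-truth computation itself: per-position
  pileup of two separately tracked read pools and the modification ratio;
* **bedRMod I/O** — parsing, writing and validating the site-level exchange
  format;
* **evaluation** — the metric suite used to rank submissions.

## The reference design

A k-mer-exhaustive reference for central base $b$ concatenates all $4^{k-1}$
k-mers with $b$ at the centre, without gaps. With $k = 5$ that is 256 blocks
and a 1280 nt core; the modifiable position of block $i$ (0-based) sits at
$5i + 2$ plus the 5' flank length. Because the concatenation is gap-free,
sliding a 5 nt window at stride 5 recovers each designed 5-mer exactly once —
this is the invariant the test suite checks exhaustively.

The packaged challenge layouts use a 2438 nt reference with 243 modified
positions. A bare 5-mer core would give 1280 nt and 256 positions, so the
packaged geometry attaches 579 nt flanks on each side
($579 + 1280 + 579 = 2438$) and drops 13 of the 256 blocks from the target
list (deterministically, at 13 evenly spaced block indices), emulating
target-coverage dropout. This geometry is a configuration choice of this
package: the discrepancy between the naive core and the published layout is
not explained by any mechanism we could model, so we chose the most
transparent configuration that reproduces the published counts. k-mer order
is lexicographic by default with an optional seed-shuffled order; flanks are
a deterministic periodic ACGT sequence.

## Simulation model

Two simulation modes are provided, both operating at the read/alignment
abstraction. Raw-signal emulation (fast5/POD5, basecalling error structure)
is deliberately out of scope: every computation downstream of basecalling —
rate estimation, format handling, scoring — is exercisable at this level, and
that is the level at which this package makes claims. Passing tests therefore
demonstrate correctness of the benchmarking arithmetic, not robustness of any
caller to raw-signal artefacts.

**Controlled-rate mode.** Each profiled position $p$ with true rate $r_p$
receives $n_{\mathrm{mod}}(p) \sim \mathrm{Binomial}(c, r_p)$ modified reads
out of a fixed coverage $c$; unprofiled positions are purely unmodified. This
is the mode used to test the rate estimator: at coverage $c$ the estimate
$\hat r_p$ should lie within $4\sqrt{r_p(1-r_p)/c}$ of $r_p$ for essentially
all positions (a 4-standard-error binomial bound).

**Transcript-mixture mode.** A pool of fully modified and a pool of
unmodified transcripts are mixed. Direct RNA sequencing proceeds 3'→5', so
reads retain the full 3' end while the 5' start is truncated; we model the 5'
start offset as geometric with configurable mean. Truncation makes the
emergent per-position mixing ratio vary along the reference, qualitatively
mimicking the position-dependent target rates seen in real challenge data.
The geometric model is a stand-in, not a claim about the mechanism in the
real datasets.

**Rate profiles.** The three packaged profiles draw 243 per-position rates
uniformly from the published ranges — `challenge1` (m5C) 0.12–0.33,
`challenge2` (m6A) 0.01–0.1, `challenge3` (psi) 0.31–0.5 — with *endpoint
anchoring*: the lowest-coordinate modified position is pinned to the range
minimum and the highest to the maximum, so the profile's extremes equal the
nominal endpoints exactly.

**Prediction perturbation.** `perturb_truth()` turns a truth table into a
method-like prediction: per-site dropout (false negatives), ±1 position
jitter, Gaussian frequency noise clipped to $[0,1]$, and spurious sites at
unmodified positions (false positives). With all parameters zero it is the
identity, which anchors the evaluator's perfect-score identities.

## Ground-truth rate estimation

With two separately mapped pools, the per-position modification ratio is

$$ r(p) = \frac{n_{\mathrm{mod}}(p)}{n_{\mathrm{mod}}(p) + n_{\mathrm{unmod}}(p)}, $$

the fraction of covering reads that come from the modified pool. We commit to
this fraction (rather than, say, the odds $n_{\mathrm{mod}}/n_{\mathrm{unmod}}$)
because target frequencies are fractions in $[0,1]$ by definition.
Zero-coverage positions yield *no* rate rather than rate 0 — "unobserved" and
"unmodified" are different statements — and the bedRMod exporter applies a
minimum-coverage gate (default 10 reads) before reporting a site. Pileup uses
run-length interval coverage; an independent per-position membership scan
serves as the test oracle.

## The metric suite

Let $Y_p$ be the target frequency at position $p$ (0 at unmodified
positions) and $\hat Y_p$ the prediction (0 where nothing was predicted),
over all $N$ evaluable reference positions. The error metrics are

$$ \mathrm{RMSE} = \sqrt{\tfrac1N \sum_p (Y_p - \hat Y_p)^2}, \qquad
   \mathrm{MAE} = \tfrac1N \sum_p |Y_p - \hat Y_p|, $$

plus the median absolute error (lower median for even $N$), and the
maximum/minimum absolute deviation restricted to the modified positions
($Y_p > 0$), which give the error range on the predicted modification
frequencies.

Classification metrics use a tolerance rule: a prediction is a true positive
for a modified position with target $Y$ if it lies within ±1 base of the
position *and* its frequency falls within $Y \pm 0.6\,Y$. At unmodified
positions a prediction is correct exactly when it is absent or exactly 0.
Then

$$ \mathrm{Accuracy} = \frac{TP + TN}{N}, \qquad
   F_1 = \frac{2\,TP}{2\,TP + FP + FN}. $$

Three points the formulas leave open are fixed explicitly:

* **Which positions enter RMSE/MAE.** All $N$ positions, with zeros filled
  in, and *strict* positional pairing (no ±1 window); the tolerance applies
  only to TP/TN classification. Deviation extremes are computed on modified
  positions only, which is consistent with published minimum deviations far
  below any plausible modified-position error.
* **Multiple candidates within the window.** Matching is one-to-one and
  TP-maximising (augmenting-path bipartite matching), so a single prediction
  can never be counted against two truth sites. Candidate edges are explored
  in order of positional offset, then leftmost site, predictions left to
  right: the result is deterministic and biased toward the smallest total
  offset, though cardinality — the only quantity entering the metrics — is
  the exact maximum (verified against exhaustive enumeration in the tests).
* **$F_1$ at $0/0$.** With $TP = FP = FN = 0$ (empty truth-free agreement)
  $F_1$ is defined as 1; with $TP = 0$ and any error it is 0.

False positives are unmatched predictions with frequency $> 0$ at positions
whose target rate is 0; $TN$ fills the remainder so that
$TP + TN + FP + FN = N$ always.

## The bedRMod dialect

bedRMod is a BED-derived tab-delimited format with a `#key=value` metadata
header and one row per modified site. The full external specification is not
reproduced field-for-field; this package fixes an 11-column BED9+2 dialect —
`chrom start end mod_name score strand thickStart thickEnd itemRgb coverage
frequency` — with 0-based half-open coordinates throughout. The frequency
column stores a decimal fraction in $[0,1]$; because the format is also used
in the wild with an integer percent column, the parser additionally accepts
values in $(1,100]$ and divides them by 100. The score column mirrors the
frequency as $\mathrm{round}(1000\,f)$ (halves away from zero), and writer
and validator enforce the mirror. Files written by `write_bedrmod()` are
canonical: records sorted by `(chrom, start)`, frequencies formatted with six
significant digits, so parse → write is byte-stable. Parsing never silently
drops a row — every malformed row becomes an error issue with its line
number — and a missing header is a warning, not a failure.

## Numerical and design choices

* **Rounding.** The train/test split size is `round(train_frac * n)` with
  halves away from zero (so 5 reads at 0.8 give 4/1); the same rounding backs
  the score/frequency mirror.
* **Seeding.** Every stochastic operation takes an explicit integer seed and
  is bit-reproducible under it; seeds are scoped locally so library calls do
  not perturb the caller's RNG stream. The command-line interface defaults to
  seed 1 and logs its resolved configuration.
* **Degenerate inputs.** Zero-coverage positions have no rate; empty read
  tables split into two empty tables; an empty prediction set is evaluable
  (all truth sites become false negatives); an empty truth set is rejected,
  as no metric in the suite is defined without expected values.
* **Problem sizes.** The test suite verifies the evaluator against an
  exhaustive matching oracle on 1000 random fixtures of up to 6 truth and 6
  prediction sites on a 40 nt reference — small enough for exact enumeration,
  large enough to hit every matching topology — and runs the controlled-rate
  recovery at coverage 20,000 over the full 2438 nt challenge geometry.

## Limitations

* The simulators do not model basecalling or alignment error, k-mer-dependent
  signal confusability, or coverage biases beyond geometric 5' truncation;
  conclusions about caller rankings on real data cannot be drawn from these
  synthetic fixtures alone.
* The published method-level metric values cannot be recomputed here: doing
  so would require the original raw-signal datasets and the participants'
  prediction files. What the package reproduces is the benchmark's design
  arithmetic (reference geometry, rate ranges, split fractions) and the exact
  behaviour of its metric suite.
* The matching tie-break among equally sized matchings prefers, but does not
  prove, minimal total positional offset.
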