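---
title: "Staged neural-network classification of b-/y-ion peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged neural-network classification of b-/y-ion peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

De novo peptide sequencing reads a peptide's sequence directly from the mass
differences between fragment-ion peaks in its tandem (MS/MS) spectrum. Under
collision-induced dissociation (CID) a doubly charged tryptic peptide of $n$
residues ideally yields two ion ladders: the N-terminal prefixes $b_1 \dots
b_{n-1}$ and the C-terminal suffixes $y_1 \dots y_{n-1}$, with

$$b_i = \sum_{j \le i} m_j + m_\mathrm{proton}, \qquad
  y_i = \sum_{j > n - i} m_j + m_{\mathrm{H_2O}} + m_\mathrm{proton},$$

so that complementary pairs satisfy $b_i + y_{n-i} = M + 2\,m_\mathrm{proton}$,
where $M$ is the peptide's monoisotopic mass. Real spectra bury these ladders
in isotopologue satellites, neutral-loss satellites, other ion series,
internal fragments and chemical noise. Because every retained peak feeds the
downstream spectrum graph, whose candidate-peptide space grows exponentially
with its edge count, the initial selection of probable $b$/$y$ peaks
dominates both the accuracy and the cost of sequencing.

`peakstage` implements a two-stage ("staged") feedforward neural network that
assigns each peak a posterior probability of being a $b$-ion, a $y$-ion or an
unknown ($u$) ion, together with the labelling protocol used to build
training targets, the sliding-window intensity baseline, and the
spectrum-graph machinery used to measure the induced search space.

## Ground-truth labelling

For spectra with known peptides, each peak within 0.2 Da of a theoretical
$b$/$y$ mass receives that label; everything else is $u$. Matches are taken
at face value — no deisotoping or charge-state checking — because the labels
serve as training targets, not identifications. Two conventions resolve
ambiguities the protocol itself leaves open:

* when several peaks fall inside one tolerance window, only the closest in
  mass takes the label (ties go to the more intense peak), preventing one
  theoretical ion from inflating the positive class;
* a peak inside both a $b$ and a $y$ window takes the closer of the two.

The 0.2 Da window is symmetric (±0.2 Da). Only singly charged fragments of
doubly charged precursors are modelled.

## The feature stack

Features are computed per peak $I_i$ with mass $x_i$ and intensity $y_i$; $pI$
denotes the singly protonated precursor mass MH⁺. Offset-based features share
one primitive: given an expected offset $\delta$ and tolerance
$\varepsilon = 0.2$ Da, the *offset peak* $I_j$ is the maximum-intensity peak
in $[x_i + \delta - \varepsilon,\, x_i + \delta + \varepsilon]$, with
experimental offset $\delta' = x_i - x_j + \delta$ and relative intensity
$y'_j = y_j / y_i$.

Stage 1 (`net1`) uses 18 inputs:

| feature | definition |
|---|---|
| intensity | $\lfloor n\, y_i/y_\mathrm{max} \rfloor / n$, $n = 10$ bins |
| strong peak | 1 if among the top 3 intensities within a 56 Da window |
| local / global rank | intensity rank mapped to $[0,1]$, window resp. spectrum |
| position (5 slots) | one-hot region of $x_i / pI$ in fifths |
| random peak | $1 - e^{-2\varepsilon\lambda}$, $\lambda$ = peaks per Da |
| principal isotope | log-odds of the $(\delta', y')$ bin of the +1 Da satellite |
| isotopologue | 1 if a peak $\ge y_i$ sits 1.00335 Da below |
| complement | $X(\delta_c)$, Gaussian score at $pI - x_i + m_\mathrm{proton}$ |
| five neutral losses | $y'_j + X(\delta')$ at $-$H₂O, $-$NH₃, $-2$H₂O, $-$H₂O$-$NH₃, $-$CO |

where $X(d) = \exp(-d^2 / 2\sigma^2)$ with $\sigma = 0.1$ Da, normalised to 1
at zero offset so every offset feature is bounded — a probability *score*,
not a density, which would exceed 1 at this $\sigma$.

The principal-isotope histogram is rebuilt from each training set: for every
labelled peak whose +1.00335 Da offset peak exists, the $(\delta', y')$ pair
increments a 0.05 Da × 0.1 grid ($\delta' \in [-0.2, 0.2]$, $y' \in [0, 2]$
with edge-bin clamping), separately for $b$/$y$ and $u$ peaks. The feature is
the elementwise log-odds $\log\frac{n_{by} + 1}{n_u + 1}$; the pseudocount
keeps it finite everywhere.

Stage 2 (`net2`) keeps the same features but replaces the complement score
with the best stage-1 evidence $\max(P_b, P_y)$ among peaks at the expected
complement mass, and appends two flanking features: the best stage-1 $b/y$
probability of any peak exactly one residue mass (±0.25 Da) below (N-side)
or above (C-side) the current peak. These leverage the defining property of a
true ladder peak — its neighbours are also ladder peaks — which a single
spectrum-only pass cannot express.

### The random-peak hypothesis

The feature list includes a "random peak hypothesis" slot with no published
defining formula. We fill the gap with the natural null model: the
probability that a homogeneous Poisson spectrum of the observed density
$\lambda$ would place at least one peak in a ±$\varepsilon$ window,
$1 - e^{-2\varepsilon\lambda}$. It is constant within a spectrum and tells
the network how much chance coincidence its offset features carry. Setting
`random_peak_enabled = FALSE` in `snn_control()` forces the slot to zero.

## Networks and training

Each stage is a 3-layer perceptron — inputs, one sigmoid hidden layer of
twice the input width, three sigmoid outputs — trained by per-instance
stochastic gradient descent (learning rate 0.1, momentum 0.9, seeded
shuffling) on the summed per-node binary cross-entropy

$$E = -\sum_{i=0}^{2} \big[ t_i \log o_i + (1 - t_i) \log(1 - o_i) \big].$$

Outputs are independent sigmoids rather than a softmax because this objective
is the per-node binary form, whose conjugate link is the sigmoid; the three
estimates are renormalised to sum to one only for reporting. Weights start
uniform $(-0.5, 0.5)/\sqrt{\text{fan-in}}$, biases at zero.

Training spectra are split 95/5 at the spectrum level into a backpropagation
set and a validation set. The backpropagation instances are rebalanced to
equal counts of $b$, $y$ and $u$ peaks (the $u$ multiplier is exposed as
`balance_ratio` because the class mix steers the precision/recall balance:
more $u$ raises precision and lowers recall). After every epoch the
validation *misclassification* rate (argmax vs argmax) is computed; at the
first epoch it worsens, training stops and the previous epoch's weights are
restored — one-epoch patience, with restoration chosen deliberately since
the worsened weights are the ones the rule rejects.

The staged protocol trains `net1`, classifies the full training set with it,
builds the stage-2 features from those estimates, and trains `net2` on the
same split membership (only the features change, matching the single
train/validation set named by the protocol). At prediction time stage-1
probabilities are recomputed per spectrum — the only reading possible for
unseen data.

```{r, eval = FALSE}
library(peakstage)
sim <- simulate_spectra(sim_config(n_spectra = 200, seed = 1))
fit <- snn_fit(sim$spectra, seed = 1)
pred <- predict(fit, simulate_spectra(sim_config(n_spectra = 50, seed = 2))$spectra)
```

## Selection, evaluation and the spectrum graph

The default decision rule selects a peak when $\max(P_b, P_y) > P_u$; a
threshold rule on the renormalised $b/y$ probability is available, though the
precision/recall balance is properly steered through `balance_ratio`, which
is how the classifier itself was designed to be tuned. Precision and recall
are micro-averaged (summed confusion counts) within peptide-length bins;
undefined ratios are reported as `NA`, never as zero. The sliding-window
baseline — top 3 peaks per 56 Da window — is the standard intensity-only
comparison.

Spectrum graphs measure the candidate space a selection implies. Nodes are
putative prefix masses: the proton-mass anchor $b_0$, the full-length prefix
$pI - m_{\mathrm{H_2O}}$, each selected peak read as a $b$-ion, and each
selected peak read as a $y$-ion ($pI - x + m_\mathrm{proton}$). Nodes closer
than the 0.5 Da edge tolerance are merged greedily in mass order. Edges join
nodes whose difference matches a residue mass ±0.5 Da, annotated with every
matching residue; isoleucine is reported as leucine since the two are
isobaric. Candidate peptides are enumerated depth-first from anchor to
terminus, capped (default $10^6$) with an explicit truncation flag because
the space is exponential in the edge count; the enumeration is verified in
the tests against an independent matrix-power path counter.

A note on the terminal node: the full-length prefix sits one water below
$pI$. Anchoring the terminus at $pI$ itself would make the final ladder hop
a residue mass *plus* water, so no path could ever spell a peptide; the
$pI - m_{\mathrm{H_2O}}$ convention is the one under which a complete
$b$-ladder spells its peptide exactly.

## The synthetic-spectrum simulator

No public benchmark ships with this package, so every end-to-end property is
established on simulated spectra whose generative model mirrors the
regularities the features exploit: random peptides of 8–20 residues (the
doubly charged tryptic range the method targets), per-ion ladder emission,
+1 Da isotopologue satellites with near-zero mass offsets, neutral-loss
satellites at the five configured offsets, and uniform-mass noise with
right-skewed (exponential) intensities.

Defaults were fixed once, before any end-to-end measurement, at values
typical of ion-trap CID spectra:

* ladder completeness 0.85 — most, not all, cleavage sites yield observable
  ions; gaps are the norm in real data;
* fragment intensities log-normal (median 500, $\sigma_{\log} = 1$, floor
  60) — intensities span about two orders of magnitude, so weak true
  fragments routinely lose intensity-rank contests, which is precisely the
  failure mode of the window baseline;
* isotope satellites present with probability 0.9, relative intensity
  $\mathcal N(0.4, 0.1)$ clipped to $[0.15, 0.9]$, offset jitter 0.01 Da;
* noise density 0.05 peaks/Da over $[50, pI]$ with exponential mean 80, so
  roughly half of the noise falls below the raw-intensity prefilter floor of
  50 — matching the prefilter's documented intent;
* fragment mass jitter 0.01 Da (clamped at ±0.15 Da).

Two structural guarantees keep the labelling oracle exact: peptides are
resampled until all theoretical ladder masses are at least 0.6 Da apart, and
noise peaks and satellites are kept at least 0.3 Da from every theoretical
ladder mass. Every peak therefore has an unambiguous truth tag at the 0.2 Da
labelling tolerance, and the label/truth agreement the tests assert is exact
rather than approximate.

What the simulator does *not* model — mobile-proton chemistry, doubly
charged fragments, internal fragments, correlated noise, detector
saturation — bounds what passing tests show: they validate the
implementation and the staging mechanism under the stated statistical
structure, not instrument-grade performance. Results on real spectra depend
on how far those assumptions hold.

## Numerical choices and degenerate inputs

* Monoisotopic residue masses, proton 1.007276 Da, water 18.010565 Da,
  ¹³C–¹²C spacing 1.00335 Da; all compiled into one constants table.
* The complement relation is implemented as $pI - x + m_\mathrm{proton}$
  (the exact $b/y$ arithmetic) rather than the rounded $pI - x + 1$;
  `comp_offset` is configurable, and at $\sigma = 0.1$ Da the 0.007 Da
  difference is immaterial.
* Offset search tolerance $\varepsilon$ defaults to the labelling tolerance
  0.2 Da; the local-rank window reuses the only published window width,
  56 Da (total width, i.e. ±28 Da).
* Intensity-rank ties break toward the lower-mass peak, making every
  rank-based feature deterministic.
* Network outputs are clipped to $[10^{-12}, 1 - 10^{-12}]$ inside the
  objective; gradients pass through unclipped outputs.
* Empty spectra flow through every stage as empty results, never errors; a
  spectrum whose maximum intensity is zero is rejected as degenerate.
* All randomness (initialisation, shuffling, splitting, balancing,
  simulation) derives from explicit seeds; refitting with the same seed
  reproduces the serialised model byte for byte. Model JSON uses 17
  significant digits so save → load → predict is bit-identical.

## Problem sizes

The test suite and the acceptance script run the pipeline at 200 training
and 100 evaluation spectra (roughly 10⁴ classified peaks), sizes at which
every property of interest — the staging recall benefit, the precision of
the selected set, the edge-count reduction against the window baseline — is
stable across seeds; the staging comparison is averaged over 20 seeded
runs. These are the package's documented benchmark sizes for reproducing
its own figures of merit.

## Limitations

* Only doubly charged precursors with singly charged $b$/$y$ fragments are
  modelled; other charge states pass through as $u$ ions at best.
* Modified residues, a/c/x/z ions and internal fragments are never labelled
  as positive classes.
* The candidate enumerator is a measurement device for the search space, not
  a sequencing engine: no scoring, reranking or I/L / K/Q disambiguation.
* The MGF reader handles centroided peak lists with the common header
  variants; profile data and other formats (mzML, mzXML) are out of scope.
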