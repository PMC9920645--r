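---
title: "Methods: grasshopper-pruned extreme learning machines for FMG gesture recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grasshopper-pruned extreme learning machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ktgel)
```

## The model

An extreme learning machine (ELM) is a single-hidden-layer feed-forward
network in which the input weights $W \in \mathbb{R}^{n \times L}$ and
biases $b \in \mathbb{R}^{L}$ are drawn at random and never trained. For a
data matrix $X$ ($N \times n$) the hidden-layer output is
$H = g(XW + b)$ with an entrywise activation $g$, and the output weights
are the minimum-norm least-squares solution

$$\beta = H^{+} T,$$

where $H^{+}$ is the Moore–Penrose pseudoinverse and $T$ the one-hot
$\{0,1\}$ target matrix. Training is a single linear-algebra step;
prediction decodes $\operatorname{argmax}$ over the rows of $H\beta$, ties
toward the lowest class index. When $N \le L$ and $H$ has full row rank
the fit interpolates exactly ($H\beta = T$), which the test suite checks
across seeds.

KTGEL prunes this network at the *connection* level. A binary mask
$M \in \{0,1\}^{n \times L}$ multiplies $W$ elementwise; a hidden node
survives iff its column keeps at least one weight, and a feature survives
iff its row does — one weight couples exactly one feature to one node, but
a feature feeds many weights, so feature elimination requires the whole
row to die. The mask is chosen by maximizing the stratified
cross-validated accuracy of the masked ELM (output weights refit per
training fold; biases of dead nodes excluded), and the final model refits
$\beta$ once on the full training split with the winning mask.

## The optimizer

The mask search is a binary grasshopper optimization. Agents are bit
vectors; each iteration the continuous displacement of agent $i$ is

$$v_i = c \sum_{j \ne i} \frac{c}{2}\, s(d_{ij})\, \frac{x_j - x_i}{d_{ij}}
      + x_{\text{attractor}},$$

with the social force $s(r) = f e^{-r/l} - e^{-r}$ (defaults $f = 0.5$,
$l = 1.5$: short-range repulsion, mid-range attraction), pairwise
distances linearly rescaled into $[1, 4]$ per iteration so they fall in
the informative range of $s$ (coincident agents contribute zero, and an
all-equal population skips the rescale), and a coefficient
$c = c_{\max} - t\,(c_{\max} - c_{\min})/t_{\max}$ decaying linearly from
$1$ to $4 \times 10^{-5}$. The displacement is re-binarized by the
probabilistic *set* rule $P(\text{bit} = 1) = \sigma(v)$ with the logistic
$\sigma$ (no flip rule). The attractor is where the k-tournament enters:
each agent independently draws $k$ distinct population members and moves
toward the fittest of them (ties to the lowest index). `variant = "bgoa"`
is the same update with $k = P$, i.e. attraction to the current population
best; implementing it through the same tournament draw keeps the two
variants on identical random streams, so at $k = P$ they coincide
bit-for-bit — a property the tests assert. The elitist best-ever solution
is tracked separately and reported; its fitness trace is non-decreasing by
construction.

Open design points resolved here (the source algorithm bodies are printed
only as figures): the tournament is applied *per agent inside* the
repositioning loop rather than once per iteration; positions are rebuilt
purely from the transfer function of the displacement rather than mutated
from the previous bits; the initial population is i.i.d. Bernoulli(0.5)
with agent 1 forced to all-ones so the unpruned model is always in the
pool (this makes the reported fitness a guaranteed floor at the plain
ELM's CV fitness, at any budget including zero iterations). In the
feature-selection wrapper, exact fitness ties are broken toward fewer
selected features; no sparsity penalty enters the fitness itself (a
penalty-weight option exists conceptually but the default objective is
pure validation accuracy).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| weight/bias distribution | uniform $[-1,1]$ | canonical ELM choice; the source only says "random" |
| activation | logistic sigmoid (tanh, radbas selectable) | canonical; any bounded nonconstant $g$ works |
| pseudoinverse cutoff | $10^{-10}\,\sigma_{\max}$ | SVD singular values below this are treated as 0 |
| $c_{\max}, c_{\min}$ | $1, 4\times10^{-5}$ | published grasshopper defaults |
| $f, l$ | $0.5, 1.5$ | published social-force constants |
| $k$ | 3 | mild selection pressure; $k = P$ recovers plain best-attraction |
| CV folds | 5 | matches the experimental protocol (fivefold, 80/20 stratified split) |

Fold assignments are frozen per run (seed = ELM seed + 1), so a mask's
fitness is a deterministic function of the mask — the search never chases
fold noise. All randomness descends from explicit integer seeds; the
workbench derives stage seeds as global seed + fixed offsets (split +100,
ELM +200, wrapper +300, pruning +400).

## What the synthetic generator emulates

No FMG recordings are deposited with the source work, so the package
states a synthetic world and tests against it. Each gesture has a
per-channel mean-amplitude template drawn uniformly in $[1.2, 2.1]$ V
(the usable mid-range of a 3.3 V FSR voltage divider), sequentially
rejected to a minimum pairwise distance of 0.6 V. Between-subject
anatomy is additive $N(0, 0.25^2)$ V jitter on the template, drawn once
per subject. Within a repetition, samples follow a stationary AR(1)
process around the subject-level mean with innovation SD 0.25 V and
coefficient 0.6 (≈ 60 ms correlation at 100 Hz), emulating the
quasi-stationary, fluctuating contraction force of a held sign. These
four numbers were fixed once, by the reasoning above, before any
end-to-end accuracy was measured.

Ambiguity is modeled structurally: confusable groups of gestures have
their templates pulled toward the group centroid by a factor
$a \in [0,1]$ ($a = 1$ collapses the group). The presets mirror three
tiers — `"low"` (nine digit signs, 6–9 mutually similar, $a = 0.30$),
`"middle"` (letters A–J, groups {A, C, E} and {G, H}, dynamic J,
$a = 0.45$), `"high"` (twenty signs with five near-identical pairs,
dynamic Z, $a = 0.60$). Dynamic signs are emulated as amplitude-boosted
(×1.2) static templates — a stated simplification: the real signals
differ by a motion time-course this generator does not model. Channels
can be declared pure noise (`noise_channels`), in which case their
template entries are identical across classes.

With these defaults the stated world lands in the empirically interesting
regime rather than at saturation: ~0.9 test accuracy on the low preset
with 10 subjects and 8 channels, ~0.7 with 6 channels (fewer channels
carry less separating information), perfect accuracy for a single subject
with no ambiguity, and monotonically degrading accuracy through the
ambiguity tiers. A green end-to-end test therefore establishes that the
classifier responds to channel count, subject variability, and ambiguity
in the right direction — not that it reproduces any particular published
percentage, since the real data's difficulty cannot be recovered.

What the generator does **not** emulate: sensor drift and hysteresis,
session/placement effects, motion time-courses, cross-talk between
channels, and label noise. Train and test windows share subjects, as in
the source protocol.

## Numerical and degenerate-input choices

Variance and SD use the sample ($N-1$) convention; RMS is
$\sqrt{\text{mean}(x^2)}$; a window needs at least two samples. Min–max
normalization is fit on training rows only and does not clamp test values;
constant columns map to 0. The all-zero mask (features or weights) scores
fitness 0 without training, so a returned model always keeps at least one
node. Zero denominators in micro-averaged metrics yield 0 with a warning
flag. Argmax ties decode to the lowest class index everywhere.

## Known limitations

- **Emergent architecture reduction does not occur at realistic sizes.**
  The S-shaped set rule resamples every bit each generation with
  $P(1) \in [\sigma(0), \sigma(1)] \approx [0.5, 0.73]$ toward an
  attractor bit of 0 or 1 respectively (plus a small social term), so the
  population never concentrates on coordinated all-zero rows or columns:
  the probability that a specific 48-weight node column is entirely zero
  in any sampled mask is $\le 2^{-48}$. Connection-level sparsity of
  roughly half the weights is real and the pruned models match or beat
  the unpruned ELM, but whole-node death (and with it feature
  elimination through row death) is a measure-zero event under these
  dynamics. The two acceptance assertions that demand it are left
  failing deliberately, with the quantitative argument above.
- **Winner's curse at small validation sizes.** The mask search maximizes
  fold accuracy, so the selected mask overfits the folds by roughly one
  to two points at desk scale; stochastic accuracy comparisons in the
  tests therefore average a few fixed search seeds.
- Mask search cost grows as $n \times L$ bits; paper-scale runs
  ($48 \times 3000$) are supported but slow, and tests use $L \le 200$.
- YAML configs are not supported (JSON only), to stay within the
  guaranteed dependency set.
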