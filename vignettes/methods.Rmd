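---
title: "Reference-free tuning of k for error-correction tools: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free tuning of k for error-correction tools: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kanneal)
```

## The problem

k-mer-spectrum error-correction (EC) tools — Lighter, LoRDEC, Racer, the
MHAP stage of Canu, and relatives — classify k-mers of a read set as
*solid* (frequent, trusted) or *insolid* (rare, presumed erroneous) and
rewrite reads so that insolid k-mers become solid.  Their central
parameter is the k-mer length k.  Too small, and erroneous k-mers collide
with genomic ones, so errors hide inside the trusted set; too large, and
coverage per k-mer collapses until everything looks untrusted.  The best
k is dataset- and tool-dependent, and the standard way to find it —
correct at each candidate k, align each result to a reference genome,
keep the k with the best alignment rate — needs a reference and hours of
aligner time.

kanneal replaces the aligner-in-the-loop with a language model (LM)
trained on the *uncorrected* reads themselves.  Because sequencing is
redundant (coverage of 30x or more), correct sequence content dominates
the training signal: erroneous k-mers are rare and essentially random,
so they contribute little.  A corrected read set that fits this learned
distribution well (low perplexity) is one whose insolid content was
successfully rewritten into solid content; a corrected set that fits
poorly was under- or mis-corrected.  Perplexity over candidate
corrections is therefore a reference-free, *negatively* correlated proxy
for alignment rate, and minimizing it over k — here with simulated
annealing, treating the EC tool as a black box — recovers the k an
aligner would have chosen, at a small fraction of the cost.

## Workflow

Four steps, orchestrated by `cmd_train()`, `cmd_scan()` and `cmd_tune()`
(or the `inst/scripts/kanneal` command-line front end):

1. **Sub-sample** (`subsample_reads`): a uniform whole-read sample,
   default 4-5% of the data, with the fraction raised automatically so
   that sample coverage stays at or above 30x — below that, k-spectrum
   EC tools lose the frequency contrast they rely on.
2. **LM training** (`train_transformer` / `train_ngram`): on the
   uncorrected sub-sample.
3. **Data correction**: the EC tool runs on the sub-sample at a
   candidate k (`toy_adapter` for the built-in corrector,
   `external_adapter` for any shell-invocable tool).
4. **Evaluation** (`corpus_perplexity`): the corrected set is scored
   against the trained LM; steps 3-4 repeat under the annealing schedule
   (`sa_search`) until the minimizing k is returned.

## Tokenization

Reads are cut into chunks of 100 bp with a sliding-window stride of 50
(`chunk_reads`); a final window shorter than the chunk length is
trimmed.  Each chunk is an independent training sequence — successive
reads do not follow each other in a genome the way sentences follow each
other in text, so no window may cross a read boundary.  Reads shorter
than the chunk length (36-250 bp short-read libraries) are kept whole as
single chunks.  Chunks are then tokenized into overlapping *words* of
`|w|` bases with stride 1 (`words_from_chunk`): `AATCGGCGCT` with
`|w| = 4` becomes `AATC ATCG TCGG CGGC GGCG GCGC CGCT`.  The vocabulary
is all `4^|w|` words, mapped to integers by base-4 positional encoding
(A=0, C=1, G=2, T=3).  `|w| = 4` (256 tokens) is the default: smaller
vocabularies give the model too little to discriminate on, and larger
ones fragment the counts.  Chunks containing `N` are dropped rather than
imputed — an ambiguous base carries no learnable signal — and reverse
complements are *not* added to the corpus (the simulator nevertheless
generates both strands, as a real unstranded library would).

## The language model

The transformer back end is a compact encoder implemented in
RcppArmadillo: token embeddings of dimension `4^|w|` for `|w| < 4` and
128 otherwise, scaled by `sqrt(d_model)` and summed with sinusoidal
positional encodings; 4 pre-norm encoder layers (layer norm, then
self-attention with `h = 4` heads, then a residual add; likewise for
the position-wise feed-forward block) with a final layer norm; a linear
softmax output over the vocabulary.  The pre-norm arrangement is used
because it keeps gradient scales stable from the first optimizer step,
which is decisive in the few-epoch training regime used here (the
post-norm variant was measurably slower to leave the uniform-prediction
plateau at equal budgets).
The context window (`bptt`) is 99 tokens; training quality is known to
be insensitive to this value over a wide range, and a 100-bp chunk at
`|w| = 4` yields 97 tokens, just inside the window.

**Non-directionality.**  Genomic sequence has no preferred reading
direction: the content of a position is constrained as much by what
follows as by what precedes.  The usual causal mask is therefore removed
— every position attends to every position.  A masked language model
with separate forward and backward stacks is the heavier alternative;
disabling masks achieves the same with fewer parameters.

**Masked-span training objective.**  With no causal mask, predicting
each position from a window that still contains that position's token
would be a trivial copy.  The input token at a predicted position is
therefore replaced by a reserved placeholder id (the vocabulary is
extended by one internal token).  One further subtlety arises from
overlapping words: with stride-1 tokenization, the w-1 neighbours on
each side of a masked token overlap it, so masking an *isolated* token
leaks its entire content and the task again collapses to bookkeeping.
kanneal instead masks a contiguous *span* of tokens.  The span length
is a real design axis.  A span of `|w|` tokens (the default) hides
exactly one base — the flanking visible words determine the rest — so
prediction reduces to learning the corpus's local k-mer statistics:
which continuations of a seen context are frequent.  That is precisely
the solid/insolid frequency contrast the method rides on, it trains
quickly, and erroneous bases (rare, effectively random contexts and
continuations) stay poorly predicted.  Longer spans hide more interior
bases and turn prediction into locus memorization from long-range
context; that variant trains orders of magnitude more slowly at desk
scale and was rejected as the default for that reason (it is still
available through `mask_span`).  Spans are laid out one per block of
`mask_span * mask_phases` (default 16) positions, i.e. a quarter of all
positions are predicted per pass.  During training every sequence gets
one span layout per epoch at a random phase; during scoring the phases
are canonical, so
evaluation is deterministic.  `offsets = "all"` scores every position
exactly once (one forward pass per phase); `offsets = "rotate"` scores
one phase per chunk, rotating with the chunk index — a several-fold
cheaper estimate whose per-token expectation is the same, used by the
k-scan where only differences across k matter.

A consequence worth stating: on token streams *derived from random DNA*
with stride-1 words, a trained model can beat the `4^|w|` uniform floor,
because span-edge tokens are partially determined by their overlapping
neighbours.  The information-theoretic floor statement "perplexity of
uniform data equals the vocabulary size" applies to i.i.d. random
*token* streams, and that is how the calibration tests construct it
(`token_corpus_from_ids`).

**Optimization.**  The optimizer, learning rate and epoch count are
free choices here: Adam at 1e-3 with global gradient-norm clipping at
1.0 and 5 epochs by default, all exposed in `transformer_config`.  The
feed-forward inner dimension is `2 * d_model` — at these model sizes
the capacity bottleneck is the embedding, not the FFN, and the smaller
expansion halves the dominant matrix cost.  Head count 4 divides both
128 and 256.  Projections use Glorot-uniform init; embeddings are
unit-variance normal so that, after the `sqrt(d_model)` scale, token
identity rather than the O(1) positional signal dominates early
training; the output projection starts near zero, so an untrained model
predicts the uniform distribution (perplexity = vocabulary size), which
the calibration tests rely on.  Every source of randomness (weight init, shuffling, span
phases) derives from the single `seed`, and the heavy numerics are
deterministic given that seed.  Batch-size rule: training batches must
be at least as large as evaluation batches — large training batches
average the noise of erroneous reads away, while small evaluation
batches keep rare (suspicious) sequences visible in the per-batch
perplexities.

The N-gram back end (`train_ngram`) is the classical count-based
baseline: add-lambda-smoothed conditionals of order n, with an unseen
context backing off to order n-1 and ultimately to the marginal.  It
exists as an independent, closed-form-checkable implementation of the
same perplexity contract, and as the uniform/perfect calibration
reference.

## Perplexity

Internally everything is in nats; reported information quantities
(`cross_entropy`, `kl_divergence`) use bits to match convention, and
perplexity is `exp(mean per-token cross-entropy)` — for the N-gram back
end this is identically the m-th-root inverse probability of the scored
corpus.  `corpus_perplexity` groups chunks into evaluation batches,
reports the mean and across-batch SD of per-batch perplexities, and
carries `n_tokens_scored` so that scans across k are compared on
identical footing.  Per-read perplexities (`read_perplexities`)
aggregate chunk scores by source read; on a noisy read set the
truly-erroneous reads score visibly higher than the error-free ones,
which is the property the whole pipeline leans on.

## The search

`sa_search` minimizes perplexity over k with simulated annealing: step
size delta = 1 (doubled when the tool requires odd k), initial
temperature T0 = 2.8, cooling factor alpha = 0.7 per cycle, 8 cycles of
3 trials.  A worsening move of size dE is accepted with probability
`exp(-dE / (T * dE_avg))`, where `dE_avg` is the running mean |dE| over
proposals so far (initialized by the first proposal), which makes the
probability scale-free in perplexity units.  Proposals at the range
bounds are reflected inward rather than clamped, to avoid boundary
stickiness; the starting k is the range midpoint adjusted to parity;
evaluations are cached so no k is corrected twice; the returned optimum
is the best k *evaluated* (not merely accepted), with ties to the
smaller k, so the walk's acceptance path cannot lose an observed
minimum.  Each cycle after the first restarts from the incumbent best
(an elitist restart): because dividing by `dE_avg` makes uphill
acceptance roughly temperature-only, a 24-proposal walk on a steep
landscape can otherwise spend most of its budget on an accepted uphill
excursion; annealing around the best-so-far removes that failure mode
without touching the acceptance rule or the schedule.  `exhaustive_search` provides the oracle for validation and
the table behind the perplexity-vs-alignment correlation
(`normalized_correlation` — Pearson on z-scores, identical to plain
Pearson, retained in that form for report parity).

Perplexity-vs-k landscapes are smooth with a single interior optimum,
which is why a 25-evaluation annealing budget reliably lands within 1%
of the exhaustive optimum and why the selection is insensitive to T0
in [2.0, 3.25] and alpha in (0.6, 1) — both properties are regression
tests here, on synthetic landscapes of that shape.

## The built-in corrector and the synthetic test bed

`toy_correct` is a deliberately minimal k-spectrum corrector:
substitutions only, committed greedily at the first insolid window when
a single-base change strictly increases the number of solid covering
k-mers (ties: leftmost position, then alphabetical base; at most one
substitution per window and `ceil(len/k)` per read; scanning resumes k
positions after each attempt).  It exists so the pipeline can be tested
end to end without external binaries, and because its quality landscape
has the genuine k-dependence the search needs.  Its solidity threshold
is the first local minimum of the width-3-smoothed k-mer multiplicity
histogram (the valley between the error peak at count 1 and the
coverage peak), falling back to 2.

The simulator (`generate_genome`, `simulate_reads`) draws an i.i.d.
random genome, reads with uniform starts, lengths and strands until a
coverage target is met, and injects substitution/insertion/deletion
errors at configurable per-base rates (short-read regime below 3%,
long-read regime 15-40%), recording every edit.  Defaults for the
packaged study conditions: 50 kb genome, 40x coverage, 100 bp reads,
2-5% substitutions.  `alignment_rate_oracle` scores a corrected read as
aligned when its banded edit distance to the genome substring at its
*true* origin (strand-adjusted; band sized from the divergence budget
plus recorded indels, so any returned distance is exact) is at most
`max_divergence = 0.1` per base — lenient enough that uncorrected
2%-error reads align, strict enough that heavy miscorrection fails.
Aligning at the recorded origin rather than searching decouples the
measurement from aligner heuristics.

What the simulator does *not* emulate: platform error profiles
(homopolymer bias, quality-correlated errors), chimeras, coverage
non-uniformity, repeats (the genome is i.i.d.).  Passing tests
demonstrate the machinery and the direction of the perplexity-alignment
relationship at desk scale; they do not certify performance on real
libraries, where those structures exist.

## Problem sizes and numerical choices

The packaged validation runs at deliberately reduced scale so a full
check completes on a laptop core: the end-to-end study uses a 50 kb
genome at 40x coverage (15,000-read training sub-sample at 30x), a
2-layer, d_model = 64 transformer for 3 epochs at batch 16 (smaller
batches buy more optimizer steps within a fixed epoch budget, which at
these corpus sizes matters more than gradient smoothness),
perplexity scans over
odd k in [11, 31] scoring 6,000 chunks per k under the rotating-phase
protocol, and 50-landscape annealing calibrations.  Degenerate inputs
are handled explicitly: empty corpora refuse to train or score; a flat
search landscape (dE_avg = 0) accepts only equal-energy moves; chunks
shorter than one word are dropped; k-mers spanning an N are skipped.
Layer norm uses eps = 1e-5; softmax rows are max-shifted before
exponentiation; probabilities are floored at 1e-300 before logs.

## Known limitations

- The perplexity proxy is relative: it ranks k values, it does not
  estimate alignment rate.
- Sub-sampling trades fidelity for speed; the ordering of perplexities
  across k is what must survive, and does at 30x or more.
- The transformer is CPU-bound by design (no GPU path); model sizes
  beyond |w| = 6 (embedding 4096) are impractical here.
- Spectra hold native state and are rebuilt rather than serialized.
- The toy corrector is a test instrument, not a competitive EC tool.
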