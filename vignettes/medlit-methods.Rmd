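---
title: "Methods: literacy-aware annotation of medical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literacy-aware annotation of medical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

medlit implements a pipeline that makes medical documents accessible to lay
readers: it estimates a reader's health literacy from a short screening
test, recognizes medical entities in free text, links them to a knowledge
base, judges how difficult each term is, and annotates only the terms that
the reader's literacy level warrants.  This vignette describes each model,
its assumptions, the tunable parameters, and the design decisions taken
where the design was genuinely open.

## Health-literacy measurement (3PL IRT)

Responses to right/wrong screening items are modelled with the
three-parameter logistic item response model,

$$P_{ij} = c_i + \frac{1 - c_i}{1 + e^{-a_i(\theta_j - b_i)}},$$

with discrimination $a_i$, difficulty $b_i$ and guessing lower asymptote
$c_i$ per item, and latent ability $\theta_j$ per respondent.  Respondents
are treated as draws from a standard-normal population, so $\theta = 0$ is
the population average (50th percentile); the two-level policy used by the
annotator classifies $\theta \ge 0$ as high literacy and $\theta < 0$ as
low.  The boundary $\theta = 0$ is deliberately classified high: the scale
calls 0 "average" without assigning a side, so the assignment is ours and
is documented in `classify_literacy`.

**Ability estimation.** We use the expected a posteriori (EAP) estimate
rather than maximum likelihood: EAP is stable on the short response
patterns a screening test produces (all-correct and all-incorrect patterns
have finite estimates), and with zero usable items it degrades gracefully
to the prior ($\theta = 0$, se $= 1$).  The posterior is integrated on a
fixed equally spaced 61-point grid over $[-6, 6]$ with normal prior
weights.  Because the integrand decays like a Gaussian well inside the
interval ends, this trapezoid-type rule converges spectrally; the test
suite checks agreement with a 10,001-point oracle to $10^{-4}$ (observed
agreement is closer to $10^{-8}$).  The grid is configurable through
`quadrature_grid()`.

**Calibration.** Item parameters are estimated by Bock–Aitkin
marginal-maximum-likelihood EM on the same fixed grid.  The E-step computes
each person's posterior over the grid; the M-step maximizes each item's
expected log-likelihood with box-constrained L-BFGS-B.  The 3PL is famously
weakly identified in $c$ (and through it, $a$); we therefore run MAP-EM
with the standard stabilizers used by established IRT software: $c$ is
constrained to $[0, 0.5]$ and carries a weak Beta(2, 8) prior (mode 0.125),
and $a$ carries a lognormal(0, 0.5) prior.  Both priors are configurable
and can be switched off.  The reported objective is the penalized marginal
log-likelihood, which is non-decreasing across iterations (EM ascent, with
a guard that keeps the previous parameters whenever the inner optimizer
fails to improve an item).  Convergence is declared when the objective
improves by less than $10^{-5}$, with a 500-iteration cap.  Columns that
are constant across respondents carry no information and are excluded with
a warning.  At the simulation sizes used in the tests (2000 respondents,
30 items), calibration recovers difficulty with RMSE well under 0.3 and
discrimination with correlation above 0.8.

**Test shortening.** The short form first removes items that cannot
separate high from low ability — operationalized as $a \le a_{\min}$ with
$a_{\min} = 0.2$ by default (no threshold is canonical; the value is
configurable) — and then selects the $n$ items with the highest mean
Fisher information $I_i(\theta) = a_i^2 (Q_i/P_i)(P_i - c_i)^2/(1-c_i)^2$
across the $\theta$ grid.  Test information is additive across items, so
top-$n$ selection by mean information *is* the exact maximizer of average
summed information; the suite confirms equality with exhaustive subset
search on small banks.  $n$ is a user choice.

## Entity recognition (BiLSTM-CNN-CRF)

Mentions of diseases, problems, drugs and tests are tagged with a
BIO-scheme sequence model: each token is represented by the concatenation
of a learned word embedding and a character-level CNN vector (width-3
filters over character embeddings, tanh, max-over-time pooling); a
bidirectional LSTM contextualizes the sequence; a linear layer produces
per-tag emissions; and a linear-chain CRF scores complete tag paths with
learned transition scores plus start/stop transitions.

The CRF layer is exact: the forward recursion computes the log-partition in
log space, and Viterbi recovers the argmax path, with ties broken toward
the smallest tag index at every step (so an all-tie instance returns the
lexicographically smallest path).  Training minimizes the negative CRF
log-likelihood by per-sentence Adam steps; all gradients — CRF marginals,
LSTM, CNN and embedding backprop — are hand-derived and pinned by
finite-difference tests at $10^{-9}$.  Decoding applies a $-\infty$ mask to
BIO-invalid transitions by default, so emitted tag sequences are always
structurally valid.

Default sizes (12-dim character embeddings, 16 CNN filters, 24-dim word
embeddings, 20 hidden units per direction, Adam at 0.02, at most 200
epochs with early stopping once training F1 reaches 1.0) are desk-scale:
they let the model memorize a 30-sentence corpus in seconds on one CPU,
which is the regime the synthetic corpus exercises.  A loader for
pretrained vectors in the standard text format (`word v1 v2 ...`) is
provided; embeddings are randomly initialized otherwise.  Unknown words
and characters map to UNK entries.  Training is deterministic given the
seed (seeded initialization and seeded epoch shuffling), and the
save/load round-trip preserves predictions bit for bit.

## Entity linking

**Candidate generation.** Every (concept, alias) pair in the knowledge
base — the canonical name counts as an alias — is encoded as an L2-normalized
TF-IDF vector of character 3-grams, with `#` boundary padding so surfaces
shorter than 3 characters still produce n-grams.  TF is the raw trigram
count in the alias; IDF is the smoothed $\log((1+N)/(1+\mathrm{df})) + 1$
over the $N$ alias strings.  The formula is fixed and documented so index
construction is bit-stable.  Trigrams below a frequency threshold are
dropped from the vocabulary; the threshold defaults to 1 (no filtering) at
desk scale, with around 10 suggested for large vocabularies.  Candidates
are the top-$k$ distinct concepts by cosine similarity ($k = 25$ by
default), found by exact search — at these scales approximate
nearest-neighbour structures buy nothing, and the contract allows swapping
the search later.  A mention identical to a stored alias has cosine 1
against it by construction.

**Disambiguation.** When a mention has several candidates, a vector-space
word-sense-disambiguation step picks the sense whose aggregated context
vector is closest (cosine) to the mention's context vector.  Features are
the three classic supervised-WSD families: unigrams and bigrams within a
5-token window on each side, and positional collocations at offsets
$-2, -1, +1, +2$.  Sense vectors aggregate each concept's KB definition
(unigrams/bigrams only — definitions have no mention position) and any
labelled training contexts, so the component works unsupervised from
definitions alone and improves with supervision.  An empty or
uninformative context falls back to candidate-generation order.  Mentions
on the medical stop-word list are discarded before linking; a mention whose
normalized surface matches exactly one alias takes a fast path and is
resolved directly.

## Term difficulty

Gold labels come from a 6-annotator panel rule: 6 positive votes (all
annotators understand the term) is easy, 4–5 is medium, fewer than 4 is
difficult.  `votes_to_label` implements the rule exactly over 0..6.

Prediction combines a character-level encoder over the term string (the
same CNN plus a character BiLSTM, concatenating the pooled CNN vector with
the final forward and initial backward hidden states) with a dense feature
vector: rule-based syntactic category, character and syllable counts,
medical prefix/suffix membership, consonant/vowel/other composition
(counts partition the character count exactly; spaces and punctuation
count as "other"), lexicon membership, general-corpus and medical-KB
frequencies (log-scaled), KB semantic types and an optional word
embedding.  Web-scale frequency services are not reproducible offline, so
frequencies come from pluggable plain-text tables; small default tables
ship with the package.  Syllables are counted as maximal `aeiouy` groups
with a trailing silent-e correction.  Features are z-scored with training
statistics; the encoder output and features feed a tanh hidden layer and a
softmax over the three labels, trained with Adam, deterministic given the
seed.  How the dense features and the character encoder should be combined
is not canonical; concatenation before the output layer is the simplest
joint treatment and is what we adopt.  A multinomial-logistic engine over
the dense features alone is provided for settings where the neural path is
unnecessary.

## Annotation policy and pipeline

The annotator runs: tag → stop-word removal → overlap resolution (keep the
longest span, leftmost on ties) → difficulty classification → literacy
policy → candidate generation → disambiguation → relation expansion.
High-literacy readers get only difficult terms; low-literacy readers get
medium and difficult terms; easy terms are never annotated.  This makes
low-literacy output a superset of high-literacy output on any document, a
property the tests assert.  Filtering happens before linking, which also
minimizes work.  Each annotation carries the concept's definition and its
depth-1 neighbours along taxonomic (`instance_of`, `subclass_of`,
`part_of`, `has_part`) and associative relations; depth 1 keeps the
annotation readable and is configurable.  Offsets are 0-based, half-open,
over code points, and the JSON renderer emits keys in sorted order with
fixed numeric precision so repeated runs are byte-identical.  The HTML view
is presentational only.

## Synthetic data

The generators stand in for licensed or web-scale resources and define the
conditions the tests run under: a 50-concept KB of pronounceable
pseudo-terms (syllable templates plus medical affixes) with 1–4 aliases
each, templated definitions over a shared symptom/anatomy vocabulary,
forest-shaped taxonomic relations, and exactly
`round(ambiguity_rate * n_aliases)` aliases shared between two concepts
(10% by default, injected by swapping a private alias for another
concept's name so totals stay exact); a 30-sentence corpus embedding KB
aliases as gold entities at 30% entity-token density; 3PL response
matrices (2000 respondents × 30 items, $a \in [0.8, 2]$, $b \in [-2, 2]$,
$c \in [0, 0.25]$ — ranges typical of screening instruments) drawn exactly
from the model with the true abilities returned for recovery tests; and a
60-term difficulty set whose labels are produced by simulated annotator
panels (per-class positive-vote probabilities 0.99 / 0.75 / 0.1) pushed
through the real vote rule.  All generators are pure functions of
(spec, seed).

What the synthetic data does *not* emulate: real clinical narrative
(sentences are templated), UMLS-scale vocabulary structure, genuinely noisy
span boundaries, or annotator disagreement beyond independent Bernoulli
votes.  Passing tests therefore demonstrate correctness of the algorithms
under controlled conditions — exact CRF inference, faithful 3PL recovery,
exact retrieval — not clinical-grade accuracy on real notes.

## Numerical choices and degenerate inputs

All log-domain reductions use max-shifted log-sum-exp.  EM keeps previous
item parameters whenever the M-step fails to improve, preserving ascent.
Probabilities are clamped away from 0/1 at $10^{-10}$ inside likelihoods.
Viterbi ties break toward the smallest tag index; candidate ties break by
concept id; short-form ties break by item-bank order.  Degenerate inputs
are contracts, not crashes: empty corpora, single-class training sets,
mismatched response vectors, votes outside 0..6, unknown concept ids, and
oversized documents all raise typed errors; empty candidate sets and
mentions with no in-vocabulary trigrams are reported as empty results.

## Problem sizes

The test-suite and the acceptance script use the generator defaults above:
200 random CRF instances with $L, T \le 4$ against exhaustive enumeration,
the 30-sentence corpus for tagger memorization, three 2000×30 replicates
for calibration recovery, 10 small banks for short-form optimality, a
~50-concept KB for retrieval checks, 20 held-out contexts for
disambiguation, and 60 terms for the difficulty classifier.  These sizes
were chosen so the entire suite runs in minutes on a single CPU while
every check remains a genuine oracle comparison.

## Known limitations

- The tagger trains by first-order methods on small corpora; no
  mini-batching, dropout or pretrained contextual encoders.
- The guessing parameter of the 3PL is reported but only weakly identified;
  its point estimates should not be over-interpreted even with the priors.
- Alias normalization is case/whitespace folding without stemming or
  transliteration; cross-lingual linking is out of scope.
- The difficulty features treat multi-word terms as a single character
  stream; syntactic category for isolated terms is a heuristic with a
  "noun" fallback.
- The annotator assumes one reader level per document and does not cache
  or stream; documents are size-capped.
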