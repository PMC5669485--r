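---
title: "Distributed smoothed tree kernels for PPI extraction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed smoothed tree kernels for PPI extraction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidstk)
```

## The task and the model

Given a sentence with annotated protein mentions, every labelled pair of
mentions is a candidate instance: does the sentence assert an
interaction between these two proteins? The two focus mentions are
blinded to `PROT1`/`PROT2` (the leftmost mention becomes `PROT1`),
other protein mentions to `PROT`, multiword names collapsing to a single
token, so the learner generalizes over protein names. Classification is
a soft-margin SVM over precomputed Gram matrices; three kernels are
compared under stratified 10-fold cross-validation.

### Feature-based kernel

Sparse binary word features — the lowercased surface words of the two
protein names (`P-`/`p-`), every non-blinded token strictly between the
two mentions (`b-`), up to three tokens left of the first and right of
the second mention (`l-`/`r-`; punctuation counts as a token), and the
lemma of the sentence's first interaction keyword (`ik-`) — plus two
numeric distance features: the count of blinded distractor proteins
between the pair, and the binned count of non-protein words between the
pair. The bins are half-open so the map is total and single-valued:
no tokens at all → 0, count < 3 → 1, count in [3,6) → 2, [6,9) → 3,
otherwise 4. The kernel is the plain inner product of these vectors.
Tokens are normalized first: lowercased, and tokens that are entirely
numeric become the sentinel `NUM` (alphanumeric identifiers such as
`IL-2` are names, not numbers, and must survive). Zero-valued features
are never stored.

The windows are anchored at the first mention's left edge and the second
mention's right edge only; windows facing into the pair's interior would
duplicate the `b-` channel and are not emitted.

### Lexicalized trees and the exact smoothed kernel

Each candidate's bracketed constituency parse (supplied with the corpus,
or generated alongside the synthetic sentences; the package does not
parse) is blinded consistently with the token sequence and lexicalized:
every node receives a head word by bottom-up percolation under a
condensed Collins-style head-rule table (`inst/extdata/head_rules.txt`;
unknown categories default to their rightmost child). If the sentence
contains an interaction keyword, every node dominating the first
keyword token has its head forced to that keyword — interaction verbs
become the heads of their whole spine up to the root, which is what lets
the semantic factor below see "bind-ness" at every structural level.

The fragment space S(t) is the classic subset-tree space: connected
subgraphs in which every included node keeps all of its children or
none; a fragment rooted at a preterminal always carries its word, and
single bare labels are not fragments (so the 3-node tree
`(A (B b) (C c))` has exactly 6 fragments). The exact smoothed tree
kernel is

$$K(t_a, t_b) \;=\; \sum_{t_i \in S(t_a)} \sum_{t_j \in S(t_b)}
\lambda^{(N_i + N_j)/2}\,\delta(t_i, t_j)\,
\langle v(h_i), v(h_j)\rangle,$$

where $N_i$ counts a fragment's *expanded* nodes (the Collins–Duffy
production count — this convention is what makes the recursion below
carry exactly one $\sqrt\lambda$ per node), $\delta$ is structural
identity of the fragments including the words at expanded preterminals,
$h_i$ is the head word of the fragment's root in the source tree, and
$v(\cdot)$ are unit-normalized distributional vectors, so the semantic
factor is a cosine and identical heads contribute 1. `exact_stk()`
computes this by exhaustive fragment enumeration with signature
grouping; it is exact but exponential, an oracle for small trees only
(`max_count` guards it).

### Distributional head-word vectors

Head-word vectors come from the corpus itself: sentences are normalized,
every entity mention collapses to the generic `PROT` token,
sentence-scope co-occurrences are counted (each ordered pair of distinct
token positions once, so the matrix is symmetric), weighted by positive
pointwise mutual information $\max(0, \log p(w,c)/(p(w)p(c)))$ — the
clipped variant is total where plain PMI is undefined at zero counts —
and reduced by truncated SVD, word vectors being rows of $U_k\Sigma_k$
with each singular vector's sign fixed so its largest component is
positive (deterministic across runs). The nominal dimension is
$k = 1024$ (2048 selectable); a small corpus caps $k$ at the matrix
rank, and the test problem sizes use $k = 8$–$16$. At lookup time
vectors are unit-normalized; `PROT1`/`PROT2` alias to the `PROT` row, so
all blinded proteins share one vector — protein identity is carried by
the structural side, protein-ness by the semantic side. Genuinely
unknown words follow the OOV policy: zero vector by default (their
fragments contribute no semantic mass), or a deterministic hash-seeded
unit vector. A precomputed word2vec-style text table can be loaded
instead (`read_embeddings()`).

### Distributed smoothed trees

The exact kernel factorizes per tree over fragment signatures, which is
what the distributed construction exploits. Every syntactic label and
every word receives a random vector drawn uniformly on the unit sphere
of $R^d$, memoized under a master seed (exact unit normalization roughly
halves the variance of the kernel estimate compared with raw Gaussian
draws of expected unit norm). Fragments are encoded by *shuffled
circular convolution* $a \circledast b = \mathrm{circconv}(\Pi a, b)$
(one fixed random permutation $\Pi$ per store, FFT-based): bilinear,
non-commutative, approximately norm-preserving, and distinct fragment
encodings are nearly orthogonal, so dot products of encodings
approximate the Kronecker delta of the exact kernel. The per-node
structural sums obey the recursion

$$s(n) = \sqrt{\lambda}\; r_{s_n} \circledast
\bigl(z(c_1) \circledast \cdots \circledast z(c_m)\bigr), \qquad
z(c) = r_{s_c} + s(c),$$

with preterminals contributing
$\sqrt{\lambda}\, r_{\mathrm{pos}} \circledast r_{\mathrm{word}}$. By
bilinearity this equals the explicit sum
$\sum_{f\ \mathrm{rooted\ at}\ n} \lambda^{N_f/2}\phi(f)$, which the
test suite verifies against the brute-force enumerator to $10^{-10}$.
The tree matrix is $T = \sum_n s(n)\, v(w_n)^\top \in R^{d\times k}$
(grouping by root node is valid because all fragments rooted at $n$
share its head word), and the kernel is the Frobenius product
$\langle T_a, T_b\rangle$. The child fold is left-to-right; the
convolution is non-associative under the permutation, so the order is
part of the encoding's definition.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lambda` | fragment-size decay, per expanded node | 0.4 | the standard choice for subset-tree kernels |
| `d` | structural dimension of the random vectors | 4096 | approximation error decreases in d; 512 is ample for corpus-scale Grams |
| `k` | distributional vector dimension | 1024 | capped at the co-occurrence rank; tests use 8–16 |
| `w` | weight of the DSTK term in the composite | 1.0 | composite is `fea' + w·dstk'` on cosine-normalized components |
| `C` | SVM soft-margin constant | 1.0 | |
| `seed` | master seed of the random label store | 42 | same seed ⇒ bit-identical Grams |

Per-kernel cosine normalization before summation is on by default:
unnormalized feature and tree kernels live on incomparable scales, and
normalization gives the composite the clean diagonal $1 + w$. The
"ensemble" is a single SVM on the summed Gram; a score-averaging
two-model variant is available (`ensemble_mode = "score_avg"`) for
comparison. Cross-validation is stratified at instance level under a
fixed fold seed; instances from one sentence can land in different
folds, which slightly flatters all kernels equally — document-grouped
splitting would be the stricter protocol but instance-level splitting is
the conventional one for these corpora and is the default.

## The synthetic corpus generator

`generate_corpus()` emulates a sentence-annotated PPI corpus: templated
clauses with gene-symbol entities (letters+digits, so the `NUM` rule is
exercised but must not fire on names), gold labels, and a gold bracketed
parse built together with the tokens, so parse and sentence cannot
disagree. Positive templates realize interaction evidence —
transitive clauses, `with`-PPs, passives, nominalizations
("the interaction of A with B"), coordinations ("A and B
heterodimerize", "A and B were crosslinked") — negatives co-mention
proteins without relating them (coordinated purification, detection in
the presence of, two-clause sentences whose interaction verb takes a
non-protein object, list contexts, and detection "by `<method>` with
B"). Design choices that shape the learning problem, chosen once to
mirror the statistics of real abstracts:

* **Zipf-tailed verb pools.** Interaction verbs and participles are
  drawn with probability proportional to 1/rank. A sparse lexical
  learner sees many test-time verbs rarely or never in training; the
  structural kernel matches the clause spine regardless of the verb, and
  the distributional vectors let rare verbs inherit similarity from
  frequent ones. This is the mechanism behind the characteristic
  high-precision/low-recall profile of the feature kernel versus the
  higher recall of the tree kernel.
* **Class-neutral modifiers.** Sentence openers, report frames ("these
  results show that …") and locative tails attach to positives and
  negatives alike, so no peripheral context word identifies the class.
  Positives may instead draw an interaction-assay tail ("in this
  binding assay"), which makes interaction verbs co-occur with
  interaction nouns in the PPMI space.
* **Minimal pairs.** The bare coordinated negative ("A and B were
  purified") is structurally identical to the passive coordination
  positive; only the participle's identity and semantics separate them.
* **Distractors.** A sentence with a third, non-interacting protein
  (default 5% of positive draws) yields one positive and two negative
  pairs whose blinded trees differ only at the `PROT1`/`PROT2`/`PROT`
  leaves — the hard multi-protein case, and deliberately the structural
  kernel's weak spot, as it is for full-scale systems.
* **Defaults as study conditions.** 250 sentences, 40% positive
  sentence draws (real PPI corpora are negative-skewed), no label noise;
  label noise flips emitted labels independently while the truth table
  keeps the clean labels.

What the generator does *not* emulate: real biomedical syntax diversity
(relative clauses, appositions, coordination ambiguity), parser errors,
discontinuous or nested entity mentions at meaningful rates, and
corpus-specific annotation idiosyncrasies. Passing the synthetic suite
therefore shows the machinery is correct and that the kernels behave as
designed under controlled conditions — not that published benchmark
scores on AIMed or BioInfer would be reproduced; those require the
downloadable corpora and a full statistical parser and are outside this
package's test surface.

## Numerical and degenerate-case choices

* Inclusive XML character offsets convert to 0-based half-open spans at
  the I/O boundary only; entity surfaces must equal the spanned text.
* Overlapping entity mentions: the longest span wins blinding, with a
  warning. Self-pairs are dropped with a warning.
* Undefined precision/recall (zero denominators) are reported as 0 with
  a warning; F is 0 when P + R = 0.
* Cosine normalization maps zero-diagonal rows (e.g. a tree whose heads
  are all OOV under the zero policy) to 0 rather than NaN.
* SVM decision values are oriented against the model's own class
  predictions before pooling for ROC, since the sign convention of the
  underlying solver is not fixed.
* kernlab's SMO is run with `shrinking = FALSE`: on the near-duplicate
  Grams produced by template corpora the shrinking heuristic can stall
  without changing the solution.
* The fragment cap (`max_count`) makes the exponential oracle fail
  loudly instead of hanging; the distributed path has no such limit.
* All randomness flows from explicit seeds through a string-hash
  splitter, so label vectors, folds and the generator are reproducible
  independently of call order and of the caller's RNG state.

## Problem sizes used by the test suite

Unit and acceptance tests run the full pipeline at reduced, documented
sizes chosen to keep the suite fast while leaving every mechanism
exercised: trees of ≤ 8–10 nodes against the brute-force oracle;
d ∈ {256, 1024, 4096} for the convergence check over 50 clause-template
tree pairs; corpora of 60–300 sentences with d = 256–512 and k = 8–16
for Gram algebra, ceiling recovery (noiseless, 250 sentences, 10-fold)
and the noisy-regime comparison (20% label noise, 300 sentences, means
over five generator seeds). The acceptance script
(`scripts/acceptance.R`) re-runs the noiseless evaluation and the
convergence measurement from scratch under a caller-supplied seed.

## Known limitations

* The rule-based POS/lemma backend is deliberately small: a
  suffix-stripping lemmatizer with lexicon-assisted stem repair and a
  closed-class tag table. It is accurate on the vocabulary the pipeline
  depends on (interaction verbs, nominalizations, participles) and
  replaceable by any backend honouring the one-tag-one-lemma contract.
* Multi-protein sentences remain the hardest case: instances from one
  sentence share almost all of their tree, and with C = 1 the SVM often
  cannot separate within such near-duplicate families.
* The distributed approximation's error grows with tree size (more,
  larger fragments per tree at fixed d); for corpora of long sentences,
  increase `d`.
* `exact_stk()` is exponential in tree size and is an oracle, not a
  production path.
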