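---
title: "Building a symptom-centric Chinese medical knowledge base: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a symptom-centric Chinese medical knowledge base: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

symkb builds a knowledge base (KB) of symptoms in Chinese by combining four
kinds of evidence: semi-structured detail pages of healthcare websites,
encyclopedia entity pages, clinical free text from electronic medical
records (EMRs), and an English terminology for cross-lingual grounding.
This vignette explains each stage's model, its tunable parameters, and the
design decisions taken where the problem was genuinely open.

## Schema and store

The schema centres on **Symptom**, connected to Disease, Medicine,
Department and Examination.  Both Symptom and Medicine split into a
traditional-Chinese-medicine (TCM) subtype and a Western-medicine subtype;
TCM vocabulary ("阴虚", "气滞") has no Western counterpart, and a symptom
related to both a TCM department and a Western one legitimately carries both
subtype labels.  Subtype labels imply their parent (`expand_types()`
enforces the closure), so per-type statistics count a multi-subtype entity
once per carried type while the distinct total counts it once.

Every predicate must be declared with a range kind before facts can use it.
This is deliberate: terminologies such as UMLS carry relations (e.g. `RO`)
with no fixed interpretation, whereas this KB's contribution is relations
with definite syntax and semantics — so undeclared predicates are rejected
at add time rather than silently stored.

**RDF export.**  Entities are minted as `ent:<id>` IRIs where `<id>` hashes
the primary source and the surface name: Chinese names are not reliable IRI
local parts, and hashing keeps the IRI stable across re-runs.  The name
travels as an `rdfs:label` literal with a language tag.  Fact provenance
cannot ride on a plain triple, so each sourced fact also emits a standard
RDF reification block whose blank-node label is itself a hash of
subject/predicate/object/source — making serialization canonical
(triples are sorted before output) and `parse(serialize(kb))` the identity
on the triple set in both Turtle and N-Triples.  One caveat is documented:
an entity attribute whose value coincides exactly with a sourced fact's
literal object is folded into that fact on re-parse.

**Evaluation machinery.**  `kb_sample_facts()` draws simple random samples
without replacement under an explicit seed (the caller's RNG state is
restored).  `majority_vote()` aggregates a judging panel; with the
seven-judge protocol ties cannot occur, but even panels resolve to
*incorrect* — the conservative choice when the quantity being estimated is
a correctness ratio.

## Wrapper extraction from healthcare sites

Detail pages within one site share a layout, so extraction is
configuration, not code: each site's wrapper (a YAML entry) names the
structural locators of the property box, its rows and cells, plus the map
from the site's attribute names to schema properties.  Only mapped rows are
emitted, values are whitespace-normalized, and a page without a property
box yields an empty result with a log line — one malformed page must not
halt a batch.

Two heuristics assign subtypes.  A symptom related to any department whose
name carries a TCM marker (default set `{"中医", "TCM", "Traditional
Chinese"}`, configurable) is a TCM symptom; any unmarked department
contributes the Western label; both can co-occur.  A medicine is typed by
description keywords (patent/herbal-medicine vocabulary for TCM;
pharmaceuticals/chemicals for Western); with no keyword evidence it stays a
plain Medicine.

Synonyms are harvested from page abstracts with two-slot lexico-syntactic
templates ("`{1}`又称`{2}`", "`{1}` is known as `{2}`", …).  The inventory
is configurable because no fixed list is canonical; matching is
literal-template with non-greedy slot fill bounded at sentence boundaries,
slot fillers are trimmed of punctuation, self-pairs are suppressed, and
each pair enters the KB as `sameAs` in both directions.

## Bootstrapping encyclopedia entities

Encyclopedia sites are noisy: category tags mix medical topics with
lifestyle content.  The bootstrap is a single pass: (1) entities already
extracted from healthcare sites act as *seeds*, and the categories of their
encyclopedia pages form the candidate set; (2) every category observed in
the corpus is scored by its *seed ratio* — seeds among members — and
labelled high- or low-confidence against a threshold; (3) any page carrying
a low-confidence category is removed as noise.  A category that no seed
page reaches simply scores zero, which uniformly extends the rule rather
than special-casing reachability.  Pages with no categories at all are
retained: the rule removes only on positive evidence.  Filtering is
idempotent, and raising the threshold can only shrink the high-confidence
set (both are property-tested).

The threshold defaults to 0.1.  No principled value exists a priori; 0.1
keeps a category whose membership is at least one-tenth seed-derived, which
on corpora with a few dozen members per category requires 3–4 independent
seed confirmations.  It is exposed in configuration and swept in tests.

**Classification.**  Retained pages are classified into seven labels
(department, TCM medicine, Western medicine, symptom, disease, examination,
other) by a CART decision tree over 26 features drawn from the five page
fields (name, abstract, content, full text, categories).  The inventory is:
per-word name-suffix tests (6) plus an any-suffix aggregate; per-word
containment tests on the abstract (4), full text (2) and categories (6),
each with an aggregate; and for the content field the distinct-hit counts
of a medicine-leaflet word list and a disease-article word list with their
"more than 3 distinct words" booleans.  Word-formation/word-distribution
features admit many reconstructions at this dimensionality; this one is
fixed and fully documented in `default_feature_config()`, and every word
list is replaceable.  Tree growing uses `rpart` with `minsplit = 4`,
`cp = 0.001` and no internal cross-validation (`xval = 0`), making training
deterministic; evaluation follows the standard ten-fold protocol with a
seeded fold shuffle.  Symptom pages are refined into TCM/Western subtypes
by harvesting department mentions from the text; with no department
evidence the page defaults to WesternSymptom, because TCM labels should
only ever arise from positive marker evidence.

## CRF symptom recognition in EMRs

Western-medicine symptoms are learned from the physical-examination and
Western-differential fields; TCM symptoms from the disease-analysis and TCM
differential — two independent models, mirroring the disjoint field
selection and terminology.  Clinical text duplicates sentences freely
(copy-forward), so within each record every sentence is kept once —
first occurrence, order preserved — before annotation and decoding.

The recognizer is a linear-chain conditional random field over 37
per-position feature templates: literal unigrams/bigrams/trigrams in a ±3
token window, the position index, and the same n-grams over POS tags, with
a `<PAD>` token filling window slots off either end so the template count
is constant at every position.  Spans are encoded as BIO (`B-SYM`,
`I-SYM`, `O`) — the minimal standard scheme — and an orphan inside-label at
decode time is promoted to a begin-label, the least destructive repair.
Tokens come from a pluggable segmenter (forward maximum matching over a
lexicon, with a character-level fallback mode recorded in the model
metadata, since clinical segmenters vary).

Training minimizes the exact negative log-likelihood (forward–backward in
log space, implemented in C++) with L-BFGS under an L2 penalty
(`l2 = 1.0`); the zero initialisation makes the fit deterministic given the
data order.  Features unseen at training time contribute nothing at decode
time.  Evaluation is exact-match entity-level precision/recall/F1, with
zero denominators reported as undefined (`NA`) rather than zero.

## Entity fusion

Duplicate entities across sources are resolved in three steps.

*Type alignment* is by voting: the type with the most source votes wins,
and ties break toward the higher-priority source (priorities are an ordered
source list, standing in for traffic rankings).

*Entity mapping* combines two signals.  **Commonness** is name-string
similarity $|\mathrm{LCS}(E_A, E_B)| \,/\, \max(|E_A|, |E_B|)$, computed at
character level over Unicode code points — Chinese medical names are short
and unsegmented, so word-level LCS would require a segmenter inside a
similarity primitive.  Two empty names are an error (0/0 is undefined, and
empty names violate entity invariants anyway).  **Relatedness** is the
similar share of attributes present in both entities, where two values
count as the same fact when their own string similarity reaches a second
threshold (default 0.85).  A pair merges when
$commonness \times relatedness$ exceeds the product threshold
(default 0.5); both thresholds are configuration, since no principled
constants exist, and the merge count is verified to be monotone
non-increasing in the threshold.  Entities sharing *no* attribute get
relatedness 0 and are flagged for manual review: name evidence alone never
merges.  Pairwise links are closed transitively — needed to merge more than
two sources coherently — and each cluster collapses into one entity keeping
the name of the highest-priority source with the union of types, sources
and attributes.  Since relatedness is bounded by 1, pairs whose commonness
already fails the product threshold skip the attribute comparison, which
keeps the quadratic scan cheap.

*Attribute mapping* rewrites source attribute names onto schema properties
by ordered rules, most-specific (type-constrained) first; an attribute no
rule covers is quarantined, never silently dropped.

## Cross-lingual linking

Symptom names are translated into English through an injected translator
interface — in practice a fixed bilingual lexicon, which is deterministic
and desk-testable where a commercial translation API is neither.  Both the
translation and every concept term are reduced to bags of words under one
frozen normalization (lowercase, punctuation stripped, whitespace split,
set semantics), and a link is made only at Jaccard similarity exactly 1.
Because the rule is exact-match, the normalization choice is consequential
and is applied identically to both sides; no stemming is performed by
default ("fevers" ≠ "fever"), keeping the linkage as strict as stated.
Several concepts sharing one bag all receive links — no disambiguation step
is defined.  Stored links are re-verifiable (`audit_links()` recomputes
every Jaccard from scratch), and the semantic-type distribution over links
quantifies how much of the colloquial symptom vocabulary lands outside the
"Sign or Symptom"/"Finding" types.

## Synthetic study conditions

All inputs are generated with planted ground truth, so the full pipeline
runs and is tested offline.  The generators are pure functions of their
seeds (byte-identical re-runs) and use floor rounding when a rate times a
count is fractional, so "exactly 20 noise pages at rate 0.2 over 100" is
well defined.

* **Healthcare sites**: two pseudo-sites with list pages, detail pages and
  differing property-box markup (so wrappers matter); a configurable
  fraction of entities is duplicated onto the second site with up to one
  character edit; some abstracts carry synonym sentences; one page omits
  its property box.
* **Fusion fixture**: 100 duplicate pairs across two pseudo-sources, names
  perturbed by up to 2 character edits and exactly 1 of 3 attribute values
  replaced, plus 100 singleton distractors.  Names are long compound
  complaints (≥ 13 characters), as real complaint-style symptom strings
  are, so a 2-edit perturbation keeps name similarity comfortably above
  what the product rule needs, while attribute values are drawn from pools
  large enough that chance collisions between unrelated entities are rare.
* **Encyclopedia corpus**: 210 pages by default — six medical labels with
  planted per-label keyword signals and type categories, 20% lifestyle
  noise pages carrying zero-seed categories, 5% feature noise (one keyword
  signal corrupted), a few category-less pages, and per-label seed pages
  that put every type category's seed ratio above the 0.1 threshold.
* **EMR corpus**: 1,000 records over the four named fields; sentences are
  templated clinical contexts around lexicon symptoms (one- and two-token
  forms), hard-negative distractor sentences, and ambiguous contexts where
  a slot holds either a symptom or a non-symptom noun, so recognition there
  depends on token identity.  The symptom vocabularies (≈ 1,500 Western,
  ≈ 500 TCM surface forms) deliberately exceed what 660 annotated records
  can cover — as in real clinical text — which is why entity-level F1 keeps
  improving with training-set size (tested at 50/200/660 records).
  Duplicate sentences are planted within records at rate 0.3, and 5% of
  training sentences lose one span from their annotation (gold labels stay
  clean).
* **Linking fixture**: 50 symptoms whose translated bag exactly matches one
  concept term (under the frozen normalization, with shuffled word order
  and `"Fever, High"`-style casing), 50 near-misses differing by one word,
  and a handful of untranslatable names; every bag is unique, so the gold
  link set is exact by construction.

What the generators do **not** emulate: the statistical texture of real
clinical language (long-range discourse, abbreviation noise, segmentation
errors), real encyclopedia category graphs, or translation ambiguity.
Passing tests therefore demonstrate that each algorithm recovers what it is
defined to recover under controlled perturbations — not field performance
on hospital corpora, which would require data none of which can ship here.

## Problem sizes and numerics

The test suite and the acceptance script run the fusion fixture at
100 + 100 entities, the encyclopedia corpus at 210 pages with ten-fold
cross-validation, the EMR corpus at 1,000 records with the 660/340 split
and learning-curve points at 50/200/660, and the linking fixture at
50 + 50 — sizes chosen so every property is exercised at meaningful scale
while a full run stays in the low minutes on one core.  L-BFGS runs at most
150 iterations with `factr = 1e7`; the CRF's L2 weight (1.0) is the
conventional default for feature sets of this size.  LCS uses a rolling
single-row dynamic program; equality with an exhaustive subsequence oracle
is property-tested on short strings.

## Known limitations

Fusion compares all same-type pairs quadratically (with the commonness
prune); very large KBs would need blocking.  The RDF layer parses the
subset it emits, not arbitrary Turtle.  The CRF ships with no
regularization-path search — the study-condition corpora are insensitive to
`l2` within an order of magnitude.  Attribute-value conflicts after a merge
are kept as a multi-valued union rather than reconciled; the merge-audit
table is the hook for manual review.
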