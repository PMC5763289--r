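# symkb — a symptom-centric Chinese medical knowledge base, built end to end

Chinese-language electronic medical records (EMRs) cannot be processed
automatically without a knowledge base (KB) of the symptoms they mention —
and symptoms, the starting point of clinical diagnosis, are exactly where
Chinese-language medical KBs are thinnest.  `symkb` is an R toolkit that
constructs such a KB from heterogeneous sources and publishes it as Linked
Data:

1. **Wrapper extraction** — entities and attribute–value pairs from the
   "property box" of healthcare-site detail pages, driven by per-site YAML
   wrappers; heuristic subtyping into TCM / Western-medicine symptoms and
   medicines; synonym (`sameAs`) pairs harvested from abstracts with
   two-slot lexico-syntactic patterns.
2. **Encyclopedia bootstrapping** — entities from healthcare sites act as
   seeds; every page category is scored by its *seed ratio* and pages
   carrying low-confidence categories are dropped as noise; survivors are
   classified into seven entity types by a decision tree over 26 features
   from the five page fields.
3. **CRF symptom recognition** — a linear-chain conditional random field
   (exact forward–backward training, Viterbi decoding) over 37
   literal/position/POS n-gram templates in a ±3 window recognizes symptom
   spans (BIO-encoded) in deduplicated EMR sentences; separate models for
   TCM and Western symptoms, trained from their respective record fields.
4. **Fusion** — duplicate entities across sources merge when
   *commonness* × *relatedness* exceeds a threshold, where commonness is
   the character-level similarity |LCS(a, b)| / max(|a|, |b|) of the names
   and relatedness the similar share of shared attribute values; clusters
   are closed transitively and keep the highest-priority source's name.
5. **Cross-lingual linking** — symptom names are translated (pluggable,
   deterministic lexicon), reduced to bags of words, and linked to a
   UMLS-style concept table only at Jaccard similarity exactly 1; stored
   links re-verify from scratch.
6. **Linked Data export** — Turtle / N-Triples serialization with hashed
   entity IRIs, `rdfs:label` names, class assertions per concept type and
   reified fact provenance; `parse(serialize(kb))` is the identity.

Because the original inputs (hospital EMR corpora, licensed terminology
releases, commercial translation APIs, 2016-era site snapshots) cannot be
shipped, the package includes first-class **synthetic-data generators**
with planted ground truth for every input, so the entire pipeline runs,
is tested, and is evaluated fully offline.

## Worked example

```r
library(symkb)

# generate a two-site healthcare corpus and extract it
site_dir <- tempfile("site")
site <- generate_healthcare_site(site_dir, site_config(seed = 7))
wrappers <- load_wrappers(site$wrapper_path)
kb <- kb_new()
for (s in names(wrappers))
  kb <- extract_website(file.path(site_dir, s), wrappers[[s]], kb)
st <- kb_statistics(kb)
st$n_entities
#> [1] 61
st$entities_by_type[c("Symptom", "TCMSymptom", "Disease", "Medicine")]
#>    Symptom TCMSymptom    Disease   Medicine
#>         19          7         14         12
```

61 distinct entities were extracted from the two pseudo-sites; 19 are
symptoms, 7 of which carry the TCM subtype.  Fusing cross-site duplicates
collapses the store and records every pair decision in an audit table:

```r
fused <- kb_fuse(kb, product_threshold = 0.5, priority = site$sites)
length(fused$kb$entities)
#> [1] 37
head(fused$audit[fused$audit$merged,
                 c("a_name", "b_name", "commonness", "relatedness", "product")], 3)
#>   a_name b_name commonness relatedness   product
#> 1   肺闷   肺闷  1.0000000           1 1.0000000
#> 2   脾晕 脾光晕  0.6666667           1 0.6666667
#> 3   眼鸣 眼鸣症  0.6666667           1 0.6666667
```

A symptom recognizer trained on 132 synthetic EMRs decodes unseen records
at entity level:

```r
corpus <- generate_emr_corpus(emr_config(seed = 17, n_records = 200))
split <- split_records(corpus$truth$record_ids, n_train = 132, seed = 5)
model <- train_crf(corpus_sequences(corpus, "western", split$train,
                                    use_train_labels = TRUE), target = "western")
ev <- evaluate_crf(model, corpus_sequences(corpus, "western", split$test))
round(c(precision = ev$precision, recall = ev$recall, f1 = ev$f1), 4)
#> precision    recall        f1
#>    1.0000    0.9849    0.9924
decode_crf(model, c("患者", "自述", "腰部", "灼痛", "三天", "。"),
           c("n", "v", "n", "n", "t", "w"))
#>   start end     text
#> 1     3   4 腰部灼痛
```

Linking against the synthetic bilingual lexicon and concept table returns
exactly the planted exact-bag matches (the lexicon's "translations" are
synthetic word bags, not real glosses):

```r
fx <- generate_linking_fixture(link_config(seed = 19))
links <- link_symptoms(fx$symptoms, make_lexicon_translator(fx$lexicon),
                       fx$concepts)
nrow(links)
#> [1] 50
head(links[, c("symptom_name", "translation", "cui", "term")], 3)
#>   symptom_name                  translation      cui                           term
#> 1         口闷 palpitation insomnia itching C0000001 Insomnia, Itching, Palpitation
#> 2         膝闷                        cough C0000002                          Cough
#> 3         胸麻                   cough rash C0000003                    Cough, Rash
```

Finally, `serialize_rdf(kb, "turtle")` / `serialize_rdf(kb, "ntriples")`
export the KB as Linked Data and `parse_rdf()` reads it back losslessly.

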