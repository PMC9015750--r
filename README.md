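# medlit

Literacy-aware annotation of medical text.

Most patient-facing documents — discharge instructions, medication leaflets,
consent forms — are written above the reading level of the people who must
act on them. `medlit` implements the full pipeline needed to adapt such
documents to an individual reader:

1. **Literacy screening** with the three-parameter logistic IRT model,
   `P = c + (1 − c) / (1 + exp(−a(θ − b)))`: EAP ability estimation under a
   standard-normal prior (θ = 0 is the population average), MAP-EM item
   calibration, and information-based short-form construction that keeps
   the `n` most informative items after removing non-discriminating ones.
2. **Medical entity recognition** with a BiLSTM-CNN-CRF tagger (character
   CNN + word embeddings + bidirectional LSTM + exact CRF decoding) over
   BIO tags for diseases, problems, drugs and tests — implemented from
   scratch in R with hand-derived, finite-difference-verified gradients.
3. **Entity linking** to a JSONL knowledge base: character-trigram TF-IDF
   cosine kNN candidate generation, then vector-space word-sense
   disambiguation from unigram/bigram/collocation context features.
4. **Term difficulty** classification (easy / medium / difficult) from a
   character-level neural encoder plus lexical features, with gold labels
   derived from a 6-annotator vote rule (6 → easy, 4–5 → medium,
   <4 → difficult).
5. **Personalized annotation**: high-literacy readers see only difficult
   terms, low-literacy readers see medium and difficult terms, easy terms
   are never annotated; each annotation carries the concept's definition
   and its taxonomic/associative neighbours.

A synthetic-data module generates knowledge bases with controlled alias
ambiguity, gold-tagged corpora, 3PL response matrices and vote-labelled
difficulty datasets, so every stage is testable offline with known ground
truth. See `vignettes/medlit-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

```r
library(medlit)

spec <- synth_spec(seed = 7)            # desk-scale study conditions
kb   <- synth_kb(spec)                  # 50 pseudo-medical concepts
corp <- synth_ner_corpus(kb, spec)      # 30 gold-tagged sentences

# -- literacy: score one simulated respondent on a 30-item bank
items <- synth_items(spec)
resp  <- synth_responses(items, 1, seed = 42)
estimate_ability_eap(resp$values[1, ], items)
#> theta = 1.612 (se 0.387, 30 items) -> high literacy

shorten_test(items, 5)                  # 5 most informative items
#> [1] "item10" "item13" "item16" "item21" "item26"

# -- train the pipeline artifacts
tagger <- train_tagger(corp$sentences, seed = 7)
ds     <- synth_difficulty_dataset(spec)
diffm  <- train_difficulty_classifier(ds[, c("term", "label")], kb = kb,
                                      config = difficulty_config(epochs = 60),
                                      seed = 7)
models <- list(tagger = tagger, difficulty = diffm, index = build_index(kb),
               kb = kb, sense_model = train_sense_model(kb))

# -- annotate the same document for two readers
doc <- corp$sentences[[1]]$text
annotate_document(doc, "low", models)
#> <medlit_annotated> literacy=low, 2 annotation(s)
#>   [43,54) na piapadae        difficult -> C0032
#>   [65,76) si piapadae        medium    -> C0032
annotate_document(doc, "high", models)
#> <medlit_annotated> literacy=high, 1 annotation(s)
#>   [43,54) na piapadae        difficult -> C0032
```

The theta of 1.612 places this simulated respondent well above the
population average, so only terms classified *difficult* would be annotated
for them; the low-literacy view additionally explains *medium* terms.
`annotated_json()` renders the result as canonical (byte-stable) JSON;
`annotated_html()` produces a highlighted view.

A thin command-line front end over the same functions ships in
`inst/cli/medlit.R`:

```sh
Rscript inst/cli/medlit.R synth responses --out data --seed 3
Rscript inst/cli/medlit.R literacy score --items data/items.csv \
    --responses data/responses.csv
Rscript inst/cli/medlit.R literacy shorten --items data/items.csv -n 15
```

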