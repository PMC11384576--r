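#!/usr/bin/env Rscript
# Stage 2 — build the health lexicon.
#
# Trains CBOW embeddings on the co-occurrence corpus, expands the seed set
# by maximum cosine similarity, and curates the result: the accept list is
# the set of planted synonyms recovered among the candidates, standing in
# for the study's expert verification of the expanded vocabulary.

suppressPackageStartupMessages(library(hpagtwr))

out <- "results/study"
cooc <- readLines(file.path(out, "cooccurrence_corpus.txt"))
seeds <- read_word_list(file.path(out, "seeds.txt"))
synonyms <- read_word_list(file.path(out, "synonyms.txt"))

emb <- train_embeddings(cooc, dim = 100, window = 5, epochs = 20,
                        min_count = 5, seed = 43)
write_embeddings(emb, file.path(out, "embeddings.txt"))
cat(sprintf("Trained %d-word vocabulary, %d dimensions.\n",
            length(emb$vocab), emb$meta$dim))

cand <- expand_seed_set(emb, seeds, top_k = 500, min_similarity = 0.3)
write.csv(cand, file.path(out, "candidates.csv"), row.names = FALSE)
recovered <- intersect(cand$word, synonyms)
cat(sprintf("Expansion: %d candidates above 0.3; %d of %d planted synonyms recovered.\n",
            nrow(cand), length(recovered), length(synonyms)))

lex <- curate_lexicon(seeds, cand, accept = recovered)
write_word_list(lex$curated, file.path(out, "lexicon.txt"))
write.csv(lex$provenance, file.path(out, "lexicon_provenance.csv"),
          row.names = FALSE)
print(lex)
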