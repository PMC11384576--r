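#!/usr/bin/env Rscript
# Stage 1 — simulate the study frame.
#
# Builds the synthetic national frame the rest of the analysis runs on:
# 323 cities placed on a 3000 km square, a 2018-2021 covariate panel drawn
# from the published variable moments, a dependent variable generated from
# the varying-coefficient model with Table-calibrated surfaces (east-west
# gradient + pandemic step), and the co-occurrence corpus the lexicon stage
# trains its embeddings on.

suppressPackageStartupMessages(library(hpagtwr))

seed <- 42
out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

grid <- generate_city_grid(n_cities = 323, extent_km = 3000, seed = seed)
cat(sprintf("Placed %d cities; capital is city %d.\n",
            nrow(grid), attr(grid, "capital_id")))

surfaces <- study_surface_set(extent_km = 3000, noise_sd = 0.22)
gp <- generate_panel(grid, 2018:2021, surfaces, default_covariate_specs(),
                     seed = seed + 1)
write_panel(gp$panel, file.path(out, "panel_truth.csv"))
write.csv(gp$truth, file.path(out, "coefficient_truth.csv"),
          row.names = FALSE)

cat(sprintf("Panel: %d observations. True HPA mean %.3f (sd %.3f);\n",
            nrow(gp$panel), mean(gp$panel$y), sd(gp$panel$y)))
cat(sprintf("  before 2020: %.3f, from 2020: %.3f.\n",
            mean(gp$panel$y[gp$panel$t < 2020]),
            mean(gp$panel$y[gp$panel$t >= 2020])))

vocab <- default_vocab()  # 50 seeds + 361 synonyms -> 411-word target lexicon
cooc <- generate_cooccurrence_corpus(vocab$seeds, vocab$synonyms,
                                     vocab$distractors,
                                     n_sentences = 12000, seed = seed + 2)
writeLines(cooc, file.path(out, "cooccurrence_corpus.txt"))
write_word_list(vocab$seeds, file.path(out, "seeds.txt"))
write_word_list(vocab$synonyms, file.path(out, "synonyms.txt"))
write_word_list(c(vocab$distractors, vocab$filler),
                file.path(out, "filler.txt"))
cat(sprintf("Wrote %d training sentences and the word inventories to %s.\n",
            length(cooc), out))
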