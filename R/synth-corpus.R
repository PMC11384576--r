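#' Generate a document corpus with planted health-term shares
#'
#' For every panel row, writes one synthetic "government work report" of
#' `doc_length` opaque tokens in which the share of health-vocabulary tokens
#' is `round(target_hpa * doc_length / 100) / doc_length`. Scoring such a
#' document against a lexicon equal to `health_vocab` recovers `target_hpa`
#' up to the quantization bound `100 / (2 * doc_length)`.
#'
#' @param panel Panel data frame with `city_id` and `t` columns.
#' @param target_hpa Per-row target index on the percent scale, in
#'   `[0, 100]`; defaults to `panel$y`.
#' @param doc_length Tokens per document (default 5000, so quantization error
#'   is at most 0.01 on the percent scale).
#' @param health_vocab,filler_vocab Disjoint character vectors to sample
#'   health and filler tokens from.
#' @param seed Integer seed.
#'
#' @return A data.frame with columns `city_id`, `year`, `text` (class
#'   `document_set`), one row per panel row.
#' @export
generate_corpus <- function(panel, target_hpa = panel$y, doc_length = 5000,
                            health_vocab, filler_vocab, seed) {
  stopifnot(is.data.frame(panel), all(c("city_id", "t") %in% names(panel)))
  if (doc_length < 1) stop("`doc_length` must be >= 1", call. = FALSE)
  if (length(target_hpa) != nrow(panel)) {
    stop("`target_hpa` must have one value per panel row", call. = FALSE)
  }
  if (any(!is.finite(target_hpa)) || any(target_hpa < 0 | target_hpa > 100)) {
    stop("`target_hpa` values must lie in [0, 100]", call. = FALSE)
  }
  if (length(intersect(health_vocab, filler_vocab)) > 0) {
    stop("health and filler vocabularies must be disjoint ",
         "(overlap would break the score round-trip)", call. = FALSE)
  }

  n_health <- as.integer(round(target_hpa * doc_length / 100))
  texts <- with_seed(seed, {
    vapply(seq_len(nrow(panel)), function(i) {
      nh <- n_health[i]
      toks <- c(
        if (nh > 0) sample(health_vocab, nh, replace = TRUE),
        if (doc_length - nh > 0) {
          sample(filler_vocab, doc_length - nh, replace = TRUE)
        }
      )
      paste(sample(toks), collapse = " ")
    }, character(1))
  })

  structure(
    data.frame(city_id = panel$city_id, year = panel$t, text = texts),
    class = c("document_set", "data.frame")
  )
}

#' Generate a co-occurrence corpus with planted synonym structure
#'
#' Builds sentences from two disjoint families of context templates: seeds
#' and their planted synonyms are embedded in shared "health" contexts, while
#' distractors only ever appear in unrelated contexts. Embeddings trained on
#' this corpus should therefore place synonyms nearer the seeds than any
#' distractor, which makes the corpus an oracle for lexicon expansion.
#'
#' @param seeds,synonyms,distractors Disjoint character vectors; `seeds`
#'   non-empty.
#' @param n_sentences Number of sentences (>= 1).
#' @param seed Integer seed.
#' @param context_size Number of context tokens on each side of the target.
#' @param n_templates Number of distinct context words per template family.
#'
#' @return Character vector of whitespace-joined sentences.
#' @export
generate_cooccurrence_corpus <- function(seeds, synonyms, distractors,
                                         n_sentences, seed,
                                         context_size = 2, n_templates = 8) {
  if (length(seeds) == 0) stop("`seeds` must be non-empty", call. = FALSE)
  if (n_sentences < 1) stop("`n_sentences` must be >= 1", call. = FALSE)
  all_words <- c(seeds, synonyms, distractors)
  if (anyDuplicated(all_words)) {
    stop("seed, synonym and distractor lists must be disjoint", call. = FALSE)
  }

  health_ctx <- sprintf("ctx_health_%02d", seq_len(n_templates))
  other_ctx <- sprintf("ctx_other_%02d", seq_len(n_templates))
  health_targets <- c(seeds, synonyms)

  with_seed(seed, {
    vapply(seq_len(n_sentences), function(i) {
      if (length(distractors) > 0 && runif(1) < 0.5) {
        target <- sample(distractors, 1)
        ctx <- sample(other_ctx, 2 * context_size, replace = TRUE)
      } else {
        target <- sample(health_targets, 1)
        ctx <- sample(health_ctx, 2 * context_size, replace = TRUE)
      }
      paste(c(ctx[seq_len(context_size)], target,
              ctx[context_size + seq_len(context_size)]),
            collapse = " ")
    }, character(1))
  })
}

#' Default synthetic vocabularies
#'
#' Opaque token inventories for the synthetic pipeline: `n_seeds` seed words,
#' `n_synonyms` planted synonyms, `n_distractors` distractor words and
#' `n_filler` generic filler words. The default 50 + 361 split makes the
#' curated lexicon 411 words when every synonym is accepted.
#'
#' @param n_seeds,n_synonyms,n_distractors,n_filler Inventory sizes.
#' @return A list with components `seeds`, `synonyms`, `distractors`,
#'   `filler`.
#' @export
default_vocab <- function(n_seeds = 50, n_synonyms = 361,
                          n_distractors = 100, n_filler = 2000) {
  list(
    seeds = sprintf("health_seed_%03d", seq_len(n_seeds)),
    synonyms = sprintf("health_syn_%03d", seq_len(n_synonyms)),
    distractors = sprintf("policy_word_%03d", seq_len(n_distractors)),
    filler = sprintf("filler_%04d", seq_len(n_filler))
  )
}
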