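#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length and nonzero norm.
#' @return `dot(a, b) / (|a| |b|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have the same dimension", call. = FALSE)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity is undefined for a zero-norm vector",
         call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Expand a seed word set by embedding similarity
#'
#' Scores every non-seed vocabulary word by its maximum cosine similarity to
#' any in-vocabulary seed, ranks candidates by score (descending, ties broken
#' lexicographically so results are reproducible), and keeps the top `top_k`
#' with score at least `min_similarity`.
#'
#' @param embeddings An `embedding_table` from [train_embeddings()].
#' @param seeds Character vector of seed words; at least one must be in the
#'   vocabulary.
#' @param top_k Maximum number of candidates returned.
#' @param min_similarity Minimum score retained (default -1, i.e. no cut).
#'
#' @return A data.frame with columns `word`, `score`, `nearest_seed`, sorted
#'   by decreasing score.
#' @export
expand_seed_set <- function(embeddings, seeds, top_k,
                            min_similarity = -1) {
  stopifnot(inherits(embeddings, "embedding_table"))
  if (top_k < 0) stop("`top_k` must be >= 0", call. = FALSE)
  in_vocab <- intersect(seeds, embeddings$vocab)
  if (length(in_vocab) == 0) {
    stop("no seed word is in the embedding vocabulary; missing: ",
         paste(seeds, collapse = ", "), call. = FALSE)
  }

  m <- embeddings$vectors
  norms <- sqrt(rowSums(m^2))
  ok <- norms > 0
  unit <- m[ok, , drop = FALSE] / norms[ok]
  sims <- unit %*% t(unit[in_vocab, , drop = FALSE])

  cand <- setdiff(rownames(unit), seeds)
  if (length(cand) == 0 || top_k == 0) {
    return(data.frame(word = character(0), score = numeric(0),
                      nearest_seed = character(0)))
  }
  s <- sims[cand, , drop = FALSE]
  best <- max.col(s, ties.method = "first")
  out <- data.frame(
    word = cand,
    score = s[cbind(seq_along(cand), best)],
    nearest_seed = in_vocab[best]
  )
  out <- out[order(-out$score, out$word), , drop = FALSE]
  out <- out[out$score >= min_similarity, , drop = FALSE]
  out <- head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Curate the expanded lexicon
#'
#' Replaces the study's expert verification step with an explicit accept
#' list: the curated lexicon is the union of the seeds and the accepted
#' candidates, with per-word provenance (seed vs expanded, similarity score)
#' retained.
#'
#' @param seeds Character vector of seed words.
#' @param candidates Ranked candidate data.frame from [expand_seed_set()].
#' @param accept Character vector of accepted candidate words; must be a
#'   subset of `candidates$word`.
#' @return An object of class `hpa_lexicon` with components `seeds`,
#'   `candidates`, `curated` and `provenance`.
#' @export
curate_lexicon <- function(seeds, candidates, accept = character(0)) {
  stopifnot(is.character(seeds), is.data.frame(candidates))
  unknown <- setdiff(accept, candidates$word)
  if (length(unknown) > 0) {
    stop("accepted word(s) not among candidates: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  accepted <- candidates[candidates$word %in% accept, , drop = FALSE]
  provenance <- data.frame(
    word = c(seeds, accepted$word),
    origin = rep(c("seed", "expanded"), c(length(seeds), nrow(accepted))),
    score = c(rep(NA_real_, length(seeds)), accepted$score),
    nearest_seed = c(rep(NA_character_, length(seeds)),
                     accepted$nearest_seed)
  )
  structure(
    list(seeds = seeds, candidates = candidates,
         curated = c(seeds, accepted$word), provenance = provenance),
    class = "hpa_lexicon"
  )
}

#' @export
print.hpa_lexicon <- function(x, ...) {
  cat(sprintf("Health lexicon: %d seed + %d expanded = %d curated words\n",
              length(x$seeds), length(x$curated) - length(x$seeds),
              length(x$curated)))
  invisible(x)
}

# Coerce a lexicon argument to its curated word vector.
lexicon_words <- function(lexicon) {
  if (inherits(lexicon, "hpa_lexicon")) lexicon$curated
  else if (is.character(lexicon)) lexicon
  else stop("`lexicon` must be an hpa_lexicon or a character vector",
            call. = FALSE)
}

#' Read and write word lists and candidate tables
#'
#' Word lists are UTF-8 plain text, one word per line; candidate tables are
#' CSV with columns `word`, `score`, `nearest_seed`.
#'
#' @param words Character vector.
#' @param path File path.
#' @name lexicon_io
#' @export
write_word_list <- function(words, path) {
  writeLines(words, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname lexicon_io
#' @export
read_word_list <- function(path) {
  w <- readLines(path, encoding = "UTF-8")
  w[nzchar(w)]
}
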