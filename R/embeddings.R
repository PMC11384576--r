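#' Train CBOW word embeddings
#'
#' Trains continuous bag-of-words (CBOW) word vectors with negative sampling:
#' each centre word is predicted from the mean of its context vectors within
#' a (randomly reduced) window, maximising
#' \eqn{\sum_{w \in C} \log p(w \mid \mathrm{Context}(w))}. Training is
#' single-threaded with its own seeded generator, so identical inputs give
#' bit-identical vectors.
#'
#' @param corpus Character vector of whitespace-tokenized sentences, or a
#'   list of token vectors.
#' @param dim Embedding dimension (>= 2).
#' @param window Maximum context window on each side of the centre word.
#' @param epochs Passes over the corpus.
#' @param min_count Words occurring fewer than `min_count` times are dropped
#'   from the vocabulary.
#' @param seed Integer seed.
#' @param negative Negative samples per positive example.
#' @param alpha Initial learning rate (linearly decayed).
#'
#' @return An object of class `embedding_table`: list with `vectors` (matrix,
#'   one row per word), `vocab`, `counts` and `meta` (the hyperparameters).
#' @export
train_embeddings <- function(corpus, dim = 100, window = 5, epochs = 20,
                             min_count = 5, seed = 1, negative = 5,
                             alpha = 0.05) {
  if (length(corpus) == 0) stop("`corpus` is empty", call. = FALSE)
  if (dim < 2) stop("`dim` must be >= 2", call. = FALSE)
  sentences <- if (is.character(corpus)) {
    strsplit(corpus, "\\s+")
  } else if (is.list(corpus)) {
    corpus
  } else {
    stop("`corpus` must be a character vector or a list of token vectors",
         call. = FALSE)
  }
  sentences <- lapply(sentences, function(s) s[nzchar(s)])

  counts <- table(unlist(sentences, use.names = FALSE))
  keep <- counts[counts >= min_count]
  if (length(keep) == 0) {
    stop(sprintf(paste0("no word reaches min_count = %d ",
                        "(max observed frequency %d); corpus too small"),
                 min_count, if (length(counts)) max(counts) else 0L),
         call. = FALSE)
  }
  # frequency-descending order (ties lexicographic) for a deterministic
  # vocabulary and negative-sampling table
  ord <- order(-as.integer(keep), names(keep))
  vocab <- names(keep)[ord]
  freq <- as.integer(keep)[ord]

  idx <- seq_along(vocab) - 1L
  names(idx) <- vocab
  sent_idx <- lapply(sentences, function(s) {
    m <- idx[match(s, vocab)]
    as.integer(m[!is.na(m)])
  })
  sent_idx <- sent_idx[lengths(sent_idx) > 0]
  if (length(sent_idx) == 0) {
    stop("corpus has no sentences left after vocabulary filtering",
         call. = FALSE)
  }

  vectors <- .cbow_train_cpp(sent_idx, freq, as.integer(dim),
                             as.integer(window), as.integer(epochs),
                             as.integer(negative), alpha, as.integer(seed))
  rownames(vectors) <- vocab
  structure(
    list(vectors = vectors, vocab = vocab, counts = freq,
         meta = list(dim = dim, window = window, epochs = epochs,
                     min_count = min_count, seed = seed,
                     negative = negative, alpha = alpha)),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("CBOW embeddings: %d words x %d dimensions (window %d, %d epochs)\n",
              length(x$vocab), x$meta$dim, x$meta$window, x$meta$epochs))
  invisible(x)
}

#' Persist embeddings in the word2vec text format
#'
#' Writes (or reads back) the standard text format: a header line
#' `"<vocab_size> <dim>"` followed by one `word v1 v2 ...` line per word.
#'
#' @param embeddings An `embedding_table`.
#' @param path File path.
#' @return `read_embeddings()` returns an `embedding_table` (without training
#'   metadata beyond the dimension).
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(inherits(embeddings, "embedding_table"))
  m <- embeddings$vectors
  lines <- c(
    sprintf("%d %d", nrow(m), ncol(m)),
    vapply(seq_len(nrow(m)), function(i) {
      paste(rownames(m)[i],
            paste(formatC(m[i, ], format = "g", digits = 17), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_embeddings
#' @param path File path.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  n <- hdr[1]; d <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, character(1), 1)
  vectors <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vectors) <- vocab
  structure(
    list(vectors = vectors, vocab = vocab, counts = NULL,
         meta = list(dim = d)),
    class = "embedding_table"
  )
}
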