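#' Tokenize a document
#'
#' Default mode lowercases and splits on runs of whitespace. A custom
#' segmenter (e.g. a Chinese word segmenter) can be injected as any function
#' mapping a string to a character vector of tokens.
#'
#' @param text A single string.
#' @param segmenter Optional function `f(text) -> character vector`; when
#'   supplied it fully replaces the whitespace rule.
#' @return Character vector of tokens (empty for empty text).
#' @examples
#' tokenize("Health  policy  health")
#' @export
tokenize <- function(text, segmenter = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.null(segmenter)) {
    stopifnot(is.function(segmenter))
    return(segmenter(text))
  }
  toks <- strsplit(tolower(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Compute the health policy attention index of one document
#'
#' The HPA index is the share of token occurrences belonging to the curated
#' health lexicon, times 100: `100 * n_lexicon_tokens / n_tokens`. Counts are
#' occurrences, not unique types, so the score is invariant to token order
#' and to duplicating the document.
#'
#' @param tokens Non-empty character vector of tokens.
#' @param lexicon An `hpa_lexicon` or a character vector of lexicon words.
#' @return The index on the percent scale, in `[0, 100]`.
#' @examples
#' compute_hpa(c(rep("health", 5), rep("x", 395)), "health")  # 1.25
#' @export
compute_hpa <- function(tokens, lexicon) {
  if (length(tokens) == 0) {
    stop("cannot score an empty document (zero total term frequency)",
         call. = FALSE)
  }
  words <- lexicon_words(lexicon)
  100 * sum(tokens %in% words) / length(tokens)
}

#' Score a corpus of city-year documents
#'
#' Computes the HPA index per (city_id, year) key. Multiple documents under
#' the same key are pooled (token lists concatenated) before scoring unless
#' `merge = FALSE`, in which case duplicate keys are an error. Keys expected
#' but absent from the corpus are reported via a warning and the
#' `missing_keys` attribute, never silently dropped.
#'
#' @param documents A data.frame with columns `city_id`, `year` and either
#'   `text` (strings, tokenized with [tokenize()]) or `tokens` (list of token
#'   vectors).
#' @param lexicon An `hpa_lexicon` or character vector.
#' @param merge Pool multiple documents per key (default `TRUE`).
#' @param expected Optional data.frame of `city_id`, `year` keys that should
#'   all be present.
#' @param segmenter Optional tokenizer override passed to [tokenize()].
#' @return A data.frame `city_id`, `year`, `hpa`, one row per key, with
#'   attribute `missing_keys`.
#' @export
score_corpus <- function(documents, lexicon, merge = TRUE, expected = NULL,
                         segmenter = NULL) {
  stopifnot(is.data.frame(documents),
            all(c("city_id", "year") %in% names(documents)))
  key <- paste(documents$city_id, documents$year, sep = "\r")
  if (!merge && anyDuplicated(key)) {
    dup <- documents[duplicated(key), c("city_id", "year"), drop = FALSE]
    stop("duplicate (city_id, year) keys with merge disabled: ",
         paste(unique(paste0("(", dup$city_id, ", ", dup$year, ")")),
               collapse = ", "),
         call. = FALSE)
  }

  token_lists <- if ("tokens" %in% names(documents)) {
    documents$tokens
  } else if ("text" %in% names(documents)) {
    lapply(documents$text, tokenize, segmenter = segmenter)
  } else {
    stop("`documents` needs a `text` or `tokens` column", call. = FALSE)
  }

  groups <- split(seq_along(key), key)
  first <- vapply(groups, `[[`, integer(1), 1L)
  words <- lexicon_words(lexicon)
  hpa <- vapply(groups, function(ix) {
    toks <- unlist(token_lists[ix], use.names = FALSE)
    compute_hpa(toks, words)
  }, numeric(1))

  out <- data.frame(
    city_id = documents$city_id[first],
    year = documents$year[first],
    hpa = unname(hpa)
  )
  out <- out[order(out$year, out$city_id), , drop = FALSE]
  rownames(out) <- NULL

  missing_keys <- NULL
  if (!is.null(expected)) {
    want <- paste(expected$city_id, expected$year, sep = "\r")
    lost <- !(want %in% key)
    if (any(lost)) {
      missing_keys <- expected[lost, c("city_id", "year"), drop = FALSE]
      warning(sprintf("%d expected (city_id, year) key(s) have no document",
                      sum(lost)), call. = FALSE)
    }
  }
  attr(out, "missing_keys") <- missing_keys
  out
}
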