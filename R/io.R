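# File formats: panel CSV, corpus JSONL, JSON reports, local-coefficient
# CSV/GeoJSON exports.

PANEL_REQUIRED <- c("city_id", "u", "v", "t", "y")

#' Read and write the city-year panel CSV
#'
#' The panel schema is `city_id, u, v, t, y, <covariates...>`. Reading
#' validates the schema and fails with the missing column names; the
#' write/read round trip is lossless for finite values.
#'
#' @param path CSV file path.
#' @param panel Panel data frame.
#' @return `read_panel()` returns the panel data frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  panel <- read.csv(path, check.names = FALSE)
  missing <- setdiff(PANEL_REQUIRED, names(panel))
  if (length(missing) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- c("u", "v", "t", "y")
  bad <- !vapply(panel[numeric_cols],
                 function(col) is.numeric(col) && all(is.finite(col)),
                 logical(1))
  if (any(bad)) {
    col <- numeric_cols[which(bad)[1]]
    row <- which(!is.finite(suppressWarnings(as.numeric(panel[[col]]))))[1]
    stop(sprintf("non-finite or non-numeric value in column '%s' (data row %s)",
                 col, ifelse(is.na(row), "?", row)), call. = FALSE)
  }
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' Read and write the document corpus (JSONL)
#'
#' One JSON object per line: `{"city_id": ..., "year": ..., "text": ...}`.
#' Blank lines are skipped with a warning (count reported via the
#' `n_skipped` attribute); malformed lines fail with their line number.
#'
#' @param path JSONL file path.
#' @param documents Data frame with `city_id`, `year`, `text`.
#' @return `read_corpus()` returns a `document_set` data frame.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  blank <- !nzchar(trimws(lines))
  n_skipped <- sum(blank)
  if (n_skipped > 0) {
    warning(sprintf("skipped %d blank line(s) in %s", n_skipped, path),
            call. = FALSE)
  }
  keep <- which(!blank)
  recs <- lapply(keep, function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) NULL)
    if (is.null(rec) || !all(c("city_id", "year", "text") %in% names(rec))) {
      stop(sprintf("malformed corpus record at line %d of %s", i, path),
           call. = FALSE)
    }
    rec
  })
  out <- data.frame(
    city_id = vapply(recs, function(r) as.integer(r$city_id), integer(1)),
    year = vapply(recs, function(r) as.integer(r$year), integer(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1))
  )
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("document_set", "data.frame")
  out
}

#' @rdname read_corpus
#' @export
write_corpus <- function(documents, path) {
  stopifnot(is.data.frame(documents),
            all(c("city_id", "year", "text") %in% names(documents)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(documents))) {
    writeLines(jsonlite::toJSON(
      list(city_id = documents$city_id[i], year = documents$year[i],
           text = documents$text[i]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Serialize a report or fit summary as JSON
#'
#' @param report Any list-like object (classes are dropped; data frames are
#'   written as row-wise records).
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Export local coefficients
#'
#' `write_coefficients_csv()` writes one row per observation:
#' `city_id, t, u, v, <coefficients...>, hat_ii`.
#' `write_coefficients_geojson()` writes the same as a GeoJSON
#' FeatureCollection of points (planar km coordinates) with the coefficients
#' as properties, for mapping.
#'
#' @param fit A [fit_gtwr()] result.
#' @param path Output path.
#' @export
write_coefficients_csv <- function(fit, path) {
  stopifnot(inherits(fit, "gtwr_fit"))
  coefs <- as.data.frame(fit$coefficients)
  names(coefs)[1] <- "beta_0"
  out <- cbind(fit$obs[, c("city_id", "t", "u", "v")], coefs,
               hat_ii = fit$hat)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients_csv
#' @export
write_coefficients_geojson <- function(fit, path) {
  stopifnot(inherits(fit, "gtwr_fit"))
  features <- lapply(seq_len(fit$n), function(i) {
    props <- as.list(fit$coefficients[i, ])
    names(props)[1] <- "beta_0"
    props$city_id <- fit$obs$city_id[i]
    props$t <- fit$obs$t[i]
    props$hat_ii <- fit$hat[i]
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(fit$obs$u[i], fit$obs$v[i])),
      properties = props
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
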