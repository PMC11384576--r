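# End-to-end pipeline: simulate (or ingest) -> lexicon -> score -> merge ->
# diagnostics -> fit -> report, with per-stage seeds fanned out from one
# global seed and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' The default configuration reproduces the synthetic study emulation: 323
#' cities over 2018-2021 on a 3000 km square, Table-calibrated covariates and
#' coefficient surfaces ([default_covariate_specs()], [study_surface_set()]),
#' 5000-token documents, a 50-seed/361-synonym vocabulary, CBOW training
#' (dim 100, window 5, 20 epochs, min_count 5), golden-section bandwidth
#' search, and k-nearest (k = 5) Moran's I with 999 permutations.
#'
#' @param seed Global seed fanned out deterministically to every stage.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 42) {
  list(
    mode = "simulate",
    seed = seed,
    simulate = list(
      n_cities = 323,
      extent_km = 3000,
      years = 2018:2021,
      noise_sd = 0.22,
      doc_length = 5000,
      vocab = list(n_seeds = 50, n_synonyms = 361, n_distractors = 100,
                   n_filler = 2000),
      cooccurrence = list(n_sentences = 12000)
    ),
    paths = list(panel = NULL, corpus = NULL, lexicon = NULL),
    cbow = list(dim = 100, window = 5, epochs = 20, min_count = 5,
                negative = 5, alpha = 0.05),
    expansion = list(top_k = 500, min_similarity = 0.3),
    kernel = list(family = "gaussian", lambda_s = NULL, mu_t = NULL,
                  grid = NULL, lo = NULL, hi = NULL, rel_tol = 0.01),
    diagnostics = list(k = 5, n_perm = 999, split_year = 2020)
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults from [default_config()];
#' everything else keeps its default.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A configuration list.
#' @examples
#' cfg <- read_config(system.file("extdata", "demo-config.yaml",
#'                                package = "hpagtwr"))
#' cfg$simulate$n_cities
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  merge_config(default_config(), user)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (or ingest) the panel and corpus,
#' build the lexicon (CBOW training, seed expansion, curation), score the
#' corpus, merge the scored index into the panel as the dependent variable,
#' run pre-fit diagnostics, fit OLS and CV-calibrated GTWR, and write every
#' artifact plus a manifest (config hash, per-stage seeds and timings, file
#' checksums) into `out_dir`. A failing stage aborts with the stage named;
#' artifacts already written are retained.
#'
#' @param config Configuration list (see [default_config()]) or a YAML/JSON
#'   path.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory objects (`panel`, `lexicon`,
#'   `scored`, `gtwr`, `ols`, `report`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  seeds <- list()
  timings <- list()
  result <- new.env(parent = emptyenv())

  stage <- function(name, fn) {
    seeds[[name]] <<- stage_seed(config$seed, name)
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fn(seeds[[name]]),
             error = function(e) {
               stop(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)), call. = FALSE)
             })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if (identical(config$mode, "simulate")) {
    stage("simulate", function(seed) {
      sim <- config$simulate
      grid <- generate_city_grid(sim$n_cities, sim$extent_km,
                                 seed = stage_seed(seed, "grid"))
      surfaces <- study_surface_set(sim$extent_km, noise_sd = sim$noise_sd)
      gp <- generate_panel(grid, sim$years, surfaces,
                           default_covariate_specs(),
                           seed = stage_seed(seed, "panel"))
      vocab <- do.call(default_vocab, sim$vocab)
      cooc <- generate_cooccurrence_corpus(
        vocab$seeds, vocab$synonyms, vocab$distractors,
        n_sentences = sim$cooccurrence$n_sentences,
        seed = stage_seed(seed, "cooccurrence"))
      result$grid <- grid
      result$panel <- gp$panel
      result$truth <- gp$truth
      result$vocab <- vocab
      result$cooc <- cooc
      write_panel(gp$panel, file.path(out_dir, "panel_truth.csv"))
      write.csv(gp$truth, file.path(out_dir, "coefficient_truth.csv"),
                row.names = FALSE)
    })
  } else if (identical(config$mode, "ingest")) {
    stage("ingest", function(seed) {
      if (is.null(config$paths$panel)) {
        stop("ingest mode requires `paths$panel`")
      }
      result$panel <- read_panel(config$paths$panel)
      if (!is.null(config$paths$corpus)) {
        result$corpus <- read_corpus(config$paths$corpus)
      }
      if (!is.null(config$paths$lexicon)) {
        words <- read_word_list(config$paths$lexicon)
        result$lexicon <- curate_lexicon(
          words, data.frame(word = character(0), score = numeric(0),
                            nearest_seed = character(0)))
      }
    })
  } else {
    stop("pipeline stage 'configure' failed: unknown mode '",
         config$mode, "'", call. = FALSE)
  }

  if (identical(config$mode, "simulate")) {
    stage("lexicon", function(seed) {
      cb <- config$cbow
      emb <- train_embeddings(result$cooc, dim = cb$dim, window = cb$window,
                              epochs = cb$epochs, min_count = cb$min_count,
                              negative = cb$negative, alpha = cb$alpha,
                              seed = seed)
      cand <- expand_seed_set(emb, result$vocab$seeds,
                              top_k = config$expansion$top_k,
                              min_similarity = config$expansion$min_similarity)
      accept <- intersect(cand$word, result$vocab$synonyms)
      result$embeddings <- emb
      result$lexicon <- curate_lexicon(result$vocab$seeds, cand, accept)
      write_embeddings(emb, file.path(out_dir, "embeddings.txt"))
      write_word_list(result$vocab$seeds, file.path(out_dir, "seeds.txt"))
      write.csv(cand, file.path(out_dir, "candidates.csv"), row.names = FALSE)
      write_word_list(result$lexicon$curated,
                      file.path(out_dir, "lexicon.txt"))
    })

    stage("corpus", function(seed) {
      sim <- config$simulate
      filler <- setdiff(c(result$vocab$filler, result$vocab$distractors),
                        result$lexicon$curated)
      result$corpus <- generate_corpus(
        result$panel, target_hpa = result$panel$y,
        doc_length = sim$doc_length,
        health_vocab = result$lexicon$curated,
        filler_vocab = filler, seed = seed)
      write_corpus(result$corpus, file.path(out_dir, "corpus.jsonl"))
    })
  }

  if (!is.null(result$corpus) && !is.null(result$lexicon)) {
    stage("score", function(seed) {
      scored <- score_corpus(result$corpus, result$lexicon,
                             expected = data.frame(
                               city_id = result$panel$city_id,
                               year = result$panel$t))
      result$scored <- scored
      write.csv(scored, file.path(out_dir, "hpa_scores.csv"),
                row.names = FALSE)
    })

    stage("merge", function(seed) {
      m <- match(paste(result$panel$city_id, result$panel$t),
                 paste(result$scored$city_id, result$scored$year))
      if (anyNA(m)) stop("scored index is missing panel keys")
      result$panel$y <- result$scored$hpa[m]
      write_panel(result$panel, file.path(out_dir, "panel.csv"))
    })
  }

  stage("fit", function(seed) {
    kern <- config$kernel
    lambda_s <- kern$lambda_s
    mu_t <- kern$mu_t
    if (is.null(lambda_s) || is.null(mu_t)) {
      sc <- st_scale_defaults(result$panel)
      if (is.null(lambda_s)) lambda_s <- sc$lambda_s
      if (is.null(mu_t)) mu_t <- sc$mu_t
    }
    if (!is.null(kern$grid)) {
      bw <- select_bandwidth(result$panel, lambda_s, mu_t, grid = kern$grid,
                             family = kern$family)
    } else {
      span <- max(dist(unique(result$panel[, c("u", "v")])))
      lo <- if (is.null(kern$lo)) span / 50 else kern$lo
      hi <- if (is.null(kern$hi)) span else kern$hi
      bw <- select_bandwidth(result$panel, lambda_s, mu_t, lo = lo, hi = hi,
                             tol = (hi - lo) * kern$rel_tol,
                             family = kern$family)
    }
    result$bandwidth <- bw
    result$gtwr <- fit_gtwr(result$panel, bw$params)
    result$ols <- fit_ols(result$panel)
    write.csv(bw$cv_curve, file.path(out_dir, "cv_curve.csv"),
              row.names = FALSE)
    write_coefficients_csv(result$gtwr,
                           file.path(out_dir, "local_coefficients.csv"))
    write_coefficients_geojson(result$gtwr,
                               file.path(out_dir, "local_coefficients.geojson"))
    write_report(list(
      h_star = bw$h_star, lambda_s = lambda_s, mu_t = mu_t,
      family = kern$family, trace_s = result$gtwr$trace_s,
      gtwr_aicc = result$gtwr$aicc, gtwr_adj_r2 = result$gtwr$adj_r2,
      ols_aicc = result$ols$aicc, ols_adj_r2 = result$ols$adj_r2
    ), file.path(out_dir, "fit_summary.json"))
  })

  stage("diagnose", function(seed) {
    dg <- config$diagnostics
    result$report <- diagnostics_report(
      result$panel, result$gtwr, result$ols, k = dg$k, n_perm = dg$n_perm,
      seed = seed, split_year = dg$split_year)
    write_report(result$report, file.path(out_dir, "diagnostics.json"))
    write.csv(result$report$coefficient_summary,
              file.path(out_dir, "coefficient_summary.csv"),
              row.names = FALSE)
    write.csv(result$report$period_averages,
              file.path(out_dir, "period_averages.csv"), row.names = FALSE)
  })

  stage("manifest", function(seed) {
    files <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
    manifest <- list(
      config_hash = config_hash(config),
      seed = config$seed,
      stage_seeds = seeds,
      timings_sec = timings,
      files = lapply(files, function(f) {
        list(name = basename(f), md5 = unname(tools::md5sum(f)))
      })
    )
    result$manifest <- manifest
    write_report(manifest, file.path(out_dir, "manifest.json"))
  })

  invisible(list(
    panel = result$panel, truth = result$truth, lexicon = result$lexicon,
    scored = result$scored, bandwidth = result$bandwidth, gtwr = result$gtwr,
    ols = result$ols, report = result$report, manifest = result$manifest
  ))
}
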