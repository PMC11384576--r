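test_that("city grids are bounded, deterministic and centre the capital", {
  g <- generate_city_grid(323, 1000, seed = 1)
  expect_equal(nrow(g), 323)
  expect_true(all(g$u >= 0 & g$u <= 1000 & g$v >= 0 & g$v <= 1000))
  expect_equal(anyDuplicated(g$city_id), 0L)

  g2 <- generate_city_grid(323, 1000, seed = 1)
  expect_identical(g, g2)

  g3 <- generate_city_grid(2, 10, seed = 7)
  d <- sqrt((g3$u - 5)^2 + (g3$v - 5)^2)
  expect_equal(attr(g3, "capital_id"), g3$city_id[which.min(d)])

  expect_error(generate_city_grid(1, 10, seed = 1), "at least 2")
  expect_error(generate_city_grid(-3, 10, seed = 1), "positive")
  expect_error(generate_city_grid(10, 0, seed = 1), "positive")
})

test_that("zero-noise constant surfaces reproduce the model equation exactly", {
  g <- generate_city_grid(10, 50, seed = 2)
  ss <- surface_set(surface_constant(1),
                    list(X1 = surface_constant(2)), noise_sd = 0)
  gp <- generate_panel(g, 2018, ss, recovery_covariate_specs(1), seed = 3)
  expect_equal(gp$panel$y, 1 + 2 * gp$panel$X1)
  expect_equal(dim(gp$truth), c(10L, 2L))
  expect_true(all(gp$truth[, "(Intercept)"] == 1 & gp$truth[, "X1"] == 2))
})

test_that("truth matrix is row-aligned with the panel under varying surfaces", {
  gp <- make_recovery_panel(n_cities = 30, seed = 4, noise_sd = 0)
  X <- cbind(1, as.matrix(gp$panel[, c("X1", "X2", "X3")]))
  expect_equal(gp$panel$y, rowSums(gp$truth * X), tolerance = 1e-12)
})

test_that("truncated-normal covariates match the published moments", {
  # independent oracle: closed-form truncated-normal mean
  m <- 13.3916; s <- 3.4073; lo <- 2.9340; hi <- 23.5260
  a <- (lo - m) / s; b <- (hi - m) / s
  mean_analytic <- m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))

  g <- generate_city_grid(323, 3000, seed = 5)
  gp <- generate_panel(g, 2018:2021, study_surface_set(3000),
                       default_covariate_specs(), seed = 6)
  age <- gp$panel$AGE65
  expect_equal(length(age), 1292L)
  expect_true(all(age >= lo & age <= hi))
  se <- s / sqrt(length(age))
  expect_lt(abs(mean(age) - mean_analytic), 3 * se)
  expect_lt(abs(mean(age) - 13.3916), 3 * se + abs(mean_analytic - 13.3916))
  expect_true(all(gp$panel$CT %in% c(0, 1)))
})

test_that("radial surfaces evaluate to their scale at the centre", {
  s <- surface_radial(0.7, range_km = 100, centre = c(10, 20))
  expect_equal(s(10, 20, 2018), 0.7)
  expect_equal(s(10, 120, 2018), 0.7 * exp(-1))
})

test_that("panel generation validates its configuration", {
  g <- generate_city_grid(5, 10, seed = 1)
  ss <- surface_set(surface_constant(1),
                    list(WRONG = surface_constant(1)), noise_sd = 0)
  expect_error(generate_panel(g, 2018, ss, recovery_covariate_specs(1),
                              seed = 1),
               "match covariate names")
  bad <- surface_set(surface_constant(1),
                     list(X1 = function(u, v, t) rep(NaN, length(u))),
                     noise_sd = 0)
  expect_error(generate_panel(g, 2018, bad, recovery_covariate_specs(1),
                              seed = 1),
               "not evaluable")
  ok <- surface_set(surface_constant(1),
                    list(X1 = surface_constant(1)), noise_sd = 0)
  expect_error(generate_panel(g, integer(0), ok, recovery_covariate_specs(1),
                              seed = 1),
               "non-empty")
})

test_that("generated documents carry the exact planted health-token count", {
  panel <- data.frame(city_id = 1:3, t = 2018, y = 0)
  vocab <- default_vocab(5, 5, 5, 50)
  docs <- generate_corpus(panel, target_hpa = c(1.25, 0, 50),
                          doc_length = 400, health_vocab = vocab$seeds,
                          filler_vocab = vocab$filler, seed = 8)
  n_health <- vapply(docs$text, function(tx) {
    sum(tokenize(tx) %in% vocab$seeds)
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(n_health, c(5, 0, 200))

  docs2 <- generate_corpus(panel, target_hpa = c(1.25, 0, 50),
                           doc_length = 400, health_vocab = vocab$seeds,
                           filler_vocab = vocab$filler, seed = 8)
  expect_identical(docs, docs2)

  expect_error(
    generate_corpus(panel, target_hpa = c(1, 1, 101), doc_length = 100,
                    health_vocab = vocab$seeds, filler_vocab = vocab$filler,
                    seed = 1),
    "\\[0, 100\\]")
  expect_error(
    generate_corpus(panel, target_hpa = c(1, 1, 1), doc_length = 100,
                    health_vocab = vocab$seeds,
                    filler_vocab = c(vocab$filler, vocab$seeds[1]), seed = 1),
    "disjoint")
})

test_that("corpus scores round-trip planted targets within quantization", {
  panel <- data.frame(city_id = 1, t = 2018, y = 0)
  vocab <- default_vocab(5, 5, 5, 50)
  docs <- generate_corpus(panel, target_hpa = 1.3089, doc_length = 10000,
                          health_vocab = vocab$seeds,
                          filler_vocab = vocab$filler, seed = 9)
  hpa <- compute_hpa(tokenize(docs$text[1]), vocab$seeds)
  expect_lt(abs(hpa - 1.3089), 100 / (2 * 10000))
})

test_that("co-occurrence corpora plant shared contexts for synonyms only", {
  corp <- generate_cooccurrence_corpus("s1", "y1", "d1", n_sentences = 500,
                                       seed = 3)
  toks <- strsplit(corp, " ")
  ctx_of <- function(word) {
    unique(unlist(lapply(toks, function(s) if (word %in% s) setdiff(s, word))))
  }
  expect_gt(length(intersect(ctx_of("s1"), ctx_of("y1"))), 0)
  expect_length(intersect(ctx_of("s1"), ctx_of("d1")), 0)

  expect_identical(corp,
                   generate_cooccurrence_corpus("s1", "y1", "d1", 500, seed = 3))
  expect_error(generate_cooccurrence_corpus(character(0), "y", "d", 10, 1),
               "non-empty")
  expect_error(generate_cooccurrence_corpus("w", "w", "d", 10, 1), "disjoint")
})
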