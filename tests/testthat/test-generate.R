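test_that("the default design yields 27 x 3 x 20 accent-bearing rows", {
  d <- generate_onglides(generator_spec(seed = 1))
  expect_equal(nrow(d), 1620L)
  expect_equal(length(unique(d$speaker)), 27L)
  expect_equal(length(unique(d$condition)), 3L)
  expect_equal(length(unique(d$word)), 20L)
  expect_true(all(d$onglide_st != 0))
})

test_that("datasets are bit-identical under a fixed seed", {
  d1 <- generate_onglides(generator_spec(seed = 11))
  d2 <- generate_onglides(generator_spec(seed = 11))
  expect_identical(d1$onglide_st, d2$onglide_st)
  d3 <- generate_onglides(generator_spec(seed = 12))
  expect_false(identical(d1$onglide_st, d3$onglide_st))
})

test_that("pooled fall proportions sit near their design values", {
  d <- generate_onglides(generator_spec(seed = 21))
  s <- summarize_onglides(d, by = "condition", value = "onglide_st")
  design <- c(broad = 0.470, narrow = 0.219, contrastive = 0.091)
  for (cc in names(design)) {
    p_fall <- 1 - s$prop_rising[s$condition == cc]
    n <- s$n_total[s$condition == cc]
    # within 3 binomial standard errors of the design value
    expect_lt(abs(p_fall - design[[cc]]),
              3 * sqrt(design[[cc]] * (1 - design[[cc]]) / n) + 1e-9)
  }
})

test_that("zero fall probability produces rises only", {
  spec <- generator_spec(seed = 2)
  spec$fall_probability[] <- 0
  d <- generate_onglides(spec)
  expect_true(all(d$onglide_st > 0))
})

test_that("raw magnitudes are right-skewed across speakers and the
           normalisation reduces the skew substantially", {
  d <- generate_onglides(generator_spec(seed = 31))
  rises_raw <- d$onglide_st[d$onglide_st > 0]
  rises_nrm <- signed_log(rises_raw)
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  expect_gt(skew(rises_raw), 0.5)
  expect_lt(abs(skew(rises_nrm)), 0.7 * abs(skew(rises_raw)))
})

test_that("strategy groups are recoverable from the generated data", {
  hits <- vapply(1:5, function(s) {
    d <- generate_onglides(generator_spec(seed = 100 + s))
    g <- assign_groups(d, value = "onglide_st")
    truth <- unique(d[, c("speaker", "group_true")])
    sum(g$group[match(truth$speaker, g$speaker)] == truth$group_true)
  }, numeric(1))
  expect_true(all(hits >= 25)) # 27 speakers; slack only near the 1/3 boundary
  expect_gte(mean(hits), 26)
})

test_that("model-backed generation orders conditions by their tilts", {
  d <- generate_from_model(c(broad = 0.3, narrow = 3.3, contrastive = 5.4),
                           n_per_condition = 1500, seed = 41)
  s <- summarize_onglides(d, by = "condition")
  p <- setNames(s$prop_rising, s$condition)
  expect_lt(p[["broad"]], p[["narrow"]])
  expect_lt(p[["narrow"]], p[["contrastive"]])
  d0 <- generate_from_model(c(flat = 0), n_per_condition = 2500, seed = 42)
  expect_lt(abs(mean(d0$onglide_norm > 0) - 0.5), 0.03)
})

test_that("fitting the model-backed data recovers the generating tilts", {
  d <- generate_from_model(c(a = 1, b = 4), n_per_condition = 2500, seed = 43)
  fit <- landscape_fit(onglide_norm ~ condition, d, method = "quadrature",
                       grid = seq(-1, 6, by = 0.1))
  expect_lt(abs(coef(fit)[["a"]] - 1), 0.3)
  expect_lt(abs(coef(fit)[["b"]] - 4), 0.4)
})

test_that("missing-utterance exclusion thins the dataset reproducibly", {
  # keep ~1554 of the 1620 planned utterances
  d <- generate_onglides(generator_spec(seed = 51,
                                        exclusion_rate = 1 - 1554 / 1620))
  expect_lt(abs(nrow(d) - 1554), 4 * sqrt(1620 * 0.04))
})

test_that("datasets round-trip through delimited text losslessly", {
  d <- generate_onglides(generator_spec(seed = 61))
  d$onglide_norm <- signed_log(d$onglide_st)
  path <- tempfile(fileext = ".csv")
  write_onglides(d, path)
  d2 <- read_onglides(path)
  expect_equal(d2$onglide_st, d$onglide_st, tolerance = 1e-15)
  expect_equal(d2$onglide_norm, d$onglide_norm, tolerance = 1e-15)
  expect_identical(d2$speaker, d$speaker)
  unlink(path)
})

test_that("the loader rejects malformed files and zero onglides", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("speaker,condition,word,onglide_st",
               "S01,broad,w01,1.5",
               "S01,narrow,w01,0"), path)
  expect_error(read_onglides(path), "zero onglide")
  writeLines(c("speaker,condition,word,onglide_st",
               "S01,sarcastic,w01,1.5"), path)
  expect_error(read_onglides(path), "unknown condition")
  writeLines(c("speaker,word,onglide_st", "S01,w01,1.5"), path)
  expect_error(read_onglides(path), "missing column")
  # column mapping adapts foreign headers
  writeLines(c("subj,focus,item,onglide",
               "S01,broad,w01,1.5"), path)
  d <- read_onglides(path, col_map = c(speaker = "subj", condition = "focus",
                                       word = "item", onglide_st = "onglide"))
  expect_equal(d$onglide_st, 1.5)
  unlink(path)
})

test_that("background rows load but stay out of summaries", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("speaker,condition,word,onglide_st",
               "S01,broad,w01,1.5",
               "S01,broad,w02,-2.0",
               "S01,background,w01,NA"), path)
  d <- read_onglides(path)
  expect_equal(nrow(d), 3L)
  expect_false(d$accented[d$condition == "background"])
  s <- summarize_onglides(d, by = "condition", value = "onglide_st")
  expect_equal(sum(s$n_total), 2L)
  unlink(path)
})

test_that("invalid generator specifications fail before sampling", {
  expect_error(generator_spec(n_words = 0))
  spec <- generator_spec()
  spec$fall_probability[1, 1] <- 1.5
  expect_error(generate_onglides(unclass(spec)), "generator_spec")
})
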