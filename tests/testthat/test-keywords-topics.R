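test_that("tfidf follows its definition on hand-computed cases", {
  docs <- list(c("haze", "mask", "haze", "sky"), c("sun", "wind"))
  kw <- tfidf_keywords(docs)
  # "haze": 2 of 4 tokens in doc 1, present in 1 of 2 docs
  row <- kw[kw$doc_id == 1 & kw$token == "haze", ]
  expect_equal(row$tf, 0.5)
  expect_equal(row$idf, log(2))
  expect_equal(row$tfidf, 0.5 * log(2), tolerance = 1e-12)
  expect_equal(row$tfidf, 0.3466, tolerance = 1e-4)
  # terms absent from a doc are not ranked in it
  expect_false("sun" %in% kw$token[kw$doc_id == 1])
})

test_that("ubiquitous terms get idf 0 and ranking is tfidf-descending", {
  docs <- list(c("haze", "mask"), c("haze", "sun"), c("haze", "wind"))
  kw <- tfidf_keywords(docs)
  expect_true(all(kw$tfidf[kw$token == "haze"] == 0))
  for (d in unique(kw$doc_id)) {
    v <- kw$tfidf[kw$doc_id == d]
    expect_true(all(diff(v) <= 0))
    expect_equal(kw$rank[kw$doc_id == d], seq_along(v))
  }
  expect_error(tfidf_keywords(list(character(0))), "non-empty")
})

test_that("idf is strictly decreasing in document frequency", {
  N <- 10
  docs <- c(
    replicate(3, c("rare", "x"), simplify = FALSE),
    replicate(7, c("common", "x"), simplify = FALSE)
  )
  kw <- tfidf_keywords(docs)
  idf_rare <- kw$idf[kw$token == "rare"][1]
  idf_common <- kw$idf[kw$token == "common"][1]
  expect_gt(idf_rare, idf_common)
  expect_equal(idf_rare, log(10 / 3))
})

test_that("topic index counts seed-incident co-occurrence per document", {
  expect_equal(topic_index(list(c("haze", "mask")), "haze"), 1.0)
  expect_equal(topic_index(list(c("sun", "wind")), "haze"), 0)
  expect_warning(ti <- topic_index(list(), "haze"), "no documents")
  expect_equal(ti, 0)
  # two seed-incident pairs in one doc of three tokens
  expect_equal(topic_index(list(c("haze", "mask", "cough")), "haze"), 2)
  # repeated tokens in a doc count once
  expect_equal(topic_index(list(c("haze", "haze", "mask")), "haze"), 1)
})

test_that("topic index is invariant to duplication and token order", {
  docs <- list(c("haze", "mask", "sky"), c("smog", "haze"), c("sun", "wind"))
  base <- topic_index(docs, c("haze", "smog"))
  expect_equal(topic_index(c(docs, docs), c("haze", "smog")), base)
  shuffled <- lapply(docs, rev)
  expect_equal(topic_index(shuffled, c("haze", "smog")), base)
})

test_that("perception index hits its floor, ceiling and midpoint", {
  # region 2 standardizes to (share, count, topic) = (1, 0, 0.5)
  haze <- c(5, 1, 3)
  total <- c(50, 10 / 3, 15)
  topic <- c(0, 0.5, 1)
  pi_val <- perception_index(haze, total, topic)
  expect_equal(pi_val[2], 0.5)
  # a region at the max of every component scores 1, at the min 0
  pi2 <- perception_index(c(1, 5), c(10, 10), c(0.1, 0.9))
  expect_equal(pi2, c(0, 1))
  expect_error(perception_index(1, 0, 1), "positive")
})

test_that("indicator correlations are computed or flagged, never defaulted", {
  dates <- as.Date("2015-12-01") + 0:9
  pm25 <- tibble::tibble(region = "A", season = 2015L, date = dates,
                         concentration = seq(50, 140, by = 10))
  # post count an exact linear function of PM2.5
  n_per_day <- round(seq(10, 28, by = 2))
  scored <- tibble::tibble(
    region = "A", season = 2015L,
    date = rep(dates, n_per_day),
    score = 0.7,
    tokens = replicate(sum(n_per_day), c("haze", "mask"), simplify = FALSE)
  )
  ind <- compute_indicators(scored, pm25)
  expect_equal(ind$corr_number, 1, tolerance = 1e-12)
  expect_equal(ind$n_microblogs, sum(n_per_day))
  expect_equal(ind$sentiment_score, 0.7)
  # constant scores: zero variance -> flagged NA
  expect_true(is.na(ind$corr_sentiment))

  # constant daily counts -> corr_number flagged NA
  scored2 <- scored
  scored2 <- scored2[rep(seq_len(10), each = 1), ]
  scored2$date <- dates
  ind2 <- compute_indicators(scored2, pm25)
  expect_true(is.na(ind2$corr_number))
})

test_that("a negative sentiment slope surfaces as negative corr_sentiment", {
  cfg <- sim_config(regions = "A", years = 2015L, season_days = 90,
                    posts_per_day_base = 110, sentiment_pm25_slope = -1.5,
                    n_train_docs = 0, seed = 3)
  pm <- generate_pm25(cfg)
  corpus <- generate_corpus(cfg, pm)$corpus   # ~10,000 posts
  expect_gt(nrow(corpus), 5000)
  corpus$score <- ifelse(corpus$latent_class == "positive", 0.9, 0.1)
  ind <- compute_indicators(corpus, pm)
  expect_lt(ind$corr_sentiment, 0)
})
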