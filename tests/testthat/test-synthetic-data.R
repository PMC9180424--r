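test_that("config validation enforces the generator's invariants", {
  expect_error(sim_config(pm25_region_means = c(-5, 60, 70, 80, 86, 60, 67)),
               "positive")
  expect_error(sim_config(sentiment_base = 1.2), "between 0 and 1")
  expect_error(sim_config(season_days = 0), "positive")
  expect_error(sim_config(persistence = 1.5), "persistence")
  cfg <- sim_config()
  expect_equal(length(cfg$regions), 7)
  expect_equal(cfg$pm25_region_means, c(90, 88, 75, 80, 86, 60, 67))
  expect_equal(cfg$years, 2013:2019)
})

test_that("seasonal PM2.5 means track the configured region means", {
  cfg <- sim_config(regions = "R1", years = 2013L, season_days = 120,
                    pm25_region_means = 90, seed = 2)
  pm <- generate_pm25(cfg)
  expect_equal(nrow(pm), 120)
  expect_true(all(pm$concentration > 0))
  expect_lt(abs(mean(pm$concentration) - 90) / 90, 0.10)
})

test_that("zero lognormal scale collapses to the region mean exactly", {
  cfg <- sim_config(regions = c("R1", "R2"), years = 2013L, season_days = 10,
                    pm25_region_means = c(90, 60), pm25_sigma = 0)
  pm <- generate_pm25(cfg)
  expect_equal(unique(pm$concentration[pm$region == "R1"]), 90)
  expect_equal(unique(pm$concentration[pm$region == "R2"]), 60)
})

test_that("identical configs generate byte-identical bundles", {
  cfg <- small_config(seed = 6)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$pm25, b2$pm25)
  expect_identical(b1$corpus, b2$corpus)
  expect_identical(b1$panel, b2$panel)
  expect_identical(b1$class_raster, b2$class_raster)
  # serialized forms agree byte for byte
  expect_identical(serialize(b1$panel, NULL), serialize(b2$panel, NULL))
  b3 <- simulate_bundle(small_config(seed = 7))
  expect_false(identical(b1$corpus, b3$corpus))
})

test_that("a zero sentiment slope leaves sentiment uncorrelated with PM2.5", {
  cfg <- sim_config(regions = "A", years = 2015L, season_days = 90,
                    posts_per_day_base = 40, sentiment_pm25_slope = 0,
                    n_train_docs = 0, seed = 10)
  pm <- generate_pm25(cfg)
  corpus <- generate_corpus(cfg, pm)$corpus
  daily <- dplyr::summarise(
    dplyr::group_by(corpus, date),
    neg_share = mean(latent_class == "negative"), .groups = "drop"
  )
  daily <- dplyr::left_join(daily, pm[, c("date", "concentration")], by = "date")
  ct <- stats::cor.test(daily$neg_share, daily$concentration)
  expect_true(ct$conf.int[1] < 0 && ct$conf.int[2] > 0)
  expect_lt(abs(mean(corpus$latent_class == "positive") - cfg$sentiment_base), 0.05)
})

test_that("a strongly negative slope couples latent sentiment to PM2.5", {
  cfg <- sim_config(regions = "A", years = 2015L, season_days = 90,
                    posts_per_day_base = 110, sentiment_pm25_slope = -1.5,
                    n_train_docs = 0, seed = 10)
  pm <- generate_pm25(cfg)
  corpus <- generate_corpus(cfg, pm)$corpus
  expect_gt(nrow(corpus), 8000)
  daily <- dplyr::summarise(
    dplyr::group_by(corpus, date),
    pos_share = mean(latent_class == "positive"), .groups = "drop"
  )
  daily <- dplyr::left_join(daily, pm[, c("date", "concentration")], by = "date")
  expect_lt(stats::cor(daily$pos_share, daily$concentration), 0)
})

test_that("post volume rises with pollution under a positive volume slope", {
  cfg <- sim_config(regions = "A", years = 2015L, season_days = 90,
                    posts_per_day_base = 30, posts_pm25_slope = 0.5,
                    n_train_docs = 0, seed = 12)
  pm <- generate_pm25(cfg)
  corpus <- generate_corpus(cfg, pm)$corpus
  daily <- as.data.frame(table(corpus$date), stringsAsFactors = FALSE)
  names(daily) <- c("date", "n")
  daily$date <- as.Date(daily$date)
  daily <- dplyr::left_join(daily, pm[, c("date", "concentration")], by = "date")
  expect_gt(stats::cor(daily$n, daily$concentration), 0)
})

test_that("an empty training request still yields the scoring corpus", {
  cfg <- sim_config(regions = "A", years = 2015L, season_days = 10,
                    n_train_docs = 0)
  pm <- generate_pm25(cfg)
  out <- generate_corpus(cfg, pm)
  expect_equal(nrow(out$train_corpus), 0)
  expect_gt(nrow(out$corpus), 0)
  expect_error(generate_corpus(cfg, pm[0, ]), "empty")
})

test_that("the panel has exactly the 18 indicator columns per region-year", {
  cfg <- small_config(seed = 3)
  b <- simulate_bundle(cfg)
  expect_equal(nrow(b$panel), length(cfg$regions) * length(cfg$years))
  expect_identical(setdiff(names(b$panel), c("region", "year")),
                   panel_indicators())
  expect_equal(length(panel_indicators()), 18)

  one <- sim_config(regions = "A", years = 2015L, season_days = 30,
                    pm25_region_means = 90, posts_per_day_base = 10,
                    n_train_docs = 100)
  bo <- simulate_bundle(one)
  expect_equal(nrow(bo$panel), 1)
})

test_that("a missing region-year in the PM2.5 table is an input error", {
  cfg <- small_config()
  pm <- generate_pm25(cfg)
  corpora <- generate_corpus(cfg, pm)
  pm_cut <- pm[pm$region != "B", ]
  expect_error(
    generate_panel(cfg, corpora$corpus, pm_cut, corpora$train_corpus),
    "missing region-years"
  )
})

test_that("class raster sequences follow the Markov persistence contract", {
  frozen <- generate_class_raster(sim_config(regions = "A", n_units = 20,
                                             persistence = 1, seed = 5))
  per_unit <- split(frozen$state, frozen$unit_id)
  expect_true(all(vapply(per_unit, function(s) length(unique(s)) == 1, logical(1))))
  expect_true(all(lengths(per_unit) == 7))

  uniform <- generate_class_raster(sim_config(regions = "A", n_units = 1000,
                                              persistence = 0.2, seed = 5))
  expect_setequal(unique(uniform$state), 1:5)
})

test_that("corpora round-trip through JSON-lines", {
  cfg <- sim_config(regions = "A", years = 2015L, season_days = 5,
                    posts_per_day_base = 4, n_train_docs = 10)
  b <- generate_corpus(cfg, generate_pm25(cfg))
  path <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(b$corpus, path)
  back <- read_corpus_jsonl(path)
  expect_equal(back$id, b$corpus$id)
  expect_equal(back$region, b$corpus$region)
  expect_identical(back$tokens, unname(b$corpus$tokens))
  expect_equal(back$date, b$corpus$date)
})

test_that("the panel round-trips through CSV into the weighting reader", {
  cfg <- small_config(seed = 13)
  b <- simulate_bundle(cfg)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(b$panel, path, row.names = FALSE)
  back <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  expect_equal(as.data.frame(back[panel_indicators()]),
               as.data.frame(b$panel[panel_indicators()]),
               tolerance = 1e-12)
  # and standardization accepts it directly
  Y <- standardize_panel(back, default_directions())
  expect_equal(dim(Y), c(nrow(b$panel), 18))
})
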