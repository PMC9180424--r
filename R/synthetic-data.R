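#' Configuration for the synthetic haze-perception study
#'
#' Defines the conditions the generator emulates: a set of heavily
#' haze-affected regions observed over consecutive winters, with daily
#' PM2.5 concentrations lognormal around region-level means, microblog
#' volume rising with same-day pollution, and a latent sentiment class
#' whose negative share grows with pollution. Defaults mirror the study
#' setting: 7 regions over the 2013--2019 winters with region-mean PM2.5
#' of 90, 88, 75, 80, 86, 60 and 67 ug/m3, a 2,000-document labelled
#' training corpus and roughly 10,000 scored posts.
#'
#' @param regions character vector of region names.
#' @param years calendar years, one winter season per year.
#' @param season_days days per winter season.
#' @param pm25_region_means per-region mean winter PM2.5 (ug/m3, > 0),
#'   recycled across regions if length 1.
#' @param pm25_sigma lognormal scale (sdlog) of daily PM2.5; 0 gives
#'   noise-free series at the region mean.
#' @param posts_per_day_base expected posts per region-day at average
#'   pollution.
#' @param posts_pm25_slope log-link coefficient of standardized PM2.5 on
#'   post volume (>= 0 for volume rising with pollution).
#' @param sentiment_pm25_slope logit-linear coefficient of standardized
#'   PM2.5 on the latent positive-class probability; negative means
#'   sentiment worsens with pollution.
#' @param sentiment_base latent positive-class probability at average
#'   pollution, in (0, 1).
#' @param vocab_size number of distinct tokens in the synthetic
#'   vocabulary (>= 30).
#' @param doc_length_mean mean tokens per post.
#' @param n_train_docs labelled training documents (0 allowed).
#' @param n_units spatial units for the class raster.
#' @param persistence probability a unit keeps its class from one year to
#'   the next, in `[0, 1]`.
#' @param seed integer seed; identical configs generate byte-identical
#'   bundles.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(regions = c("Beijing", "Tianjin", "Hebei", "Shanxi",
                                   "Inner Mongolia", "Liaoning", "Shandong"),
                       years = 2013:2019,
                       season_days = 90,
                       pm25_region_means = c(90, 88, 75, 80, 86, 60, 67),
                       pm25_sigma = 0.3,
                       posts_per_day_base = 2.3,
                       posts_pm25_slope = 0.3,
                       sentiment_pm25_slope = -0.8,
                       sentiment_base = 0.55,
                       vocab_size = 200,
                       doc_length_mean = 8,
                       n_train_docs = 2000,
                       n_units = 66,
                       persistence = 0.6,
                       seed = 1L) {
  if (missing(pm25_region_means) || length(pm25_region_means) == 1) {
    pm25_region_means <- rep_len(pm25_region_means, length(regions))
  }
  cfg <- list(
    regions = as.character(regions), years = as.integer(years),
    season_days = as.integer(season_days),
    pm25_region_means = as.numeric(pm25_region_means),
    pm25_sigma = as.numeric(pm25_sigma),
    posts_per_day_base = as.numeric(posts_per_day_base),
    posts_pm25_slope = as.numeric(posts_pm25_slope),
    sentiment_pm25_slope = as.numeric(sentiment_pm25_slope),
    sentiment_base = as.numeric(sentiment_base),
    vocab_size = as.integer(vocab_size),
    doc_length_mean = as.numeric(doc_length_mean),
    n_train_docs = as.integer(n_train_docs),
    n_units = as.integer(n_units),
    persistence = as.numeric(persistence),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$regions) < 1) stop("at least one region is required")
  if (length(cfg$years) < 1) stop("at least one year is required")
  if (cfg$season_days < 1) stop("season_days must be positive")
  if (length(cfg$pm25_region_means) != length(cfg$regions)) {
    stop("pm25_region_means must have one value per region")
  }
  if (any(cfg$pm25_region_means <= 0)) stop("pm25_region_means must be positive concentrations")
  if (cfg$pm25_sigma < 0) stop("pm25_sigma must be non-negative")
  if (cfg$posts_per_day_base <= 0) stop("posts_per_day_base must be positive")
  if (cfg$sentiment_base <= 0 || cfg$sentiment_base >= 1) {
    stop("sentiment_base must lie strictly between 0 and 1")
  }
  if (cfg$vocab_size < 30) stop("vocab_size must be at least 30")
  if (cfg$n_train_docs < 0) stop("n_train_docs must be non-negative")
  if (cfg$n_units < 1) stop("n_units must be positive")
  if (cfg$persistence < 0 || cfg$persistence > 1) stop("persistence must be in [0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic haze-study configuration\n")
  cat("  ", length(x$regions), "regions x", length(x$years), "winters x",
      x$season_days, "days; seed", x$seed, "\n")
  cat("  PM2.5 means:", paste(x$pm25_region_means, collapse = ", "), "ug/m3\n")
  cat("  sentiment slope:", x$sentiment_pm25_slope,
      "| volume slope:", x$posts_pm25_slope, "\n")
  invisible(x)
}

#' Generate daily winter PM2.5 series
#'
#' Daily concentrations are lognormal with the meanlog chosen so the
#' arithmetic mean equals the configured region mean
#' (\eqn{\mu_{log} = \ln m - \sigma^2/2}): strictly positive and
#' right-skewed, like pollution data. Each year's winter season starts on
#' 1 December and runs `season_days` days.
#'
#' @param config a [sim_config()].
#' @return tibble: region, season (year label), date, concentration.
#' @export
generate_pm25 <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, 1L, {
    grid <- expand.grid(
      day = seq_len(config$season_days),
      season = config$years,
      region = config$regions,
      stringsAsFactors = FALSE
    )
    grid$date <- as.Date(paste0(grid$season, "-12-01")) + grid$day - 1
    means <- config$pm25_region_means[match(grid$region, config$regions)]
    if (config$pm25_sigma == 0) {
      grid$concentration <- means
    } else {
      mu <- log(means) - config$pm25_sigma^2 / 2
      grid$concentration <- stats::rlnorm(nrow(grid), mu, config$pm25_sigma)
    }
    tibble::as_tibble(grid[, c("region", "season", "date", "concentration")])
  })
}

# Synthetic vocabulary with class-conditional multinomial token
# distributions. Sentiment-bearing tokens are over-represented in their
# class (matching the naive-Bayes family, so classifier recovery is
# well-posed); haze seed terms and neutral filler are class-neutral.
build_vocabulary <- function(vocab_size) {
  n_sent <- max(5L, round(vocab_size * 0.1))
  seeds <- c("haze", "smog", "pm25", "mask", "airquality")
  n_neutral <- vocab_size - 2L * n_sent - length(seeds)
  vocab <- c(
    paste0("pos", sprintf("%03d", seq_len(n_sent))),
    paste0("neg", sprintf("%03d", seq_len(n_sent))),
    seeds,
    paste0("w", sprintf("%03d", seq_len(n_neutral)))
  )
  base <- rep(1, length(vocab))
  w_pos <- base; w_pos[seq_len(n_sent)] <- 8
  w_neg <- base; w_neg[n_sent + seq_len(n_sent)] <- 8
  list(
    tokens = vocab,
    prob = cbind(positive = w_pos / sum(w_pos), negative = w_neg / sum(w_neg))
  )
}

# Draw n documents of the given classes in one vectorized pass.
draw_documents <- function(vocab, classes, doc_length_mean) {
  n <- length(classes)
  lens <- 1L + stats::rpois(n, max(doc_length_mean - 1, 0))
  docs <- vector("list", n)
  for (cl in c("positive", "negative")) {
    idx <- which(classes == cl)
    if (length(idx) == 0) next
    total <- sum(lens[idx])
    toks <- sample(vocab$tokens, total, replace = TRUE, prob = vocab$prob[, cl])
    docs[idx] <- split(toks, rep(seq_along(idx), lens[idx]))
  }
  docs
}

#' Generate the microblog corpus and labelled training corpus
#'
#' Per region-day, the post count is Poisson with a log-link on
#' standardized PM2.5 (volume rises with pollution when the slope is
#' positive); each post's latent sentiment class is Bernoulli with a
#' logit-linear dependence on standardized PM2.5 via
#' `sentiment_pm25_slope`, and its tokens are drawn from the
#' class-conditional multinomial vocabulary. The scoring corpus carries
#' the latent class in `latent_class` (ground truth for validation, not
#' visible to the classifier); the training corpus carries explicit
#' `label`s with balanced classes.
#'
#' @param config a [sim_config()].
#' @param pm25 daily table from [generate_pm25()]; must cover every
#'   region-day.
#' @return list with `corpus` and `train_corpus` tibbles (columns id,
#'   region, season, date, timestamp, tokens, and latent_class / label).
#' @export
generate_corpus <- function(config, pm25) {
  validate_sim_config(config)
  if (is.null(pm25) || nrow(pm25) == 0) stop("pm25 table is empty; generate it first")
  with_substream(config$seed, 2L, {
    vocab <- build_vocabulary(config$vocab_size)
    z <- as.vector(scale(pm25$concentration))
    if (anyNA(z)) z <- rep(0, nrow(pm25))   # constant series standardizes to 0
    rate <- config$posts_per_day_base * exp(config$posts_pm25_slope * z)
    n_posts <- stats::rpois(nrow(pm25), rate)
    day_idx <- rep(seq_len(nrow(pm25)), n_posts)
    n <- length(day_idx)
    p_pos <- stats::plogis(stats::qlogis(config$sentiment_base) +
                             config$sentiment_pm25_slope * z[day_idx])
    classes <- ifelse(stats::runif(n) < p_pos, "positive", "negative")
    corpus <- tibble::tibble(
      id = sprintf("post%07d", seq_len(n)),
      region = pm25$region[day_idx],
      season = pm25$season[day_idx],
      date = pm25$date[day_idx],
      timestamp = as.POSIXct(pm25$date[day_idx], tz = "UTC") +
        round(stats::runif(n, 0, 86399)),
      tokens = draw_documents(vocab, classes, config$doc_length_mean),
      latent_class = classes
    )
    n_tr <- config$n_train_docs
    train_classes <- rep(c("positive", "negative"), length.out = n_tr)
    train_corpus <- tibble::tibble(
      id = sprintf("train%06d", seq_len(n_tr)),
      region = rep("training", n_tr),
      season = rep(NA_integer_, n_tr),
      date = rep(as.Date(NA), n_tr),
      timestamp = rep(as.POSIXct(NA), n_tr),
      tokens = draw_documents(vocab, train_classes, config$doc_length_mean),
      label = train_classes
    )
    list(corpus = corpus, train_corpus = train_corpus)
  })
}

#' Generate the 18-indicator evaluation panel
#'
#' One row per region-year. The five ecological columns derive from the
#' PM2.5 series plus synthetic winter weather; the eight socio-economic
#' columns are drawn from plausible positive ranges with persistent
#' region-level effects (distributional forms are generator conventions —
#' the yearbook quantities have no published distributions); the five
#' social-media columns are computed from the corpus through the
#' sentiment and keyword modules ([nb_train()], [score_corpus()],
#' [compute_indicators()]).
#'
#' @param config a [sim_config()].
#' @param corpus scoring corpus from [generate_corpus()]; if it lacks a
#'   `score` column, `train_corpus` must be supplied to fit the sentiment
#'   model.
#' @param pm25 daily PM2.5 table.
#' @param train_corpus labelled corpus used to train the sentiment model
#'   when `corpus` is unscored.
#' @param alpha naive-Bayes smoothing passed to [nb_train()].
#' @return tibble: region, year, then exactly 18 indicator columns.
#' @export
generate_panel <- function(config, corpus, pm25, train_corpus = NULL, alpha = 1) {
  validate_sim_config(config)
  if (!"score" %in% names(corpus)) {
    if (is.null(train_corpus) || nrow(train_corpus) == 0) {
      stop("corpus is unscored and no train_corpus was supplied")
    }
    model <- nb_train(train_corpus, alpha = alpha)
    corpus <- score_corpus(model, corpus)$corpus
  }
  grid <- expand.grid(year = config$years, region = config$regions,
                      stringsAsFactors = FALSE)[, c("region", "year")]
  covered <- unique(pm25[, c("region", "season")])
  miss <- !paste(grid$region, grid$year) %in% paste(covered$region, covered$season)
  if (any(miss)) {
    stop("pm25 table is missing region-years: ",
         paste(grid$region[miss], grid$year[miss], collapse = ", "))
  }
  eco <- dplyr::summarise(
    dplyr::group_by(pm25, region = .data$region, year = .data$season),
    air_quality = mean(.data$concentration),
    pollution_days = sum(.data$concentration > 75),
    .groups = "drop"
  )
  social <- compute_indicators(corpus, pm25)
  names(social)[names(social) == "season"] <- "year"
  with_substream(config$seed, 3L, {
    n <- nrow(grid)
    region_effect <- stats::setNames(stats::rnorm(length(config$regions), 0, 0.25),
                                     config$regions)
    eff <- region_effect[grid$region]
    weather <- tibble::tibble(
      region = grid$region, year = grid$year,
      temperature = stats::rnorm(n, -2, 3),
      relative_humidity = stats::runif(n, 40, 70),
      wind_speed = stats::runif(n, 1.5, 4)
    )
    economy <- tibble::tibble(
      region = grid$region, year = grid$year,
      population_density = exp(stats::rnorm(n, log(500), 0.2) + eff),
      per_capita_gdp = exp(stats::rnorm(n, log(60000), 0.15) + eff),
      secondary_industry_share = stats::runif(n, 30, 55),
      built_up_area_share = stats::runif(n, 5, 20),
      road_area = exp(stats::rnorm(n, log(8000), 0.3) + eff),
      green_space_per_capita = stats::runif(n, 8, 18),
      education_level = stats::runif(n, 8, 13),
      gender_ratio = stats::rnorm(n, 105, 2)
    )
    panel <- dplyr::left_join(tibble::as_tibble(grid), eco, by = c("region", "year"))
    panel <- dplyr::left_join(panel, weather, by = c("region", "year"))
    panel <- dplyr::left_join(panel, economy, by = c("region", "year"))
    panel <- dplyr::left_join(panel, social, by = c("region", "year"))
    panel[, c("region", "year", panel_indicators())]
  })
}

#' Names of the 18 indicator columns, by rule layer
#'
#' @param by_layer return a named list split by rule layer instead of the
#'   flat vector.
#' @return character vector of the 18 indicator names (or a 3-element
#'   list).
#' @export
panel_indicators <- function(by_layer = FALSE) {
  layers <- list(
    ecological_environment = c("air_quality", "temperature", "relative_humidity",
                               "wind_speed", "pollution_days"),
    social_economy = c("population_density", "per_capita_gdp",
                       "secondary_industry_share", "built_up_area_share",
                       "road_area", "green_space_per_capita",
                       "education_level", "gender_ratio"),
    social_media = c("n_microblogs", "corr_number", "sentiment_score",
                     "corr_sentiment", "topic_index")
  )
  if (by_layer) layers else unlist(layers, use.names = FALSE)
}

#' Generate per-unit class-state sequences
#'
#' A first-order Markov chain over states `1..n_states` per spatial unit:
#' a unit keeps its state with probability `persistence`, otherwise moves
#' to one of the other states uniformly. `persistence = 1` freezes every
#' unit's sequence; `persistence = 1/n_states` makes transitions uniform
#' over all states.
#'
#' @param config a [sim_config()].
#' @param n_states number of tolerance classes (default 5).
#' @return tibble: unit_id, year, state.
#' @export
generate_class_raster <- function(config, n_states = 5) {
  validate_sim_config(config)
  q <- length(config$years)
  with_substream(config$seed, 4L, {
    states <- matrix(NA_integer_, config$n_units, q)
    states[, 1] <- sample.int(n_states, config$n_units, replace = TRUE)
    if (q > 1) {
      for (t in 2:q) {
        stay <- stats::runif(config$n_units) < config$persistence
        move <- sample.int(n_states - 1L, config$n_units, replace = TRUE)
        prev <- states[, t - 1]
        moved <- move + (move >= prev)   # uniform over the other states
        states[, t] <- ifelse(stay, prev, moved)
      }
    }
    tibble::tibble(
      unit_id = rep(sprintf("unit%03d", seq_len(config$n_units)), each = q),
      year = rep(config$years, config$n_units),
      state = as.integer(t(states))
    )
  })
}

#' Generate the full synthetic bundle
#'
#' Runs all generators in order under the config's single seed: PM2.5
#' series, scoring and training corpora, the 18-indicator panel and the
#' class raster.
#'
#' @param config a [sim_config()].
#' @return a `syn_bundle` list: config, pm25, corpus, train_corpus,
#'   panel, class_raster.
#' @export
simulate_bundle <- function(config = sim_config()) {
  pm25 <- generate_pm25(config)
  corpora <- generate_corpus(config, pm25)
  panel <- generate_panel(config, corpora$corpus, pm25, corpora$train_corpus)
  raster <- generate_class_raster(config)
  structure(
    list(config = config, pm25 = pm25, corpus = corpora$corpus,
         train_corpus = corpora$train_corpus, panel = panel,
         class_raster = raster),
    class = "syn_bundle"
  )
}

#' @export
print.syn_bundle <- function(x, ...) {
  cat("Synthetic haze-study bundle\n")
  cat("  corpus:", nrow(x$corpus), "posts | training:", nrow(x$train_corpus), "labelled\n")
  cat("  pm25:", nrow(x$pm25), "region-days | panel:", nrow(x$panel), "region-years\n")
  cat("  class raster:", length(unique(x$class_raster$unit_id)), "units x",
      length(unique(x$class_raster$year)), "years\n")
  invisible(x)
}

#' Write a corpus as JSON-lines
#'
#' One UTF-8 JSON object per line with the record's id, region, season,
#' timestamp, token list and, when present, label and score.
#'
#' @param corpus corpus tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  keep <- intersect(c("id", "region", "season", "date", "timestamp",
                      "tokens", "label", "latent_class", "score"),
                    names(corpus))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- lapply(keep, function(k) {
      v <- corpus[[k]][[i]]
      if (inherits(v, "Date") || inherits(v, "POSIXct")) v <- format(v)
      v
    })
    names(rec) <- keep
    rec <- rec[!vapply(rec, function(v) length(v) == 1 && is.na(v), logical(1))]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-lines corpus
#'
#' @param path file written by [write_corpus_jsonl()].
#' @return corpus tibble with a `tokens` list-column.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  get_col <- function(k, cast = identity) {
    vals <- lapply(recs, function(r) r[[k]])
    if (all(vapply(vals, is.null, logical(1)))) return(NULL)
    cast(vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v),
                character(1)))
  }
  out <- tibble::tibble(
    id = get_col("id"),
    region = get_col("region"),
    tokens = lapply(recs, function(r) as.character(r$tokens %||% character(0)))
  )
  for (k in c("season", "score")) {
    v <- get_col(k, as.numeric)
    if (!is.null(v)) out[[k]] <- v
  }
  v <- get_col("date")
  if (!is.null(v)) out$date <- as.Date(v)
  v <- get_col("label")
  if (!is.null(v)) out$label <- v
  out
}
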