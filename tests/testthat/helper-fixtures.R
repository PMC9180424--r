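# Shared in-code fixtures for the suite.

# The two-document corpus behind the hand-computed smoothing arithmetic:
# one positive doc {good, sky}, one negative doc {bad, haze}; vocab size 4.
tiny_train_corpus <- function() {
  tibble::tibble(
    id = c("d1", "d2"),
    region = "X",
    season = 2013L,
    tokens = list(c("good", "sky"), c("bad", "haze")),
    label = c("positive", "negative")
  )
}

# Small study: 2 regions, 1 winter, enough posts for stable correlations
# but cheap to generate.
small_config <- function(seed = 1L, ...) {
  sim_config(
    regions = c("A", "B"),
    years = 2015L,
    season_days = 60,
    pm25_region_means = c(90, 60),
    posts_per_day_base = 6,
    n_train_docs = 400,
    n_units = 10,
    seed = seed,
    ...
  )
}

# Brute-force probability-domain naive-Bayes oracle: recomputes priors,
# smoothed conditionals and the posterior by direct arithmetic, with no
# log-domain shortcuts. Independent of nb_train()/nb_score().
nb_oracle_score <- function(train, alpha, tokens) {
  classes <- c("positive", "negative")
  prior <- sapply(classes, function(cl) mean(train$label == cl))
  vocab <- sort(unique(unlist(train$tokens)))
  V <- length(vocab)
  lik <- sapply(classes, function(cl) {
    bag <- unlist(train$tokens[train$label == cl])
    n_c <- length(bag)
    p <- 1
    for (tok in tokens) {
      n_wc <- sum(bag == tok)
      p <- p * (n_wc + alpha) / (n_c + alpha * V)
    }
    p
  })
  unname(prior["positive"] * lik["positive"] / sum(prior * lik))
}

# Random positive reciprocal matrix of order n (not necessarily
# consistent): fills the upper triangle with 1-9 scale values.
random_reciprocal_matrix <- function(n) {
  m <- diag(n)
  vals <- c(1 / (9:2), 1:9)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- sample(vals, 1)
      m[j, i] <- 1 / m[i, j]
    }
  }
  judgment_matrix(m)
}

# Dense-eigendecomposition oracle for AHP weights.
eigen_weights <- function(M) {
  e <- eigen(unclass(M))
  i <- which.max(Re(e$values))
  w <- Re(e$vectors[, i])
  w <- w / sum(w)
  list(weights = w, lambda_max = Re(e$values[i]))
}
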