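#' TF-IDF keyword extraction
#'
#' For each document, the term frequency of a token is its count divided by
#' the document length; the inverse document frequency is
#' \eqn{\mathrm{idf} = \ln(N / \mathrm{df})} with \eqn{N} the number of
#' documents and df the number containing the token (no +1 offsets: a
#' ubiquitous term gets idf 0). Keywords are ranked per document by the
#' product tf x idf, descending, ties broken lexicographically by token.
#'
#' @param docs list of token sequences; at least one must be non-empty.
#' @param top_k keep at most this many keywords per document
#'   (default `Inf`, keep all).
#' @return tibble: doc_id, token, tf, idf, tfidf, rank.
#' @export
tfidf_keywords <- function(docs, top_k = Inf) {
  if (length(docs) == 0 || all(lengths(docs) == 0)) {
    stop("keyword extraction needs at least one non-empty document")
  }
  N <- length(docs)
  df_counts <- table(unlist(lapply(docs, unique)))
  idf <- log(N / as.vector(df_counts))
  names(idf) <- names(df_counts)
  per_doc <- lapply(seq_along(docs), function(i) {
    toks <- docs[[i]]
    if (length(toks) == 0) return(NULL)
    tf_tab <- table(toks) / length(toks)
    token <- names(tf_tab)
    tfidf <- as.vector(tf_tab) * idf[token]
    ord <- order(-tfidf, token)
    k <- min(length(ord), top_k)
    tibble::tibble(
      doc_id = i,
      token = token[ord[seq_len(k)]],
      tf = as.vector(tf_tab)[ord[seq_len(k)]],
      idf = unname(idf[token[ord[seq_len(k)]]]),
      tfidf = unname(tfidf[ord[seq_len(k)]]),
      rank = seq_len(k)
    )
  })
  dplyr::bind_rows(per_doc)
}

#' Co-word topic index
#'
#' Measures the intensity of discussion around a set of seed terms through
#' a co-occurrence (co-word) network: tokens are nodes, and an edge's
#' weight is the number of documents in which both endpoints occur
#' (each document contributes at most once per pair, so repeated tokens
#' within a post don't inflate it). The index is the total weight of edges
#' incident to at least one seed term, divided by the number of documents.
#' The per-document normalisation makes the index invariant under
#' duplicating the corpus.
#'
#' @param docs list of token sequences.
#' @param seed_terms non-empty character vector of topic seed terms.
#' @return non-negative scalar; 0 with a warning when `docs` is empty.
#' @export
topic_index <- function(docs, seed_terms) {
  if (length(seed_terms) == 0) stop("seed_terms must be non-empty")
  if (length(docs) == 0) {
    warning("no documents: topic index is 0")
    return(0)
  }
  total <- 0
  for (toks in docs) {
    u <- unique(toks)
    if (length(u) < 2) next
    n_seed <- sum(u %in% seed_terms)
    if (n_seed == 0) next
    # pairs with >=1 seed endpoint: seed-seed pairs + seed-other pairs
    n_other <- length(u) - n_seed
    total <- total + choose(n_seed, 2) + n_seed * n_other
  }
  total / length(docs)
}

#' Haze perception index
#'
#' A weighted sum of min-max standardized components of haze discussion
#' intensity: the share of haze-related posts, the haze-related post
#' count, and the co-word topic index. Standardization is across the
#' regions of one dataset, so the region at the dataset maximum of every
#' component scores 1 and the minimum scores 0. Weights default to equal
#' thirds and must sum to 1. The method names its inputs (post counts,
#' topic intensity) but not their combination; the weighted standardized
#' sum here is this package's documented convention.
#'
#' @param n_haze_posts,n_total_posts,topic_index numeric vectors, one
#'   entry per region; `n_total_posts` must be positive.
#' @param weights 3 non-negative coefficients summing to 1 (share, count,
#'   topic).
#' @return numeric vector of perception indices in `[0, 1]`.
#' @export
perception_index <- function(n_haze_posts, n_total_posts, topic_index,
                             weights = c(1, 1, 1) / 3) {
  if (any(n_total_posts <= 0)) stop("n_total_posts must be positive")
  if (length(weights) != 3) stop("weights must have length 3")
  check_sums_to_one(weights, "weights")
  comp <- cbind(
    share = n_haze_posts / n_total_posts,
    count = n_haze_posts,
    topic = topic_index
  )
  std <- apply(comp, 2, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) rep(0.5, length(x)) else (x - rng[1]) / (rng[2] - rng[1])
  })
  std <- matrix(std, ncol = 3)
  as.vector(std %*% weights)
}

#' Social-media indicators per region-season
#'
#' Computes the five social-media columns of the evaluation system from a
#' scored corpus and a daily PM2.5 table, per (region, season):
#' the post count; the Pearson correlation between daily post count and
#' daily mean PM2.5; the mean sentiment score; the Pearson correlation
#' between daily mean sentiment and daily mean PM2.5; and the co-word
#' topic index of the season's posts. Correlations need at least 3 paired
#' days with variation on both sides; otherwise (or for zero-variance
#' series) they are returned as `NA`, never silently defaulted.
#'
#' @param scored tibble with `region`, `season`, `date`, `score`, `tokens`.
#' @param pm25 tibble with `region`, `season`, `date`, `concentration`.
#' @param seed_terms topic seed terms for the topic index.
#' @return tibble: region, season, n_microblogs, corr_number,
#'   sentiment_score, corr_sentiment, topic_index.
#' @export
compute_indicators <- function(scored, pm25, seed_terms = c("haze", "smog", "pm25")) {
  need <- c("region", "season", "date", "score", "tokens")
  miss <- setdiff(need, names(scored))
  if (length(miss) > 0) stop("scored corpus is missing columns: ", paste(miss, collapse = ", "))
  groups <- dplyr::distinct(scored, .data$region, .data$season)
  out <- lapply(seq_len(nrow(groups)), function(i) {
    reg <- groups$region[i]; sea <- groups$season[i]
    posts <- scored[scored$region == reg & scored$season == sea, ]
    air <- pm25[pm25$region == reg & pm25$season == sea, ]
    daily_posts <- dplyr::summarise(
      dplyr::group_by(posts, .data$date),
      n = dplyr::n(), mean_score = mean(.data$score), .groups = "drop"
    )
    daily_air <- dplyr::summarise(
      dplyr::group_by(air, .data$date),
      pm25 = mean(.data$concentration), .groups = "drop"
    )
    # days with PM2.5 but no posts are true zero-count days
    paired <- dplyr::left_join(daily_air, daily_posts, by = "date")
    paired$n[is.na(paired$n)] <- 0L
    with_posts <- paired[!is.na(paired$mean_score), ]
    tibble::tibble(
      region = reg,
      season = sea,
      n_microblogs = nrow(posts),
      corr_number = safe_cor(paired$n, paired$pm25),
      sentiment_score = mean(posts$score),
      corr_sentiment = safe_cor(with_posts$mean_score, with_posts$pm25),
      topic_index = topic_index(posts$tokens, seed_terms)
    )
  })
  dplyr::bind_rows(out)
}

safe_cor <- function(x, y) {
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
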