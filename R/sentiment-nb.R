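#' Train a multinomial naive-Bayes sentiment model
#'
#' Fits the classical two-class multinomial model: class priors
#' \eqn{P(c)} are document frequencies, and word conditionals are token
#' counts with additive (Laplace) smoothing,
#' \eqn{P(w \mid c) = (n_{wc} + \alpha) / (n_c + \alpha V)} where
#' \eqn{n_{wc}} is the count of word \eqn{w} in class \eqn{c}, \eqn{n_c}
#' the total token count of the class and \eqn{V} the vocabulary size.
#' Tokens never seen in training score with the zero-count smoothed mass
#' \eqn{\alpha / (n_c + \alpha V)}. Conditionals are stored in the log
#' domain; scores are returned in the probability domain.
#'
#' @param corpus tibble of labeled records: a `tokens` list-column and a
#'   `label` column with values `"positive"` / `"negative"`; both classes
#'   must be present.
#' @param alpha smoothing pseudo-count, strictly positive (default 1).
#' @return an `nb_model`: list with `prior`, `log_cond` (matrix token x
#'   class), `log_unseen`, `vocab`, `alpha`.
#' @export
nb_train <- function(corpus, alpha = 1) {
  if (!is.numeric(alpha) || alpha <= 0) {
    stop("alpha must be > 0: unsmoothed counts put zero probability on unseen words")
  }
  if (!all(c("tokens", "label") %in% names(corpus))) {
    stop("training corpus needs 'tokens' and 'label' columns")
  }
  labs <- corpus$label
  classes <- c("positive", "negative")
  if (!all(labs %in% classes)) stop("labels must be 'positive' or 'negative'")
  if (!all(classes %in% labs)) {
    stop("training corpus must contain at least one document of each class")
  }
  prior <- stats::setNames(as.vector(table(factor(labs, classes)) / length(labs)), classes)
  vocab <- sort(unique(unlist(corpus$tokens)))
  if (length(vocab) == 0) stop("training corpus has no tokens")
  counts <- sapply(classes, function(cl) {
    toks <- unlist(corpus$tokens[labs == cl])
    tab <- table(factor(toks, levels = vocab))
    as.vector(tab)
  })
  rownames(counts) <- vocab
  denom <- colSums(counts) + alpha * length(vocab)
  log_cond <- log(sweep(counts + alpha, 2, denom, "/"))
  log_unseen <- log(alpha / denom)
  structure(
    list(prior = prior, log_cond = log_cond, log_unseen = log_unseen,
         vocab = vocab, alpha = alpha),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat("Multinomial naive-Bayes sentiment model\n")
  cat("  vocabulary:", length(x$vocab), "tokens; alpha =", x$alpha, "\n")
  cat("  priors: positive", format(x$prior[["positive"]]),
      "/ negative", format(x$prior[["negative"]]), "\n")
  invisible(x)
}

#' Score a token sequence with a naive-Bayes model
#'
#' Returns the positive-class posterior
#' \eqn{P(pos \mid tokens) = P(pos)\prod_w P(w \mid pos) / \sum_c
#' P(c)\prod_w P(w \mid c)}, computed in the log domain for stability.
#' An empty token sequence yields the prior. Polarity follows the 0.5
#' rule: a score strictly above 0.5 is positive; 0.5 itself counts as
#' negative, because only scores exceeding the threshold express positive
#' sentiment.
#'
#' @param model an `nb_model` from [nb_train()].
#' @param tokens character vector of tokens.
#' @return list with `score` in `[0, 1]` and `polarity`
#'   (`"positive"` / `"negative"`).
#' @export
nb_score <- function(model, tokens) {
  stopifnot(inherits(model, "nb_model"))
  ll <- log(model$prior)
  if (length(tokens) > 0) {
    idx <- match(tokens, model$vocab)
    seen <- !is.na(idx)
    if (any(seen)) ll <- ll + colSums(model$log_cond[idx[seen], , drop = FALSE])
    if (any(!seen)) ll <- ll + sum(!seen) * model$log_unseen
  }
  ll <- ll - max(ll)
  post <- exp(ll) / sum(exp(ll))
  score <- unname(post[["positive"]])
  list(score = score, polarity = sentiment_polarity(score))
}

#' @rdname nb_score
#' @param score numeric vector of positive-class posteriors.
#' @export
sentiment_polarity <- function(score) {
  ifelse(score > 0.5, "positive", "negative")
}

#' Score a corpus and aggregate sentiment per region-season
#'
#' Scores every record and computes, per (region, season) group, the
#' quantities the tolerance index consumes: `WEp` / `WEN`, the counts of
#' positive and negative posts, and `AEp` / `AEN`, the mean positive and
#' mean negative sentiment scores. A polarity group with no members gets
#' count 0 and an `NA` mean — flagged, never imputed.
#'
#' @param model an `nb_model`.
#' @param corpus tibble with `tokens` list-column plus `region` and
#'   `season` columns (season = the winter's label, e.g. its year).
#' @return list with `corpus` (input plus `score`, `polarity` columns) and
#'   `aggregates` (tibble: region, season, WEp, WEN, AEp, AEN).
#' @export
score_corpus <- function(model, corpus) {
  if (!"tokens" %in% names(corpus)) stop("corpus must be tokenized before scoring")
  scores <- vapply(corpus$tokens, function(t) nb_score(model, t)$score, numeric(1))
  corpus$score <- scores
  corpus$polarity <- sentiment_polarity(scores)
  list(corpus = corpus, aggregates = aggregate_sentiment(corpus))
}

#' Aggregate already-scored posts per region-season
#'
#' @param scored tibble with `region`, `season`, `score` columns.
#' @return tibble: region, season, WEp, WEN, AEp, AEN.
#' @export
aggregate_sentiment <- function(scored) {
  need <- c("region", "season", "score")
  miss <- setdiff(need, names(scored))
  if (length(miss) > 0) stop("scored corpus is missing columns: ", paste(miss, collapse = ", "))
  dplyr::summarise(
    dplyr::group_by(scored, .data$region, .data$season),
    WEp = sum(sentiment_polarity(.data$score) == "positive"),
    WEN = sum(sentiment_polarity(.data$score) == "negative"),
    AEp = if (any(sentiment_polarity(.data$score) == "positive"))
      mean(.data$score[sentiment_polarity(.data$score) == "positive"]) else NA_real_,
    AEN = if (any(sentiment_polarity(.data$score) == "negative"))
      mean(.data$score[sentiment_polarity(.data$score) == "negative"]) else NA_real_,
    .groups = "drop"
  )
}
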