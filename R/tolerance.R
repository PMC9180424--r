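#' Psychological tolerance index
#'
#' The prefecture-level tolerance index combines post counts, sentiment
#' means and haze severity:
#' \deqn{T = \frac{W_{Ep} \cdot A_{Ep}}{W_{EN} \cdot (1 - A_{EN}) \cdot C_{PM2.5}}}
#' where \eqn{W_{Ep}} / \eqn{W_{EN}} are the counts of positive and
#' negative posts, \eqn{A_{Ep}} / \eqn{A_{EN}} their mean sentiment
#' scores, and \eqn{C_{PM2.5}} the mean PM2.5 concentration (ug/m3). The
#' larger the index, the higher the population's tolerance of haze. T is
#' undefined — flagged `NA`, not epsilon-patched — when a polarity group
#' is empty (`WEp = 0` or `WEN = 0`) or `AEN = 1`, since a silently
#' patched value would distort downstream class binning.
#'
#' @param WEp,WEN non-negative post counts.
#' @param AEp,AEN mean sentiment scores in `[0, 1]` (may be `NA` when the
#'   group is empty).
#' @param CPM25 mean PM2.5 concentration, strictly positive.
#' @return numeric vector of T values with `NA` where undefined.
#' @export
tolerance <- function(WEp, WEN, AEp, AEN, CPM25) {
  if (any(CPM25 <= 0, na.rm = TRUE) || anyNA(CPM25)) {
    stop("CPM25 must be a positive concentration")
  }
  if (any(WEp < 0 | WEN < 0, na.rm = TRUE)) stop("post counts must be non-negative")
  undefined <- WEp == 0 | WEN == 0 | (!is.na(AEN) & AEN == 1) | is.na(AEp) | is.na(AEN)
  t_val <- rep(NA_real_, length(WEp))
  ok <- !undefined
  t_val[ok] <- (WEp[ok] * AEp[ok]) / (WEN[ok] * (1 - AEN[ok]) * CPM25[ok])
  t_val
}

#' Tolerance panel with 5-class reclassification
#'
#' Joins per-region-season sentiment aggregates with seasonal PM2.5 means,
#' computes [tolerance()] for every row, and reclassifies the defined T
#' values into `n_classes` equal-interval bins over the pooled panel (all
#' periods together), so class codes are comparable across time — a
#' requirement for trajectory coding. Bins are right-open except the last,
#' which is closed, and run from the panel minimum to the panel maximum of
#' the defined T values; with a single defined value (degenerate range)
#' that value falls in the top class. Regions present in the corpus but
#' missing from the PM2.5 table are reported with `NA` PM2.5 and T, never
#' dropped.
#'
#' @param aggregates tibble from [aggregate_sentiment()] /
#'   [score_corpus()]: region, season, WEp, WEN, AEp, AEN.
#' @param pm25_means tibble: region, season, CPM25 (seasonal mean
#'   concentration).
#' @param n_classes number of tolerance classes (default 5, labelled 1 =
#'   low tolerance ... 5 = high tolerance).
#' @return tibble: region, season, WEp, WEN, AEp, AEN, CPM25, T, class
#'   (integer, `NA` where T is undefined or PM2.5 missing).
#' @export
tolerance_panel <- function(aggregates, pm25_means, n_classes = 5) {
  if (n_classes < 2) stop("n_classes must be at least 2")
  need <- c("region", "season", "CPM25")
  miss <- setdiff(need, names(pm25_means))
  if (length(miss) > 0) stop("pm25_means is missing columns: ", paste(miss, collapse = ", "))
  out <- dplyr::left_join(aggregates, pm25_means, by = c("region", "season"))
  has_air <- !is.na(out$CPM25)
  out$T <- NA_real_
  out$T[has_air] <- tolerance(out$WEp[has_air], out$WEN[has_air],
                              out$AEp[has_air], out$AEN[has_air], out$CPM25[has_air])
  out$class <- classify_equal_interval(out$T, n_classes)
  out
}

#' Equal-interval reclassification into 1..n classes
#'
#' @param x numeric vector (`NA`s stay `NA`).
#' @param n_classes number of bins.
#' @return integer class codes in `1..n_classes`.
#' @export
classify_equal_interval <- function(x, n_classes = 5) {
  cls <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(cls)
  rng <- range(x[ok])
  if (rng[1] == rng[2]) {
    cls[ok] <- n_classes   # sole occupied bin: top class by convention
    return(cls)
  }
  width <- (rng[2] - rng[1]) / n_classes
  idx <- floor((x[ok] - rng[1]) / width) + 1
  idx[idx > n_classes] <- n_classes   # closes the last bin at the maximum
  cls[ok] <- as.integer(idx)
  cls
}
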