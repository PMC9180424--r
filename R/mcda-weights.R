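#' Construct a pairwise-comparison judgment matrix
#'
#' A judgment matrix encodes expert pairwise comparisons of criteria on the
#' 1--9 scale: entry \eqn{a_{ij}} is the judged importance of criterion
#' \eqn{i} relative to criterion \eqn{j}. A valid matrix is square, strictly
#' positive, has a unit diagonal and is reciprocal
#' (\eqn{a_{ij} a_{ji} = 1}).
#'
#' @param x numeric matrix of positive entries.
#' @param labels optional character vector of criterion names; defaults to
#'   the matrix dimnames or `C1..Cn`.
#' @param reciprocity_tol maximum tolerated relative deviation of
#'   \eqn{a_{ij} a_{ji}} from 1. Printed matrices are rounded to about five
#'   decimals, so the default allows 1e-3.
#' @return a `judgment_matrix` object (a labelled numeric matrix).
#' @export
judgment_matrix <- function(x, labels = NULL, reciprocity_tol = 1e-3) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop("judgment matrix must be square, got ", nrow(x), "x", ncol(x))
  }
  if (!is.numeric(x) || anyNA(x)) stop("judgment matrix entries must be numeric and non-missing")
  if (any(x <= 0)) stop("judgment matrix entries must be strictly positive")
  if (is.null(labels)) {
    labels <- rownames(x) %||% colnames(x) %||% paste0("C", seq_len(nrow(x)))
  }
  if (length(labels) != nrow(x)) stop("labels length must equal matrix order")
  if (any(abs(diag(x) - 1) > reciprocity_tol)) stop("diagonal entries must equal 1")
  prod_dev <- abs(x * t(x) - 1)
  bad <- which(prod_dev > reciprocity_tol, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad) > 0) {
    cells <- apply(bad, 1, function(ij) {
      sprintf("(%s,%s): a_ij*a_ji = %.6f", labels[ij[1]], labels[ij[2]], x[ij[1], ij[2]] * x[ij[2], ij[1]])
    })
    stop("reciprocity violated in cells ", paste(cells, collapse = "; "))
  }
  dimnames(x) <- list(labels, labels)
  structure(x, class = c("judgment_matrix", "matrix", "array"))
}

#' @export
print.judgment_matrix <- function(x, ...) {
  cat("Judgment matrix (", nrow(x), "x", ncol(x), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Read a judgment matrix from CSV
#'
#' Expects a header row of criterion labels and a first column repeating
#' them, as in the matrices shipped under `inst/extdata/table6.csv` ...
#' `table9.csv`.
#'
#' @param path path to the CSV file.
#' @inheritParams judgment_matrix
#' @return a [judgment_matrix()].
#' @export
read_judgment_matrix <- function(path, reciprocity_tol = 1e-3) {
  if (!file.exists(path)) stop("judgment matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  judgment_matrix(m, labels = labels, reciprocity_tol = reciprocity_tol)
}

#' Average random consistency index (RI)
#'
#' Order-dependent constants used in the consistency ratio CR = CI / RI.
#' Tabulated for matrix orders 1 through 9.
#'
#' @param n matrix order, an integer between 1 and 9.
#' @return the RI value.
#' @export
ri_lookup <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 1) {
    stop("matrix order must be a single integer >= 1")
  }
  if (n > 9) stop("RI table only covers orders 1-9, got ", n)
  ri[n]
}

#' Principal-eigenvector weights and consistency test
#'
#' Derives priority weights from a judgment matrix as its principal
#' eigenvector (power iteration on the positive matrix, normalised to sum
#' to one), with the principal eigenvalue \eqn{\lambda_{max}} taken from
#' the converged Rayleigh quotient. The consistency index is
#' \eqn{CI = (\lambda_{max} - n)/(n - 1)} and the consistency ratio
#' \eqn{CR = CI / RI(n)}; matrices with CR below 0.1 are deemed
#' acceptably consistent. For orders 1 and 2 the RI is zero and CR is
#' defined to be 0 (such matrices are always consistent).
#'
#' @param M a [judgment_matrix()] or a plain positive reciprocal matrix.
#' @param tol relative convergence tolerance of the power iteration.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return list with `weights` (named, sums to 1) and `consistency`, a
#'   one-row tibble with `lambda_max`, `CI`, `RI`, `CR`, `consistent`.
#' @export
ahp_weights <- function(M, tol = 1e-12, max_iter = 10000) {
  if (!inherits(M, "judgment_matrix")) M <- judgment_matrix(M)
  n <- nrow(M)
  A <- unclass(M)
  if (n == 1) {
    w <- stats::setNames(1, rownames(M))
    cons <- tibble::tibble(lambda_max = 1, CI = 0, RI = 0, CR = 0, consistent = TRUE)
    return(list(weights = w, consistency = cons))
  }
  w <- rep(1 / n, n)
  lambda <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v <- as.vector(A %*% w)
    lambda_new <- sum(w * v) / sum(w * w)   # Rayleigh quotient
    v <- v / sum(v)
    if (max(abs(v - w)) < tol * max(abs(v)) &&
        !is.na(lambda) && abs(lambda_new - lambda) < tol * lambda_new) {
      w <- v
      lambda <- lambda_new
      converged <- TRUE
      break
    }
    w <- v
    lambda <- lambda_new
  }
  if (!converged) stop("power iteration did not converge in ", max_iter, " iterations")
  ri <- ri_lookup(n)
  ci <- (lambda - n) / (n - 1)
  cr <- if (ri == 0) 0 else ci / ri
  list(
    weights = stats::setNames(w, rownames(M)),
    consistency = tibble::tibble(
      lambda_max = lambda, CI = ci, RI = ri, CR = cr, consistent = cr < 0.1
    )
  )
}

#' Compose hierarchical weights into absolute indicator weights
#'
#' In a two-level hierarchy the absolute weight of an indicator is the
#' product of its rule-layer (first-level) weight and its within-group
#' weight; absolute weights over all indicators again sum to one.
#'
#' @param first_level named numeric vector of rule-layer weights (sums to 1).
#' @param groups named list, one numeric within-group weight vector per
#'   rule layer, names matching `first_level`.
#' @return tibble with `rule_layer`, `indicator`, `group_weight`,
#'   `absolute_weight`.
#' @export
compose_hierarchy <- function(first_level, groups) {
  if (!setequal(names(first_level), names(groups)) ||
      is.null(names(first_level)) || is.null(names(groups))) {
    stop("rule-layer names of 'first_level' and 'groups' must match")
  }
  check_sums_to_one(first_level, "first_level")
  out <- lapply(names(first_level), function(g) {
    w <- groups[[g]]
    check_sums_to_one(w, paste0("groups$", g))
    tibble::tibble(
      rule_layer = g,
      indicator = names(w) %||% paste0(g, "_", seq_along(w)),
      group_weight = unname(w),
      absolute_weight = unname(first_level[[g]] * w)
    )
  })
  dplyr::bind_rows(out)
}

check_sums_to_one <- function(w, what, tol = 1e-6) {
  if (any(w < 0)) stop(what, " has negative weights")
  if (abs(sum(w) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(w)), ")")
  }
  invisible(w)
}

#' Range (min-max) standardization of an indicator panel
#'
#' Benefit indicators map to \eqn{(x - min)/(max - min)}, cost indicators
#' to \eqn{(max - x)/(max - min)}, column-wise across evaluation objects.
#' Exact zeros are then replaced by 0.01 so the subsequent entropy step is
#' defined on strictly positive shares. A constant column has no range; it
#' is set to 1 for every object, so it carries maximal entropy and ends up
#' with zero information weight.
#'
#' @param panel data frame; all columns named in `directions` must be numeric.
#' @param directions named character vector over the indicator columns,
#'   values `"benefit"` or `"cost"`.
#' @param zero_replacement value substituted for exact zeros (default 0.01).
#' @return tibble of standardized values `Y`, same rows, indicator columns
#'   only, values in `[0.01, 1]`.
#' @export
standardize_panel <- function(panel, directions, zero_replacement = 0.01) {
  miss <- setdiff(names(directions), names(panel))
  if (length(miss) > 0) stop("panel is missing indicator columns: ", paste(miss, collapse = ", "))
  if (!all(directions %in% c("benefit", "cost"))) {
    stop("directions must be 'benefit' or 'cost'")
  }
  if (nrow(panel) < 2) stop("standardization needs at least 2 evaluation objects")
  cols <- names(directions)
  out <- lapply(cols, function(j) {
    x <- panel[[j]]
    if (!is.numeric(x)) stop("non-numeric values in indicator column '", j, "'")
    if (anyNA(x)) stop("missing values in indicator column '", j, "'")
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(1, length(x)))
    y <- if (directions[[j]] == "benefit") (x - rng[1]) / (rng[2] - rng[1])
         else (rng[2] - x) / (rng[2] - rng[1])
    y[y == 0] <- zero_replacement
    y
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' Entropy weights of standardized indicators
#'
#' For each indicator \eqn{j}, the share of object \eqn{i} is
#' \eqn{P_{ij} = Y_{ij} / \sum_i Y_{ij}}; the indicator's entropy is
#' \eqn{e_j = -\frac{1}{\ln m} \sum_i P_{ij} \ln P_{ij}} with \eqn{m} the
#' number of evaluation objects, so \eqn{e_j \in [0, 1]}; the entropy
#' weight is \eqn{S_j = (1 - e_j) / \sum_j (1 - e_j)}. Indicators whose
#' values are more dispersed across objects carry more information and get
#' more weight; a constant (uniform-share) indicator has entropy 1 and
#' weight 0.
#'
#' @param Y strictly positive standardized table as returned by
#'   [standardize_panel()].
#' @return list with `P` (share matrix), `entropy` (named e_j) and
#'   `weights` (named S_j summing to 1).
#' @export
entropy_weights <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y <= 0)) stop("entropy weighting needs strictly positive standardized values")
  m <- nrow(Y)
  if (m < 2) stop("entropy weighting needs at least 2 evaluation objects")
  P <- sweep(Y, 2, colSums(Y), "/")
  e <- -colSums(P * log(P)) / log(m)
  # clamp tiny fp overshoot above the theoretical maximum of 1
  e <- pmin(e, 1)
  d <- 1 - e
  if (sum(d) <= 0) stop("every indicator is uniform across objects; entropy weights are degenerate")
  S <- d / sum(d)
  list(P = P, entropy = e, weights = S)
}

#' Combine subjective and objective weights
#'
#' The combination weight is the normalised geometric mean
#' \eqn{\omega_i = \sqrt{\omega_{1i}\,\omega_{2i}} / \sum_k
#' \sqrt{\omega_{1k}\,\omega_{2k}}} of the subjective (AHP) weight
#' \eqn{\omega_{1i}} and the objective (entropy) weight \eqn{\omega_{2i}}.
#'
#' @param w1,w2 non-negative weight vectors of equal length, each summing
#'   to 1.
#' @return combined weight vector summing to 1; names taken from `w1`.
#' @export
combine_weights <- function(w1, w2) {
  if (length(w1) != length(w2)) {
    stop("weight vectors differ in length: ", length(w1), " vs ", length(w2))
  }
  check_sums_to_one(w1, "w1")
  check_sums_to_one(w2, "w2")
  g <- sqrt(w1 * w2)
  stats::setNames(g / sum(g), names(w1))
}

#' Composite tolerance score per evaluation object
#'
#' The composite score of object \eqn{i} is the weighted sum
#' \eqn{z_i = \sum_j \omega_j x_{ij}} of its standardized indicator values;
#' with weights summing to 1 and standardized values in `[0, 1]`, `z` lies
#' in `[0, 1]`. Per-indicator contributions \eqn{\omega_j x_{ij}} are
#' retained for reporting.
#'
#' @param weights named weight vector over exactly the indicator columns.
#' @param Y standardized indicator table (one row per object).
#' @param ids optional data frame of identifier columns (e.g. region, year)
#'   to carry along, one row per object.
#' @return tibble with the id columns, `z`, and one `contrib_<indicator>`
#'   column per indicator.
#' @export
composite_score <- function(weights, Y, ids = NULL) {
  if (is.null(names(weights))) stop("weights must be named by indicator")
  miss <- setdiff(names(weights), names(Y))
  if (length(miss) > 0) stop("standardized table is missing indicators: ", paste(miss, collapse = ", "))
  check_sums_to_one(weights, "weights")
  Ym <- as.matrix(Y[, names(weights), drop = FALSE])
  contrib <- sweep(Ym, 2, weights, "*")
  out <- tibble::as_tibble(contrib, .name_repair = ~ paste0("contrib_", names(weights)))
  out <- tibble::add_column(out, z = rowSums(contrib), .before = 1)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble::as_tibble(ids), out)
  out
}

#' Full AHP-entropy weight table for the 18-indicator evaluation system
#'
#' Convenience wrapper tying the pieces together for the standard
#' three-rule-layer evaluation system: computes within-group AHP weights
#' from the four judgment matrices (one first-level, three second-level),
#' composes them into absolute subjective weights, computes entropy weights
#' from a standardized panel, and combines the two.
#'
#' @param matrices named list of four [judgment_matrix()] objects:
#'   `first_level` plus one per rule layer, names matching the
#'   `first_level` labels.
#' @param Y standardized indicator panel whose columns are the indicator
#'   labels of the second-level matrices (any order).
#' @return list with `table` (tibble: rule_layer, indicator, ahp, entropy,
#'   combined) and `consistency` (tibble of per-matrix CR reports).
#' @export
weight_table <- function(matrices, Y) {
  if (is.null(matrices$first_level)) stop("matrices must include 'first_level'")
  top <- ahp_weights(matrices$first_level)
  layer_names <- names(top$weights)
  miss <- setdiff(layer_names, names(matrices))
  if (length(miss) > 0) stop("missing second-level matrices for: ", paste(miss, collapse = ", "))
  groups <- list()
  cons <- list(dplyr::mutate(top$consistency, matrix = "first_level", .before = 1))
  for (g in layer_names) {
    res <- ahp_weights(matrices[[g]])
    groups[[g]] <- res$weights
    cons[[g]] <- dplyr::mutate(res$consistency, matrix = g, .before = 1)
  }
  subj <- compose_hierarchy(top$weights, groups)
  miss <- setdiff(subj$indicator, names(Y))
  if (length(miss) > 0) stop("standardized panel is missing indicators: ", paste(miss, collapse = ", "))
  ent <- entropy_weights(Y[, subj$indicator, drop = FALSE])
  w1 <- stats::setNames(subj$absolute_weight, subj$indicator)
  w2 <- ent$weights[subj$indicator]
  comb <- combine_weights(w1, w2)
  list(
    table = tibble::tibble(
      rule_layer = subj$rule_layer,
      indicator = subj$indicator,
      ahp = unname(w1),
      entropy = unname(w2),
      combined = unname(comb)
    ),
    consistency = dplyr::bind_rows(cons)
  )
}

#' Paths to the bundled judgment-matrix fixtures
#'
#' The four expert pairwise-comparison matrices of the standard evaluation
#' system ship with the package: the first-level matrix over the three rule
#' layers (ecological environment, social economy, social media) and one
#' second-level matrix per layer.
#'
#' @return named character vector of file paths (`first_level`,
#'   `ecological_environment`, `social_economy`, `social_media`).
#' @export
judgment_matrix_paths <- function() {
  f <- function(x) system.file("extdata", x, package = "hazetol", mustWork = TRUE)
  c(
    first_level = f("table6.csv"),
    ecological_environment = f("table7.csv"),
    social_economy = f("table8.csv"),
    social_media = f("table9.csv")
  )
}

#' Load the bundled judgment matrices
#'
#' @return named list of [judgment_matrix()] objects suitable for
#'   [weight_table()].
#' @export
load_judgment_matrices <- function() {
  lapply(judgment_matrix_paths(), read_judgment_matrix)
}
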