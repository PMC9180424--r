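#' Encode a class-state sequence as a base-10 trajectory code
#'
#' A unit observed over \eqn{q > 1} time phases, with class state
#' \eqn{P_i \in \{1, \dots, 9\}} in phase \eqn{i}, is summarised by the
#' positional code \eqn{C = \sum_i P_i \, 10^{q-i}}: the i-th decimal digit
#' of \eqn{C} is the state in phase i, so e.g. states (1,2,3,2) encode to
#' 1232. Codes are returned as digit strings, which survive any sequence
#' length; [trajectory_code_int()] parses them to integers when q <= 18.
#'
#' @param states integer vector of class states, each in 1..9, length >= 2.
#' @return the trajectory code as a digit string.
#' @export
encode_trajectory <- function(states) {
  if (length(states) < 2) stop("a trajectory needs at least 2 time phases")
  if (anyNA(states)) stop("states must not be missing; filter incomplete units first")
  if (any(states != round(states)) || any(states < 1) || any(states > 9)) {
    stop("states must be integers in 1..9 (positional decimal digits)")
  }
  paste(as.integer(states), collapse = "")
}

#' Parse a trajectory code string to an integer
#'
#' @param code digit string from [encode_trajectory()].
#' @return numeric value of the code (exact for q <= 18 digits).
#' @export
trajectory_code_int <- function(code) {
  if (nchar(code) > 18) stop("code of ", nchar(code), " digits exceeds exact integer range; keep it as a string")
  as.numeric(code)
}

#' Decode a trajectory code back into its state sequence
#'
#' Inverse of [encode_trajectory()]: splits the code's `q` decimal digits
#' back into per-phase states. A zero digit is invalid because class states
#' start at 1.
#'
#' @param code trajectory code, digit string or number.
#' @param q number of time phases the code must span.
#' @return integer vector of states, length `q`.
#' @export
decode_trajectory <- function(code, q) {
  s <- if (is.character(code)) code else format(code, scientific = FALSE)
  if (!grepl("^[0-9]+$", s)) stop("code must be a non-negative integer or digit string")
  if (nchar(s) != q) stop("code '", s, "' does not have q = ", q, " digits")
  digits <- as.integer(strsplit(s, "")[[1]])
  if (any(digits == 0)) stop("code contains a zero digit; class states start at 1")
  digits
}

#' Classify the shape of a tolerance-class trajectory
#'
#' Reduces a state sequence to its signed shape and maps it onto the
#' five-type change taxonomy. Successive differences are computed, zero
#' differences (plateaus) are dropped, and runs of equal sign are collapsed
#' to a single sign, giving a pattern like `(-,+)`. The mapping is:
#' empty pattern (constant sequence) -> `no_change`; `(-,+)` ->
#' `decline_rise`; `(-,+,-)` -> `decline_rise_decline`; `(+,-,+)` ->
#' `rise_decline_rise`; anything else, including purely monotone rises or
#' falls and patterns of four or more sign runs, -> `complex`. The taxonomy
#' has no monotone class, so monotone sequences land in `complex` rather
#' than inventing a sixth type. The label depends only on the ordering of
#' states, so any strictly increasing relabeling leaves it unchanged.
#'
#' @param states integer vector of class states, length >= 2; any missing
#'   state makes the type `NA`.
#' @return one of `"no_change"`, `"decline_rise"`, `"decline_rise_decline"`,
#'   `"rise_decline_rise"`, `"complex"`, or `NA_character_`.
#' @export
classify_change_type <- function(states) {
  if (length(states) < 2) stop("a trajectory needs at least 2 time phases")
  if (anyNA(states)) return(NA_character_)
  d <- sign(diff(states))
  d <- d[d != 0]
  if (length(d) == 0) return("no_change")
  pattern <- d[c(TRUE, diff(d) != 0)]   # collapse equal-sign runs
  key <- paste(pattern, collapse = ",")
  switch(key,
    "-1,1" = "decline_rise",
    "-1,1,-1" = "decline_rise_decline",
    "1,-1,1" = "rise_decline_rise",
    "complex"
  )
}

change_types <- c(
  "no_change", "decline_rise", "decline_rise_decline",
  "rise_decline_rise", "complex"
)

#' Trajectory codes and change types for a set of units
#'
#' Applies [encode_trajectory()] and [classify_change_type()] to every
#' unit's state sequence and summarises the result. Units with any missing
#' state are excluded from the coded table and summary but listed
#' separately, never silently dropped.
#'
#' @param states data frame with columns `unit_id`, `period`, `state`
#'   (one row per unit-period), or a named list of state vectors. All units
#'   must share the same number of phases.
#' @return list with `table` (tibble: unit_id, code, change_type),
#'   `incomplete` (unit ids excluded for missing states), and `summary`
#'   (list: n_units, q, n_distinct_codes, n_distinct_patterns, type_counts).
#'   Distinct-code and distinct-collapsed-pattern counts are both reported,
#'   since either can serve as the count of trajectory-change varieties.
#' @export
trajectory_table <- function(states) {
  if (is.data.frame(states)) {
    need <- c("unit_id", "period", "state")
    miss <- setdiff(need, names(states))
    if (length(miss) > 0) stop("states table is missing columns: ", paste(miss, collapse = ", "))
    states <- states[order(states$unit_id, states$period), ]
    seqs <- split(states$state, states$unit_id)
  } else if (is.list(states)) {
    seqs <- states
    if (is.null(names(seqs))) names(seqs) <- paste0("unit", seq_along(seqs))
  } else {
    stop("states must be a data frame or a named list of state vectors")
  }
  q <- unique(lengths(seqs))
  if (length(q) != 1) {
    stop("ragged sequences: units differ in number of phases (", paste(q, collapse = ", "), ")")
  }
  complete <- vapply(seqs, function(s) !anyNA(s), logical(1))
  incomplete <- names(seqs)[!complete]
  seqs <- seqs[complete]
  tab <- tibble::tibble(
    unit_id = names(seqs),
    code = vapply(seqs, encode_trajectory, character(1)),
    change_type = vapply(seqs, classify_change_type, character(1))
  )
  patterns <- vapply(seqs, function(s) {
    d <- sign(diff(s)); d <- d[d != 0]
    if (length(d) == 0) "" else paste(d[c(TRUE, diff(d) != 0)], collapse = ",")
  }, character(1))
  counts <- table(factor(tab$change_type, levels = change_types))
  list(
    table = tab,
    incomplete = incomplete,
    summary = list(
      n_units = nrow(tab),
      q = q,
      n_distinct_codes = length(unique(tab$code)),
      n_distinct_patterns = length(unique(patterns)),
      type_counts = stats::setNames(as.integer(counts), names(counts))
    )
  )
}
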