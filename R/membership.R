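#' Construct a membership table
#'
#' A membership table holds, for each item, the collapse (membership)
#' probabilities for two concepts `A` and `B` and for their disjunction
#' `A or B`. When the data arise from a forced-choice ("pick the best
#' member") experiment, or from renormalised Likert ratings (see
#' [likert_to_collapse()]), each of the three columns is a probability
#' distribution over the items and sums to 1.
#'
#' @param item character vector of unique item labels.
#' @param mu_A,mu_B,mu_AorB numeric vectors in \[0, 1\]: collapse
#'   probabilities of each item under concept A, concept B, and the
#'   disjunction.
#' @return A data frame of class `"membership_table"` with columns
#'   `item`, `mu_A`, `mu_B`, `mu_AorB`. Items with `mu_A == 0` or
#'   `mu_B == 0` are flagged with a warning: the interference phase is
#'   undefined for them (division by `sqrt(mu_A * mu_B)` downstream).
#' @seealso [read_membership_table()], [fruits_vegetables_table()],
#'   [disjunction_model()]
#' @examples
#' membership_table(c("a", "b"), c(0.6, 0.4), c(0.3, 0.7), c(0.5, 0.5))
#' @export
membership_table <- function(item, mu_A, mu_B, mu_AorB) {
  item <- as.character(item)
  mu_A <- as.numeric(mu_A)
  mu_B <- as.numeric(mu_B)
  mu_AorB <- as.numeric(mu_AorB)
  n <- length(item)
  if (n < 1L)
    stop("membership table must contain at least one item")
  if (length(mu_A) != n || length(mu_B) != n || length(mu_AorB) != n)
    stop("'item', 'mu_A', 'mu_B' and 'mu_AorB' must have equal length")
  if (anyDuplicated(item))
    stop("duplicate item labels: ",
         paste(unique(item[duplicated(item)]), collapse = ", "))
  probs <- c(mu_A, mu_B, mu_AorB)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("all membership probabilities must lie in [0, 1]")
  zero <- mu_A == 0 | mu_B == 0
  if (any(zero))
    warning("items with a zero component probability (phase undefined): ",
            paste(item[zero], collapse = ", "))
  out <- data.frame(item = item, mu_A = mu_A, mu_B = mu_B,
                    mu_AorB = mu_AorB, stringsAsFactors = FALSE)
  class(out) <- c("membership_table", "data.frame")
  out
}

as_membership_table <- function(x) {
  if (inherits(x, "membership_table")) return(x)
  need <- c("item", "mu_A", "mu_B", "mu_AorB")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  membership_table(x$item, x$mu_A, x$mu_B, x$mu_AorB)
}

#' Read or write a membership table from delimited text
#'
#' Files must carry a header `item,mu_A,mu_B,mu_AorB` (comma- or
#' tab-delimited; the delimiter is auto-detected from the header line
#' unless `sep` is given). `write_membership_table()` followed by
#' `read_membership_table()` is the identity up to printed precision.
#'
#' @param path file path.
#' @param sep field delimiter, `","` or `"\t"`; `NULL` auto-detects.
#' @return A [membership_table()].
#' @export
read_membership_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  need <- c("item", "mu_A", "mu_B", "mu_AorB")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  num <- lapply(raw[c("mu_A", "mu_B", "mu_AorB")], function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) stop("non-numeric cell in file ", path, ": ",
                       paste(col[is.na(v)], collapse = ", "))
    v
  })
  membership_table(raw$item, num$mu_A, num$mu_B, num$mu_AorB)
}

#' @param table a [membership_table()].
#' @rdname read_membership_table
#' @export
write_membership_table <- function(table, path, sep = ",") {
  table <- as_membership_table(table)
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Check column normalization of a membership table
#'
#' Each of the three probability columns of a normalised membership table
#' sums to 1; printed tables typically carry 4-decimal rounding, so the
#' default tolerance admits residuals up to 0.003.
#'
#' @param table a [membership_table()].
#' @param tol nonnegative tolerance on `|column sum - 1|`.
#' @return A list with `residuals` (named, one per column), `sums`, and
#'   logical `pass`.
#' @examples
#' validate_normalization(fruits_vegetables_table())
#' @export
validate_normalization <- function(table, tol = 0.003) {
  table <- as_membership_table(table)
  stopifnot(tol >= 0)
  sums <- c(mu_A = sum(table$mu_A), mu_B = sum(table$mu_B),
            mu_AorB = sum(table$mu_AorB))
  residuals <- abs(sums - 1)
  list(residuals = residuals, sums = sums, pass = all(residuals <= tol))
}

.classicality_levels <- c("classical", "underextension",
                          "double-underextension", "overextension",
                          "double-overextension")

#' Classicality diagnostics for disjunction membership data
#'
#' Classifies each item against the bounds a single classical (Kolmogorov
#' or fuzzy-set) probability model imposes on a disjunction:
#' `max(mu_A, mu_B) <= mu_AorB <= min(1, mu_A + mu_B)`. Falling below the
#' maximum of the components is *underextension* (below both:
#' *double-underextension*); exceeding the additive bound is
#' *overextension*. The label set includes `double-overextension` for
#' symmetry with conjunction data, though the disjunction rule above never
#' produces it. Items violating any bound admit no single classical
#' probability space.
#'
#' @param table a [membership_table()] (or any data frame with the four
#'   columns).
#' @return `classify_items()`: a factor of labels, one per item.
#'   `classicality_report()`: a list with `labels` (named factor) and
#'   `counts` (table over all five labels).
#' @examples
#' classicality_report(fruits_vegetables_table())$counts
#' @export
classify_items <- function(table) {
  table <- as_membership_table(table)
  lo <- pmax(table$mu_A, table$mu_B)
  hi <- pmin(1, table$mu_A + table$mu_B)
  lab <- rep("classical", nrow(table))
  lab[table$mu_AorB < lo] <- "underextension"
  lab[table$mu_AorB < pmin(table$mu_A, table$mu_B)] <- "double-underextension"
  lab[table$mu_AorB > hi] <- "overextension"
  factor(lab, levels = .classicality_levels)
}

#' @rdname classify_items
#' @export
classicality_report <- function(table) {
  table <- as_membership_table(table)
  labels <- classify_items(table)
  names(labels) <- table$item
  list(labels = labels, counts = table(labels))
}

#' Convert 7-point Likert ratings to collapse probabilities
#'
#' Membership degree ratings on the 7-point scale (-3..-1 degrees of
#' non-membership, 0 borderline, 1..3 degrees of membership) are shifted
#' by +3 to make them nonnegative, averaged over participants per item,
#' and divided by their sum over items, yielding a probability
#' distribution over the items that substitutes for forced-choice
#' collapse probabilities.
#'
#' @param ratings integer matrix, participants in rows, items in columns,
#'   entries in `{-3, ..., 3}`. A vector is treated as one participant.
#' @return Named numeric probability vector over items (nonnegative, sums
#'   to 1).
#' @examples
#' likert_to_collapse(rbind(c(-3, 0, 3)))
#' @export
likert_to_collapse <- function(ratings) {
  if (is.null(dim(ratings))) ratings <- matrix(ratings, nrow = 1L)
  if (anyNA(ratings) || any(ratings != round(ratings)) ||
      any(ratings < -3) || any(ratings > 3))
    stop("ratings must be integers in {-3, ..., 3}")
  shifted <- colMeans(ratings + 3)
  total <- sum(shifted)
  if (total == 0)
    stop("degenerate ratings: every rating is -3, shifted sum is zero")
  out <- shifted / total
  names(out) <- colnames(ratings)
  out
}

#' Euclidean distance between an item and a concept prototype
#'
#' In prototype theory a concept is summarised by feature applicability
#' weights; the representativeness of an item is the Euclidean distance
#' between its feature vector and the prototype's weight vector (smaller
#' means more representative).
#'
#' @param item_features,prototype_weights numeric vectors of equal length.
#' @return Nonnegative scalar `sqrt(sum((x - p)^2))`.
#' @export
prototype_distance <- function(item_features, prototype_weights) {
  if (length(item_features) != length(prototype_weights))
    stop("feature vectors must have equal length")
  if (length(item_features) < 1L)
    stop("feature vectors must be non-empty")
  sqrt(sum((item_features - prototype_weights)^2))
}

qc_extdata <- function(name) {
  path <- system.file("extdata", name, package = "qconcept")
  if (!nzchar(path)) stop("fixture not found: ", name)
  path
}

#' Packaged Fruits/Vegetables membership data
#'
#' The 24-item membership collapse probabilities for the concepts
#' *Fruits* (A), *Vegetables* (B) and *Fruits or Vegetables*, derived
#' from a published 7-point membership-rating experiment via the Likert
#' renormalisation of [likert_to_collapse()]. `fruits_vegetables_reference()` returns the
#' published per-item interference budgets, ranks, signs and phases
#' (4-decimal / one-decimal-degree rounding) used as regression
#' references.
#'
#' @return `fruits_vegetables_table()`: a 24-row [membership_table()].
#'   `fruits_vegetables_reference()`: a data frame with columns `item`,
#'   `lambda`, `rank`, `epsilon`, `phi_deg`.
#' @examples
#' head(fruits_vegetables_table())
#' @export
fruits_vegetables_table <- function() {
  read_membership_table(qc_extdata("table1_fruits_vegetables.csv"))
}

#' @rdname fruits_vegetables_table
#' @export
fruits_vegetables_reference <- function() {
  utils::read.csv(qc_extdata("table1_reference_angles.csv"),
                  stringsAsFactors = FALSE)
}
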