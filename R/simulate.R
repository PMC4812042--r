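# Seeded synthetic-data generators for every pipeline input: membership
# tables with a quantum interference structure and known ground-truth
# phases, classical tables derived from latent 2x2 joint distributions,
# and Likert rating matrices whose renormalisation recovers a target
# collapse distribution.

#' Generate a membership table with quantum interference structure
#'
#' Draws normalised component columns and ground-truth phases, then sets
#' `mu_AorB = (mu_A + mu_B)/2 + sqrt(mu_A mu_B) cos(phi)` per item (unit
#' basis overlap). By default the disjunction column is left exact — its
#' sum, generally different from 1, is recorded in the `"sum_AorB"`
#' attribute — so the fitted model recovers the generating phases. The
#' ground-truth phases are attached as attribute `"phi_true"`.
#'
#' @param n_items number of items (at least 2).
#' @param seed optional integer seed.
#' @param phase_range magnitude range of the generated phases in degrees;
#'   the default keeps the arccos recovery well-conditioned. Signs are
#'   drawn at random.
#' @param balanced if `TRUE`, recentre the interference terms (weighted
#'   by `sqrt(mu_A mu_B)`) so that the disjunction column also sums to 1
#'   exactly and the fitted concept vectors are orthogonal to machine
#'   precision; the attached phases are adjusted accordingly.
#' @param rescale_disjunction if `TRUE`, divide the disjunction column by
#'   its sum (breaks the exact interference decomposition; off by
#'   default).
#' @param max_tries resampling bound for degenerate draws.
#' @return A [membership_table()] with attributes `phi_true` (degrees)
#'   and `sum_AorB`.
#' @examples
#' tab <- gen_quantum_table(6, seed = 1)
#' attr(tab, "phi_true")
#' @export
gen_quantum_table <- function(n_items = 24L, seed = NULL,
                              phase_range = c(30, 150), balanced = FALSE,
                              rescale_disjunction = FALSE,
                              max_tries = 100L) {
  stopifnot(n_items >= 2L, length(phase_range) == 2L,
            phase_range[1] >= 0, phase_range[2] <= 180)
  if (!is.null(seed)) set.seed(seed)
  items <- sprintf("item%02d", seq_len(n_items))
  for (try in seq_len(max_tries)) {
    mu_A <- stats::rgamma(n_items, shape = 2)
    mu_B <- stats::rgamma(n_items, shape = 2)
    mu_A <- mu_A / sum(mu_A)
    mu_B <- mu_B / sum(mu_B)
    eps <- sample(c(-1, 1), n_items, replace = TRUE)
    phi <- eps * stats::runif(n_items, phase_range[1], phase_range[2])
    v <- sqrt(mu_A * mu_B)
    f <- v * cos(rad(phi))
    if (balanced) {
      f <- f - sum(f) * v / sum(v)
      if (max(abs(f / v)) > 0.99) next
      phi <- eps * deg(acos(f / v))
    }
    mu_AorB <- (mu_A + mu_B) / 2 + f
    if (any(mu_AorB < 0) || any(mu_AorB > 1)) next
    sum_AorB <- sum(mu_AorB)
    if (rescale_disjunction) mu_AorB <- mu_AorB / sum_AorB
    out <- membership_table(items, mu_A, mu_B, mu_AorB)
    attr(out, "phi_true") <- stats::setNames(phi, items)
    attr(out, "sum_AorB") <- sum_AorB
    return(out)
  }
  stop("failed to generate an admissible table in ", max_tries, " tries")
}

#' Generate a classical membership table with latent joint distributions
#'
#' Per item, draws a latent 2x2 joint distribution over membership in A
#' and in B (four cells summing to 1) and sets the component weights to
#' its margins and the disjunction weight to
#' `mu_A + mu_B - mu(A and B)`. Every item therefore satisfies the
#' classical disjunction bounds, and every quadruple of cells has
#' [i_statistic()] exactly zero. The columns are per-item weights, not a
#' collapse distribution over items, so they do not sum to 1.
#'
#' @param n_items number of items.
#' @param seed optional integer seed.
#' @return A list with `table` (a [membership_table()]) and `quadruples`
#'   (data frame with `item`, `mu_AB`, `mu_ABp`, `mu_ApB`, `mu_ApBp`).
#' @export
gen_classical_table <- function(n_items = 24L, seed = NULL) {
  stopifnot(n_items >= 1L)
  if (!is.null(seed)) set.seed(seed)
  items <- sprintf("item%02d", seq_len(n_items))
  cells <- matrix(stats::rgamma(4L * n_items, shape = 1), ncol = 4L)
  cells <- cells / rowSums(cells)
  colnames(cells) <- c("mu_AB", "mu_ABp", "mu_ApB", "mu_ApBp")
  mu_A <- cells[, "mu_AB"] + cells[, "mu_ABp"]
  mu_B <- cells[, "mu_AB"] + cells[, "mu_ApB"]
  mu_AorB <- mu_A + mu_B - cells[, "mu_AB"]
  list(table = membership_table(items, mu_A, mu_B, mu_AorB),
       quadruples = data.frame(item = items, cells,
                               stringsAsFactors = FALSE))
}

#' Simulate 7-point Likert ratings with a target collapse distribution
#'
#' Samples one integer rating in `{-3, ..., 3}` per participant and item
#' such that the expected shifted rating is proportional to the target
#' weight (shifted ratings are Binomial(6, p) draws with
#' `p = weight / max(weight)`). [likert_to_collapse()] applied to the
#' sample converges to `true_weights` as the number of participants
#' grows.
#'
#' @param true_weights probability vector over items (nonnegative, sums
#'   to 1).
#' @param participants number of participants (rows).
#' @param seed optional integer seed.
#' @return Integer matrix `participants` by `length(true_weights)` with
#'   entries in `{-3, ..., 3}`; column names from `true_weights`.
#' @export
gen_likert <- function(true_weights, participants, seed = NULL) {
  if (any(true_weights < 0) || abs(sum(true_weights) - 1) > 1e-8)
    stop("'true_weights' must be a probability vector")
  stopifnot(participants >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_weights)
  p <- true_weights / max(true_weights)
  shifted <- vapply(p, function(pk) stats::rbinom(participants, 6L, pk),
                    integer(participants))
  if (participants == 1L) shifted <- matrix(shifted, nrow = 1L)
  ratings <- shifted - 3L
  colnames(ratings) <- names(true_weights)
  ratings
}
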