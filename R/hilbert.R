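# Complex Hilbert-space representation of two concepts and their disjunction.
#
# Each item k gets the decomposition
#   mu_k(A or B) = (mu_k(A) + mu_k(B))/2 + c_k sqrt(mu_k(A) mu_k(B)) cos(phi_k)
# where the second term is the interference between the two concept states.
# The per-item budget lambda_k bounds the interference magnitude at unit basis
# overlap (c_k = 1); a greedy partial-sum scheme over the ranked budgets
# assigns the phase signs so that the sine-sum orthogonality constraint can be
# closed by a single overlap coefficient c_m < 1 on the top-ranked item.

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Per-item interference budget
#'
#' The maximal magnitude of the interference term for an item at unit
#' basis overlap:
#' `sqrt(mu_A * mu_B - (mu_AorB - (mu_A + mu_B)/2)^2)`.
#'
#' @param mu_A,mu_B,mu_AorB numeric vectors of collapse probabilities.
#' @param item optional labels used in error messages.
#' @return Numeric vector of budgets, one per item.
#' @examples
#' interference_lambda(0.0359, 0.0133, 0.0269)  # Almond: 0.0217
#' @export
interference_lambda <- function(mu_A, mu_B, mu_AorB, item = NULL) {
  dev <- mu_AorB - (mu_A + mu_B) / 2
  radicand <- mu_A * mu_B - dev^2
  bad <- radicand < 0
  if (any(bad)) {
    who <- if (is.null(item)) which(bad) else item[bad]
    stop("interference model infeasible (|deviation| > sqrt(mu_A*mu_B)) for: ",
         paste(who, collapse = ", "))
  }
  sqrt(radicand)
}

#' Per-item interference phase
#'
#' The phase whose cosine reproduces the observed deviation of the
#' disjunction probability from the classical average:
#' `epsilon * acos((mu_AorB - (mu_A + mu_B)/2) / (c * sqrt(mu_A * mu_B)))`,
#' reported in degrees.
#'
#' @inheritParams interference_lambda
#' @param c basis-overlap coefficient(s) in (0, 1].
#' @param epsilon phase sign(s), +1 or -1.
#' @return Signed phases in degrees.
#' @examples
#' interference_phase(0.0359, 0.0133, 0.0269)  # Almond: 84.0 degrees
#' @export
interference_phase <- function(mu_A, mu_B, mu_AorB, c = 1, epsilon = 1,
                               item = NULL) {
  stopifnot(all(c > 0), all(c <= 1), all(epsilon %in% c(-1, 1)))
  arg <- (mu_AorB - (mu_A + mu_B) / 2) / (c * sqrt(mu_A * mu_B))
  bad <- !is.finite(arg) | abs(arg) > 1
  if (any(bad)) {
    who <- if (is.null(item)) which(bad) else item[bad]
    stop("interference phase undefined (cosine argument outside [-1, 1]) for: ",
         paste(who, collapse = ", "))
  }
  epsilon * deg(acos(arg))
}

#' Greedy partial-sum sign assignment over ranked budgets
#'
#' Orders the budgets from largest to smallest (ties broken by original
#' position) and assigns each a sign: the largest gets +1; each subsequent
#' budget is subtracted when the running sum stays nonnegative, otherwise
#' added. The running sum therefore never goes negative and the final sum
#' is the residual the top-ranked item's overlap coefficient must absorb.
#'
#' @param lambda numeric vector of nonnegative budgets.
#' @return A list with `epsilon` (signs in the original item order),
#'   `rank` (1 = largest budget), `S_n` (final partial sum), and `trace`,
#'   a data frame of the scheme steps (`rank`, `index`, `lambda`,
#'   `epsilon`, running sum `S`).
#' @examples
#' partial_sum_signs(c(0.5, 0.3, 0.2))  # signs +, -, -; final sum 0
#' @export
partial_sum_signs <- function(lambda) {
  n <- length(lambda)
  if (n < 1L) stop("empty budget vector")
  if (any(lambda < 0)) stop("budgets must be nonnegative")
  ord <- order(lambda, decreasing = TRUE)
  eps <- integer(n)
  S <- numeric(n)
  run <- 0
  for (j in seq_len(n)) {
    k <- ord[j]
    if (j == 1L) {
      eps[k] <- 1L
      run <- lambda[k]
    } else if (run - lambda[k] >= 0) {
      eps[k] <- -1L
      run <- run - lambda[k]
    } else {
      eps[k] <- 1L
      run <- run + lambda[k]
    }
    S[j] <- run
  }
  list(epsilon = eps,
       rank = order(ord),
       S_n = run,
       trace = data.frame(rank = seq_len(n), index = ord,
                          lambda = lambda[ord], epsilon = eps[ord], S = S))
}

#' Basis-overlap coefficient for the top-ranked item
#'
#' Fixes the single overlap coefficient `c_m < 1` so the sine-sum
#' orthogonality constraint closes:
#' `sqrt(((S_n - lambda_m)^2 + (mu_AorB - (mu_A + mu_B)/2)^2) / (mu_A * mu_B))`
#' evaluated on the rank-1 item.
#'
#' @param S_n final partial sum from [partial_sum_signs()].
#' @param lambda_m budget of the rank-1 item.
#' @param mu_A,mu_B,mu_AorB the rank-1 item's probabilities.
#' @return Scalar in \[0, 1\].
#' @export
basis_overlap <- function(S_n, lambda_m, mu_A, mu_B, mu_AorB) {
  dev <- mu_AorB - (mu_A + mu_B) / 2
  cm <- sqrt(((S_n - lambda_m)^2 + dev^2) / (mu_A * mu_B))
  if (cm > 1)
    stop("no unit-norm basis overlap exists: c_m = ", format(cm), " > 1")
  cm
}

#' Fit the two-concept disjunction interference model
#'
#' Builds the complex Hilbert-space representation of two concepts and
#' their disjunction from per-item collapse probabilities. For `n` items
#' the space has `n + 1` complex dimensions: every item spans one
#' coordinate except the item with the largest interference budget, whose
#' two concept projections are allowed a basis overlap `c_m < 1` and an
#' extra coordinate. Concept A's vector has real coordinates
#' `sqrt(mu_A)` (phase 0); concept B's carries the interference phases.
#' The disjunction is the normalised superposition of the two vectors,
#' and the model reconstructs the observed disjunction column exactly.
#'
#' @param table a [membership_table()] (or coercible data frame).
#' @param normalization_tol tolerance for the column-sum check.
#' @param check_normalization if `TRUE` (default), error when a column sum
#'   deviates from 1 by more than `normalization_tol`; set `FALSE` to fit
#'   unnormalised disjunction columns (e.g. synthetic tables generated
#'   with free phases).
#' @return An object of class `"disjunction_model"`: a list with
#'   components `table`, `angles` (per-item `lambda`, `rank`, `epsilon`,
#'   `phi_deg`, `c`), `trace` and `S_n` (the partial-sum scheme),
#'   `m` (index of the rank-1 item), `c_m`, `vector_A` and `vector_B`
#'   (complex vectors of length `n + 1`), and `normalization`.
#'   Supported methods: [print()], [summary()], [coef()], [fitted()],
#'   [predict()], [residuals()], [plot()], [simulate()].
#' @examples
#' fit <- disjunction_model(fruits_vegetables_table())
#' fit$S_n                 # final partial sum (0.0154)
#' fit$c_m                 # basis overlap of the top-ranked item (0.803)
#' head(coef(fit))
#' @export
disjunction_model <- function(table, normalization_tol = 0.003,
                              check_normalization = TRUE) {
  table <- as_membership_table(table)
  norm <- validate_normalization(table, normalization_tol)
  if (check_normalization && !norm$pass)
    stop("membership table is not normalized within ", normalization_tol,
         " (residuals: ", paste(signif(norm$residuals, 3), collapse = ", "),
         "); pass check_normalization = FALSE to fit anyway")
  if (any(table$mu_A == 0 | table$mu_B == 0))
    stop("items with mu_A = 0 or mu_B = 0 have no defined phase: ",
         paste(table$item[table$mu_A == 0 | table$mu_B == 0], collapse = ", "))

  n <- nrow(table)
  lambda <- interference_lambda(table$mu_A, table$mu_B, table$mu_AorB,
                                table$item)
  scheme <- partial_sum_signs(lambda)
  m <- which(scheme$rank == 1L)
  c_k <- rep(1, n)
  c_k[m] <- basis_overlap(scheme$S_n, lambda[m], table$mu_A[m],
                          table$mu_B[m], table$mu_AorB[m])
  phi <- interference_phase(table$mu_A, table$mu_B, table$mu_AorB,
                            c = c_k, epsilon = scheme$epsilon,
                            item = table$item)

  # Explicit C^(n+1) vectors: alpha_k = gamma_k = 0, so beta_k = phi_k.
  # The rank-1 item m splits over coordinates m and n+1 on the B side:
  # b_m*c_m on coordinate m (phase phi_m), b_m*sqrt(1 - c_m^2) on n+1.
  a <- sqrt(table$mu_A)
  b <- sqrt(table$mu_B)
  vector_A <- c(a, 0) * exp(0i)
  modB <- b
  modB[m] <- b[m] * c_k[m]
  vector_B <- c(modB * exp(1i * rad(phi)), b[m] * sqrt(1 - c_k[m]^2))

  out <- list(table = table,
              angles = data.frame(item = table$item, lambda = lambda,
                                  rank = scheme$rank,
                                  epsilon = scheme$epsilon,
                                  phi_deg = phi, c = c_k,
                                  stringsAsFactors = FALSE),
              trace = scheme$trace,
              S_n = scheme$S_n,
              m = m,
              c_m = c_k[m],
              vector_A = vector_A,
              vector_B = vector_B,
              normalization = norm)
  class(out) <- "disjunction_model"
  out
}

#' Reconstruct the disjunction column from a fitted model
#'
#' Evaluates the interference decomposition
#' `(mu_A + mu_B)/2 + c_k sqrt(mu_A mu_B) cos(phi_k)` per item, which
#' equals the quantum expectation of each item projector on the
#' superposition state `(|A> + |B>)/sqrt(2)` and returns the observed
#' disjunction probabilities to machine precision.
#'
#' @param model a [disjunction_model()].
#' @return Named numeric vector of per-item disjunction probabilities.
#' @export
reconstruct_disjunction <- function(model) {
  stopifnot(inherits(model, "disjunction_model"))
  tab <- model$table
  ang <- model$angles
  out <- (tab$mu_A + tab$mu_B) / 2 +
    ang$c * sqrt(tab$mu_A * tab$mu_B) * cos(rad(ang$phi_deg))
  names(out) <- tab$item
  out
}

#' Orthogonality diagnostics of a fitted disjunction model
#'
#' The two concept vectors must be orthogonal. The real part of their
#' inner product (the "cosine sum") vanishes automatically when all three
#' probability columns are exactly normalised; on 4-decimal rounded data
#' it is bounded by the column-sum discrepancy. The imaginary part (the
#' "sine sum") is closed by the sign scheme and the overlap coefficient.
#'
#' @param model a [disjunction_model()].
#' @return A list with `cosine_residual`, `sine_residual` (both signed)
#'   and `inner_product_modulus` (= `|<A|B>|`).
#' @export
verify_orthogonality <- function(model) {
  stopifnot(inherits(model, "disjunction_model"))
  ip <- sum(Conj(model$vector_A) * model$vector_B)
  list(cosine_residual = Re(ip),
       sine_residual = Im(ip),
       inner_product_modulus = Mod(ip))
}

#' Sampled one-dimensional interference waves for an item
#'
#' The intuitive wave picture of a single item: an oscillatory wave of
#' amplitude `sqrt(mu_A)`, a second of amplitude `sqrt(mu_B)` offset by
#' the interference phase, and their half-sum, whose amplitude at the
#' origin carries the constructive/destructive interference.
#'
#' @param mu_A,mu_B component probabilities of the item.
#' @param phi_deg interference phase in degrees.
#' @param x numeric vector of sample points (radians).
#' @return Data frame with columns `x`, `wave_A`, `wave_B`,
#'   `superposition` (= `(wave_A + wave_B)/2`).
#' @export
interference_waves <- function(mu_A, mu_B, phi_deg,
                               x = seq(-2 * pi, 2 * pi, length.out = 401)) {
  wave_A <- sqrt(mu_A) * cos(x)
  wave_B <- sqrt(mu_B) * cos(x + rad(phi_deg))
  data.frame(x = x, wave_A = wave_A, wave_B = wave_B,
             superposition = (wave_A + wave_B) / 2)
}

#' Serialize a fitted model to structured text
#'
#' Writes per-item angles (`lambda`, `rank`, `epsilon`, `phi_deg`, `c`),
#' the partial-sum result, and the two concept vectors (modulus and phase
#' in degrees per coordinate) as JSON.
#'
#' @param model a [disjunction_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "disjunction_model"))
  payload <- list(
    n_items = nrow(model$table),
    dimension = length(model$vector_A),
    S_n = model$S_n,
    c_m = model$c_m,
    rank1_item = model$table$item[model$m],
    items = model$angles,
    vector_A = data.frame(modulus = Mod(model$vector_A),
                          phase_deg = deg(Arg(model$vector_A))),
    vector_B = data.frame(modulus = Mod(model$vector_B),
                          phase_deg = deg(Arg(model$vector_B))),
    orthogonality = verify_orthogonality(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.disjunction_model <- function(x, ...) {
  n <- nrow(x$table)
  cat("Two-concept disjunction interference model\n")
  cat(sprintf("  %d items embedded in C^%d\n", n, n + 1L))
  cat(sprintf("  final partial sum S_%d = %.4f\n", n, x$S_n))
  cat(sprintf("  basis overlap c_m = %.4f on rank-1 item '%s'\n",
              x$c_m, x$table$item[x$m]))
  ortho <- verify_orthogonality(x)
  cat(sprintf("  |<A|B>| = %.2e\n", ortho$inner_product_modulus))
  invisible(x)
}

#' @export
summary.disjunction_model <- function(object, ...) {
  out <- list(n = nrow(object$table),
              angles = object$angles,
              S_n = object$S_n,
              c_m = object$c_m,
              rank1_item = object$table$item[object$m],
              orthogonality = verify_orthogonality(object),
              normalization = object$normalization,
              classicality = classicality_report(object$table)$counts)
  class(out) <- "summary.disjunction_model"
  out
}

#' @export
print.summary.disjunction_model <- function(x, ...) {
  cat("Two-concept disjunction interference model\n\n")
  cat("Per-item interference parameters:\n")
  print(x$angles, digits = 4)
  cat(sprintf("\nS_%d = %.4f; c_m = %.4f (item '%s')\n",
              x$n, x$S_n, x$c_m, x$rank1_item))
  cat(sprintf("Orthogonality: cosine residual %.2e, sine residual %.2e\n",
              x$orthogonality$cosine_residual, x$orthogonality$sine_residual))
  cat("\nClassicality counts:\n")
  print(x$classicality)
  invisible(x)
}

#' @export
coef.disjunction_model <- function(object, ...) {
  object$angles
}

#' @export
fitted.disjunction_model <- function(object, ...) {
  reconstruct_disjunction(object)
}

#' Predict disjunction probabilities from fitted phases
#'
#' Applies the fitted per-item phases and overlap coefficients to
#' (possibly new) component probabilities. `newdata` must contain columns
#' `item`, `mu_A` and `mu_B`; items are matched by label to the fitted
#' phases.
#'
#' @param object a [disjunction_model()].
#' @param newdata optional data frame; defaults to the training table.
#' @param ... unused.
#' @return Named numeric vector of predicted disjunction probabilities.
#' @export
predict.disjunction_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(reconstruct_disjunction(object))
  need <- c("item", "mu_A", "mu_B")
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("newdata lacks column(s): ",
                         paste(miss, collapse = ", "))
  idx <- match(newdata$item, object$angles$item)
  if (anyNA(idx))
    stop("items not in the fitted model: ",
         paste(newdata$item[is.na(idx)], collapse = ", "))
  out <- (newdata$mu_A + newdata$mu_B) / 2 +
    object$angles$c[idx] * sqrt(newdata$mu_A * newdata$mu_B) *
    cos(rad(object$angles$phi_deg[idx]))
  names(out) <- newdata$item
  out
}

#' Residuals of a disjunction interference model
#'
#' @param object a [disjunction_model()].
#' @param type `"interference"` (default) returns the per-item deviation
#'   from the classical average, `mu_AorB - (mu_A + mu_B)/2`, i.e. the
#'   real interference term; `"reconstruction"` returns
#'   `mu_AorB - fitted`, zero to machine precision by construction.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
residuals.disjunction_model <- function(object,
                                        type = c("interference",
                                                 "reconstruction"), ...) {
  type <- match.arg(type)
  tab <- object$table
  out <- switch(type,
                interference = tab$mu_AorB - (tab$mu_A + tab$mu_B) / 2,
                reconstruction = tab$mu_AorB - reconstruct_disjunction(object))
  names(out) <- tab$item
  out
}

#' Plot the one-dimensional interference waves of selected items
#'
#' Draws, for each selected item, the component waves
#' `sqrt(mu_A) cos(x)` and `sqrt(mu_B) cos(x + phi)` and their half-sum,
#' whose squared amplitude at the origin exhibits the constructive or
#' destructive interference measured in the disjunction.
#'
#' @param x a [disjunction_model()].
#' @param items item labels or indices to draw (default: first item).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.disjunction_model <- function(x, items = 1L, ...) {
  if (is.character(items)) items <- match(items, x$table$item)
  if (anyNA(items) || any(items < 1) || any(items > nrow(x$table)))
    stop("unknown item selection")
  old <- graphics::par(mfrow = c(length(items), 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in items) {
    w <- interference_waves(x$table$mu_A[k], x$table$mu_B[k],
                            x$angles$phi_deg[k])
    graphics::matplot(w$x, w[, c("wave_A", "wave_B", "superposition")],
                      type = "l", lty = c(2, 3, 1), col = c(2, 4, 1),
                      xlab = "x", ylab = "amplitude",
                      main = sprintf("%s (phi = %.1f deg)", x$table$item[k],
                                     x$angles$phi_deg[k]), ...)
    graphics::abline(v = 0, col = "grey")
  }
  invisible(x)
}

#' Simulate membership tables from a fitted model
#'
#' Resamples the two component columns as relative frequencies of
#' `participants` forced choices (multinomial draws over items) and
#' recomputes the disjunction column from the fitted phases and overlap
#' coefficients, emulating replicate collapse-probability experiments
#' under the fitted interference structure.
#'
#' @param object a [disjunction_model()].
#' @param nsim number of tables.
#' @param seed optional integer seed.
#' @param participants number of forced choices per concept.
#' @param ... unused.
#' @return A list of `nsim` [membership_table()] objects.
#' @export
simulate.disjunction_model <- function(object, nsim = 1, seed = NULL,
                                       participants = 10000L, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$table)
  replicate(nsim, simplify = FALSE, {
    mu_A <- as.numeric(stats::rmultinom(1, participants,
                                        object$table$mu_A)) / participants
    mu_B <- as.numeric(stats::rmultinom(1, participants,
                                        object$table$mu_B)) / participants
    mu_AorB <- (mu_A + mu_B) / 2 +
      object$angles$c * sqrt(mu_A * mu_B) * cos(rad(object$angles$phi_deg))
    membership_table(object$table$item, mu_A, mu_B, mu_AorB)
  })
}
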