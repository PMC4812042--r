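# Two-dimensional interfering-prototype illustration: each concept is a
# Gaussian wave packet over a plane of items, the disjunction is their
# normalised superposition, and a polynomial field of phase differences
# theta(x, y) is interpolated so the interference density reproduces the
# observed disjunction probabilities at the item locations.

#' Gaussian wave packet
#'
#' A two-dimensional Gaussian probability density
#' `D * exp(-((x - x0)^2 / (2 sigma_x^2) + (y - y0)^2 / (2 sigma_y^2)))`,
#' where `D` is the peak density. Multiplied by the effective cell weight
#' of a [gaussian_pair()], it yields collapse probabilities at item
#' locations.
#'
#' @param D peak density, positive.
#' @param sigma_x,sigma_y packet widths, positive.
#' @param center numeric length-2 packet center `(x0, y0)`.
#' @return An object of class `"gaussian_packet"`.
#' @examples
#' p <- gaussian_packet(1.18412, 5.6539, 3.8036)
#' packet_density(p, 0, 0)
#' @export
gaussian_packet <- function(D, sigma_x, sigma_y, center = c(0, 0)) {
  stopifnot(D > 0, sigma_x > 0, sigma_y > 0, length(center) == 2)
  structure(list(D = D, sigma_x = sigma_x, sigma_y = sigma_y,
                 center = as.numeric(center)),
            class = "gaussian_packet")
}

#' @param packet a [gaussian_packet()].
#' @param x,y coordinates (vectorized).
#' @rdname gaussian_packet
#' @export
packet_density <- function(packet, x, y) {
  stopifnot(inherits(packet, "gaussian_packet"))
  packet$D * exp(-((x - packet$center[1])^2 / (2 * packet$sigma_x^2) +
                   (y - packet$center[2])^2 / (2 * packet$sigma_y^2)))
}

#' Pair of concept wave packets with an effective cell weight
#'
#' Bundles the packet of concept A (conventionally centered at the
#' origin), the packet of concept B (centered at an offset), and the
#' effective cell weight `delta_eff`: the area of the small cell around
#' each item location over which the density is integrated, so that
#' `delta_eff * density` at an item's location is its collapse
#' probability.
#'
#' @param packet_A,packet_B [gaussian_packet()] objects.
#' @param delta_eff positive effective cell weight.
#' @return An object of class `"gaussian_pair"`.
#' @export
gaussian_pair <- function(packet_A, packet_B, delta_eff = 0.1) {
  stopifnot(inherits(packet_A, "gaussian_packet"),
            inherits(packet_B, "gaussian_packet"), delta_eff > 0)
  structure(list(A = packet_A, B = packet_B, delta_eff = delta_eff),
            class = "gaussian_pair")
}

#' Calibrate a packet's peak density from the peak item's probability
#'
#' At the packet center the exponential equals 1, so
#' `delta_eff * D = mu_peak` forces `D = mu_peak / delta_eff`.
#'
#' @param mu_peak collapse probability of the item at the packet center.
#' @param delta_eff effective cell weight.
#' @return The peak density `D`.
#' @examples
#' calibrate_amplitude(0.1184)  # Fruits packet: 1.184
#' @export
calibrate_amplitude <- function(mu_peak, delta_eff = 0.1) {
  stopifnot(mu_peak > 0, delta_eff > 0)
  mu_peak / delta_eff
}

#' Packaged wave-field solution parameters
#'
#' Accessors for the published two-packet solution for the 24
#' Fruits/Vegetables items: `wavefield_pair()` returns the two Gaussian
#' packets (Fruits centered at the origin, Vegetables at (10, 4)) with
#' effective cell weight 0.1; `wavefield_coordinates()` the 24 item
#' locations; `wavefield_coefficients()` the published 24 phase-field
#' polynomial coefficients as a `"phase_field"` object.
#'
#' @return See description.
#' @export
wavefield_pair <- function() {
  par <- utils::read.csv(qc_extdata("table2_gaussian_parameters.csv"),
                         stringsAsFactors = FALSE)
  v <- function(key) par$value[match(key, par$parameter)]
  gaussian_pair(gaussian_packet(v("D_A"), v("sigma_Ax"), v("sigma_Ay")),
                gaussian_packet(v("D_B"), v("sigma_Bx"), v("sigma_By"),
                                center = c(v("a"), v("b"))),
                delta_eff = v("delta_eff"))
}

#' @rdname wavefield_pair
#' @export
wavefield_coordinates <- function() {
  utils::read.csv(qc_extdata("table2_item_coordinates.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname wavefield_pair
#' @export
wavefield_coefficients <- function() {
  co <- utils::read.csv(qc_extdata("table2_field_coefficients.csv"),
                        stringsAsFactors = FALSE)
  structure(list(coefficients = stats::setNames(co$F, co$monomial)),
            class = "phase_field")
}

# Monomial exponents of the fixed 24-term basis:
# 1, x, y, x^2, xy, y^2, ..., y^5, x^6, x^5 y, x^4 y^2.
.field_powers <- cbind(
  px = c(0, 1, 0, 2, 1, 0, 3, 2, 1, 0, 4, 3, 2, 1, 0, 5, 4, 3, 2, 1, 0, 6, 5, 4),
  py = c(0, 0, 1, 0, 1, 2, 0, 1, 2, 3, 0, 1, 2, 3, 4, 0, 1, 2, 3, 4, 5, 0, 1, 2))

.field_names <- c("1", "x", "y", "x^2", "x*y", "y^2", "x^3", "x^2*y",
                  "x*y^2", "y^3", "x^4", "x^3*y", "x^2*y^2", "x*y^3", "y^4",
                  "x^5", "x^4*y", "x^3*y^2", "x^2*y^3", "x*y^4", "y^5",
                  "x^6", "x^5*y", "x^4*y^2")

field_design_matrix <- function(x, y) {
  out <- sapply(seq_len(nrow(.field_powers)),
                function(j) x^.field_powers[j, 1] * y^.field_powers[j, 2])
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  colnames(out) <- .field_names
  out
}

#' Per-item phase targets for the wave-field solve
#'
#' Signed phases under the unit-overlap convention (`c = 1` for every
#' item, including the top-ranked one):
#' `epsilon_k * acos((mu_AorB - (mu_A + mu_B)/2) / sqrt(mu_A mu_B))`
#' in degrees. When `epsilon` is omitted, the signs come from the greedy
#' partial-sum scheme on the interference budgets.
#'
#' @param table a [membership_table()].
#' @param epsilon optional vector of signs (+1/-1), one per item.
#' @return Named vector of signed phases in degrees.
#' @examples
#' theta_targets(fruits_vegetables_table())[["Almond"]]  # 84.0
#' @export
theta_targets <- function(table, epsilon = NULL) {
  table <- as_membership_table(table)
  if (is.null(epsilon)) {
    lambda <- interference_lambda(table$mu_A, table$mu_B, table$mu_AorB,
                                  table$item)
    epsilon <- partial_sum_signs(lambda)$epsilon
  }
  stopifnot(length(epsilon) == nrow(table))
  out <- interference_phase(table$mu_A, table$mu_B, table$mu_AorB,
                            c = 1, epsilon = epsilon, item = table$item)
  names(out) <- table$item
  out
}

#' Solve the 24-coefficient polynomial phase field
#'
#' Interpolates the per-item phase targets with the fixed 24-monomial
#' polynomial `theta(x, y)` (degrees): the 24x24 design matrix of
#' monomials evaluated at the item coordinates is solved against the
#' targets, so `theta` passes exactly through every node.
#'
#' @param coords data frame with columns `x`, `y` (24 rows, pairwise
#'   distinct points).
#' @param targets numeric vector of 24 signed phases in degrees.
#' @param max_condition condition-number bound above which the design
#'   matrix is declared numerically singular.
#' @return An object of class `"phase_field"` holding the named
#'   coefficient vector and the condition estimate.
#' @examples
#' fld <- solve_phase_field(wavefield_coordinates(),
#'                          theta_targets(fruits_vegetables_table()))
#' fld$coefficients[["1"]]  # about 87.6 (Apple sits at the origin)
#' @export
solve_phase_field <- function(coords, targets, max_condition = 1e14) {
  if (nrow(coords) != 24L || length(targets) != 24L)
    stop("the phase-field basis has exactly 24 monomials; 24 nodes required")
  if (anyDuplicated(coords[, c("x", "y")]))
    stop("item coordinates must be pairwise distinct")
  P <- field_design_matrix(coords$x, coords$y)
  cond <- kappa(P, exact = FALSE)
  if (!is.finite(cond) || cond > max_condition)
    stop("phase-field design matrix is numerically singular ",
         "(condition estimate ", format(cond, digits = 3), ")")
  F <- solve(P, targets)
  structure(list(coefficients = stats::setNames(as.numeric(F), .field_names),
                 condition = cond),
            class = "phase_field")
}

#' Evaluate a phase field
#'
#' @param field a `"phase_field"` (from [solve_phase_field()] or
#'   [wavefield_coefficients()]).
#' @param x,y coordinates (vectorized).
#' @return Phases `theta(x, y)` in degrees.
#' @export
eval_phase_field <- function(field, x, y) {
  stopifnot(inherits(field, "phase_field"))
  as.numeric(field_design_matrix(x, y) %*% field$coefficients)
}

#' @export
print.phase_field <- function(x, ...) {
  cat("Polynomial phase field (degrees), 24 monomial coefficients:\n")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Pointwise density of a wave-packet layer
#'
#' For layers `"A"` and `"B"` the single-packet densities; for `"AorB"`
#' the interference density of the normalised superposition:
#' `(|psi_A|^2 + |psi_B|^2)/2 + |psi_A psi_B| cos(theta(x, y))`.
#'
#' @param pair a [gaussian_pair()].
#' @param x,y coordinates (vectorized).
#' @param field a `"phase_field"` (required for layer `"AorB"`).
#' @param layer one of `"AorB"`, `"A"`, `"B"`.
#' @return Density values (not yet multiplied by `delta_eff`).
#' @examples
#' pr <- wavefield_pair()
#' fld <- solve_phase_field(wavefield_coordinates(),
#'                          theta_targets(fruits_vegetables_table()))
#' 0.1 * interference_density(pr, 0, 0, fld)  # Apple: about 0.0688
#' @export
interference_density <- function(pair, x, y, field = NULL,
                                 layer = c("AorB", "A", "B")) {
  stopifnot(inherits(pair, "gaussian_pair"))
  layer <- match.arg(layer)
  dA <- packet_density(pair$A, x, y)
  dB <- packet_density(pair$B, x, y)
  switch(layer,
         A = dA,
         B = dB,
         AorB = {
           if (is.null(field))
             stop("a phase field is required for the interference layer")
           (dA + dB) / 2 +
             sqrt(dA * dB) * cos(rad(eval_phase_field(field, x, y)))
         })
}

#' Sample a wave-packet layer on a rectangular grid
#'
#' @inheritParams interference_density
#' @param xlim,ylim grid extent (defaults cover the packaged item
#'   coordinates).
#' @param nx,ny number of samples per axis.
#' @return An object of class `"wave_grid"`: list with axis vectors `x`,
#'   `y`, the `nx` by `ny` `density` matrix, and `layer`.
#' @export
wave_grid <- function(pair, field = NULL, layer = c("AorB", "A", "B"),
                      xlim = c(-12, 16), ylim = c(-4, 12),
                      nx = 600L, ny = 400L) {
  layer <- match.arg(layer)
  gx <- seq(xlim[1], xlim[2], length.out = nx)
  gy <- seq(ylim[1], ylim[2], length.out = ny)
  pts <- expand.grid(x = gx, y = gy)
  dens <- interference_density(pair, pts$x, pts$y, field = field,
                               layer = layer)
  structure(list(x = gx, y = gy,
                 density = matrix(dens, nrow = nx, ncol = ny),
                 layer = layer),
            class = "wave_grid")
}

#' Render a wave grid to a raster image
#'
#' Writes a PNG heat map of the layer density with optional item markers.
#'
#' @param grid a [wave_grid()].
#' @param path output PNG path.
#' @param coords optional data frame with `item`, `x`, `y`: marker
#'   positions and labels.
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
render_grid <- function(grid, path, coords = NULL,
                        width = 900L, height = 600L) {
  stopifnot(inherits(grid, "wave_grid"))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::image(grid$x, grid$y, grid$density,
                  col = grDevices::hcl.colors(64, "YlOrBr", rev = TRUE),
                  xlab = "x", ylab = "y",
                  main = sprintf("layer %s", grid$layer), useRaster = TRUE)
  if (!is.null(coords)) {
    graphics::points(coords$x, coords$y, pch = 20, cex = 0.8)
    if (!is.null(coords$item))
      graphics::text(coords$x, coords$y, coords$item, pos = 3, cex = 0.7)
  }
  invisible(path)
}

#' Locate an item on the plane of two wave packets
#'
#' Finds the point(s) where the effective cell weight times each packet
#' density reproduces the item's two component probabilities, i.e. the
#' intersection of the ellipse
#' `x^2/(2 sigma_Ax^2) + y^2/(2 sigma_Ay^2) = log(delta_eff D_A / mu_A)`
#' with its B-centered analogue. The A-ellipse is parameterised by angle
#' and the B-constraint solved as a one-dimensional root find; up to four
#' real intersections exist.
#'
#' @param mu_A,mu_B the item's component probabilities.
#' @param pair a [gaussian_pair()].
#' @param hint optional length-2 point: return the intersection nearest
#'   to it.
#' @param item optional label for error messages.
#' @param n_scan number of angular scan points for bracketing roots.
#' @return A matrix with columns `x`, `y`: one row per intersection, or a
#'   single row when `hint` is given. If the A-radius is zero (the item is
#'   the A-packet's peak), the packet center is returned directly.
#' @export
locate_item <- function(mu_A, mu_B, pair, hint = NULL, item = NULL,
                        n_scan = 720L) {
  stopifnot(inherits(pair, "gaussian_pair"))
  lab <- if (is.null(item)) "item" else item
  rA2 <- log(pair$delta_eff * pair$A$D / mu_A)
  rB2 <- log(pair$delta_eff * pair$B$D / mu_B)
  if (rA2 < 0 || rB2 < 0)
    stop("no real location for ", lab,
         ": component probability exceeds the packet peak weight")
  bfun <- function(x, y)
    (x - pair$B$center[1])^2 / (2 * pair$B$sigma_x^2) +
    (y - pair$B$center[2])^2 / (2 * pair$B$sigma_y^2) - rB2
  if (rA2 < 1e-12) {
    # degenerate A-ellipse: the location is forced to the A center
    pts <- matrix(pair$A$center, 1, 2)
  } else {
    ax <- sqrt(2 * rA2) * pair$A$sigma_x
    ay <- sqrt(2 * rA2) * pair$A$sigma_y
    g <- function(t) bfun(pair$A$center[1] + ax * cos(t),
                          pair$A$center[2] + ay * sin(t))
    ts <- seq(0, 2 * pi, length.out = n_scan + 1L)
    gs <- vapply(ts, g, numeric(1))
    roots <- ts[gs == 0]
    flip <- which(gs[-1] * gs[-length(gs)] < 0)
    for (i in flip)
      roots <- c(roots, stats::uniroot(g, c(ts[i], ts[i + 1L]),
                                       tol = 1e-14)$root)
    if (!length(roots))
      stop("no real intersection of the two constraint ellipses for ", lab)
    pts <- cbind(pair$A$center[1] + ax * cos(roots),
                 pair$A$center[2] + ay * sin(roots))
    pts <- unique(round(pts, 9))
  }
  colnames(pts) <- c("x", "y")
  if (!is.null(hint)) {
    d2 <- (pts[, 1] - hint[1])^2 + (pts[, 2] - hint[2])^2
    pts <- pts[which.min(d2), , drop = FALSE]
  }
  pts
}
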