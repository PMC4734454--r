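# World geometry and population initialization --------------------------

#' Minimal wrap-around (torus) distance between points
#'
#' Euclidean distance on a square torus of side `world`: each coordinate
#' difference is wrapped to the shorter way around.  Vectorized over
#' points.
#'
#' @param a,b numeric vectors `c(x, y)`, or two-column matrices of points.
#' @param world side length of the torus (m).
#' @return numeric distance(s); at most `world * sqrt(2) / 2`.
#' @examples
#' torus_distance(c(0, 0), c(299, 0), 300)  # 1
#' @export
torus_distance <- function(a, b, world) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 2); b <- matrix(b, ncol = 2)
    dx <- wrap_delta(a[, 1] - b[, 1], world)
    dy <- wrap_delta(a[, 2] - b[, 2], world)
  } else {
    dx <- wrap_delta(a[1] - b[1], world)
    dy <- wrap_delta(a[2] - b[2], world)
  }
  sqrt(dx * dx + dy * dy)
}

# signed coordinate difference wrapped into (-world/2, world/2]
wrap_delta <- function(d, world) {
  d - world * round(d / world)
}

# wrap absolute positions into [0, world)
wrap_pos <- function(x, world) x - world * floor(x / world)

#' Dyadic FEAR attitude
#'
#' The fixed, directed agonism attitude of individual `i` toward `j`:
#' the dominance-strength difference `dom_j - dom_i`, in
#' `[-0.95, 0.95]` for dominance strengths in `[0.05, 1]`.
#'
#' @param dom_i,dom_j dominance strengths in `[0.05, 1]` (vectorized).
#' @return signed numeric level.
#' @examples
#' fear_attitude(0.05, 1.00)  # 0.95
#' @export
fear_attitude <- function(dom_i, dom_j) {
  stopifnot(all(dom_i >= 0.05 - 1e-12), all(dom_i <= 1 + 1e-12),
            all(dom_j >= 0.05 - 1e-12), all(dom_j <= 1 + 1e-12))
  dom_j - dom_i
}

#' Full FEAR matrix of a dominance vector
#'
#' `fear[i, j] = dom[j] - dom[i]`; exactly antisymmetric.
#'
#' @param dom numeric vector of dominance strengths.
#' @return square matrix with zero diagonal.
#' @export
fear_matrix <- function(dom) {
  outer(dom, dom, function(a, b) b - a)
}

#' Initialize a population
#'
#' Creates the initial state of all agents: dominance strengths from
#' `params$dom_values` (by default evenly spaced on `[0.05, 1]`), positions
#' drawn uniformly from a disc of diameter `init_disc_diameter` (50 m)
#' centered in the world, headings uniform on `[1, 360]` degrees, the
#' default 120-degree view angle, arousal at its default (0.09), anxiety,
#' satisfaction, every partner-specific satisfaction and every LIKE
#' attitude at 0, and first activation times drawn from Normal(1, 0.05)
#' minutes.
#'
#' Uses R's global RNG stream; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param params an [emo_params()] object.
#' @return an object of class `emo_population`: a list with vectors `dom`,
#'   `x`, `y`, `heading`, `view`, `arousal`, `anxiety`, `satisfaction`,
#'   `my_time`, matrices `partner_sat`, `like`, and the derived `fear`
#'   matrix.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "emo_params"))
  n <- params$n_agents
  if (n < 1) stop("population must have at least one agent")
  r <- params$init_disc_diameter / 2
  cx <- params$world_size / 2
  # uniform on a disc: sqrt-radius trick
  rad <- r * sqrt(stats::runif(n))
  ang <- stats::runif(n, 0, 2 * pi)
  pop <- list(
    n = n,
    dom = params$dom_values,
    x = wrap_pos(cx + rad * cos(ang), params$world_size),
    y = wrap_pos(cx + rad * sin(ang), params$world_size),
    heading = stats::runif(n, 1, 360),
    view = rep(params$view_angle, n),
    arousal = rep(params$default_arousal, n),
    anxiety = rep(0, n),
    satisfaction = rep(0, n),
    my_time = stats::rnorm(n, 1, 0.05),
    partner_sat = matrix(0, n, n),
    like = matrix(0, n, n),
    fear = fear_matrix(params$dom_values)
  )
  class(pop) <- "emo_population"
  pop
}

#' @export
print.emo_population <- function(x, ...) {
  cat(sprintf("<emo_population> %d agents, dominance %g..%g\n",
              x$n, min(x$dom), max(x$dom)))
  invisible(x)
}

# bearing (degrees, counter-clockwise from +x) from point 1 to point 2 on
# the torus, using the wrapped (shortest) displacement
torus_bearing <- function(x1, y1, x2, y2, world) {
  dx <- wrap_delta(x2 - x1, world)
  dy <- wrap_delta(y2 - y1, world)
  (atan2(dy, dx) * 180 / pi) %% 360
}

# absolute angular offset between two angles in degrees, in [0, 180]
angle_offset <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
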