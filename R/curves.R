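#' Parametric test curves with closed-form length and tortuosity
#'
#' Defines a family of analytic space curves (line, circular arc, helix,
#' sinusoid) used as ground truth for the measurement pipeline. Each curve
#' carries its analytic arc length and tortuosity index so that extraction,
#' resampling and smoothing can be validated against a known answer.
#'
#' Supported kinds and their parameters (all lengths mm, angles radians):
#' \describe{
#'   \item{line}{`length`}
#'   \item{circular_arc}{`radius`, `angle` (subtended arc angle)}
#'   \item{helix}{`radius`, `pitch` (axial rise per turn), `turns`}
#'   \item{sinusoid}{`amplitude`, `period`, `n_periods` (default 1); planar
#'     curve y = A sin(2 pi x / period). Its arc length has no elementary
#'     closed form and is evaluated by adaptive quadrature.}
#' }
#'
#' @param kind one of "line", "circular_arc", "helix", "sinusoid".
#' @param params named list of scalars for the chosen kind (see Details).
#' @param n_points number of sample points (>= 2).
#' @return object of class `parametric_curve` with fields `kind`, `params`,
#'   `n_points` and `closed_form` (list with `length` and `tortuosity`).
#' @export
parametric_curve <- function(kind, params = list(), n_points = 2000L) {
  kind <- match.arg(kind, c("line", "circular_arc", "helix", "sinusoid"))
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  p <- params
  need_pos <- function(nm) {
    if (is.null(p[[nm]]) || !is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("parameter '%s' must be a positive scalar for kind '%s'", nm, kind))
    p[[nm]]
  }
  cf <- switch(kind,
    line = {
      L <- need_pos("length")
      list(length = L, tortuosity = 0)
    },
    circular_arc = {
      R <- need_pos("radius"); th <- need_pos("angle")
      if (th >= 2 * pi) stop("arc angle must be < 2*pi (chord degenerate)")
      L <- R * th
      chord <- 2 * R * sin(th / 2)
      list(length = L, tortuosity = L / chord - 1)
    },
    helix = {
      a <- need_pos("radius"); pitch <- need_pos("pitch"); turns <- need_pos("turns")
      th_end <- 2 * pi * turns
      c_ax <- pitch / (2 * pi)           # axial rise per radian
      L <- th_end * sqrt(a^2 + c_ax^2)
      chord <- sqrt((a * (cos(th_end) - 1))^2 + (a * sin(th_end))^2 + (c_ax * th_end)^2)
      list(length = L, tortuosity = L / chord - 1)
    },
    sinusoid = {
      A <- need_pos("amplitude"); per <- need_pos("period")
      np <- if (is.null(p$n_periods)) 1 else need_pos("n_periods")
      k <- 2 * pi / per
      L <- stats::integrate(function(x) sqrt(1 + (A * k * cos(k * x))^2),
                            0, np * per, rel.tol = 1e-12,
                            subdivisions = 1000L)$value
      chord <- np * per                  # endpoints on the axis for whole periods
      if (np %% 1 != 0) {
        xe <- np * per
        chord <- sqrt(xe^2 + (A * sin(k * xe))^2)
      }
      list(length = L, tortuosity = L / chord - 1)
    })
  structure(list(kind = kind, params = p, n_points = n_points, closed_form = cf),
            class = "parametric_curve")
}

# Evaluate the curve at parameter values t in [0, 1].
eval_parametric <- function(spec, t) {
  p <- spec$params
  switch(spec$kind,
    line = cbind(p$length * t, 0, 0),
    circular_arc = {
      th <- p$angle * t
      cbind(p$radius * cos(th), p$radius * sin(th), 0)
    },
    helix = {
      th <- 2 * pi * p$turns * t
      cbind(p$radius * cos(th), p$radius * sin(th), p$pitch / (2 * pi) * th)
    },
    sinusoid = {
      np <- if (is.null(p$n_periods)) 1 else p$n_periods
      x <- np * p$period * t
      cbind(x, p$amplitude * sin(2 * pi * x / p$period), 0)
    })
}

#' Sample a parametric curve into a centerline
#'
#' Samples the curve at `n_points` equal parameter steps. The analytic
#' `closed_form` record travels with the result (as attribute
#' `"closed_form"`) so tests can compare measured against analytic values.
#'
#' @param spec a [parametric_curve()].
#' @return a [centerline()] with attribute `closed_form`.
#' @export
make_centerline <- function(spec) {
  stopifnot(inherits(spec, "parametric_curve"))
  t <- seq(0, 1, length.out = spec$n_points)
  line <- centerline(eval_parametric(spec, t), frame_id = "curve_local")
  attr(line, "closed_form") <- spec$closed_form
  line
}
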