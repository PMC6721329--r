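# Sagittal-plane spine curve reconstruction from five forward tilt angles.
#
# Convention: x = anterior offset, y = cranial. A tilt angle tau (degrees at
# the interface, radians internally) gives the curve's tangent direction
# (sin tau, cos tau) at the sensor, so tau = 0 is vertical and positive tau
# leans anteriorly -- consistent with a lordotic standing profile (lowest
# sensor circa +20 deg, topmost circa -12 deg).

deg2rad <- function(x) x * pi / 180

# sin(h)/h, series near zero so the chord formula is smooth across
# equal-angle segments (removable singularity at h = 0)
sinc_ <- function(h) {
  out <- numeric(length(h))
  small <- abs(h) < 1e-4
  out[small] <- 1 - h[small]^2 / 6 + h[small]^4 / 120
  out[!small] <- sin(h[!small]) / h[!small]
  out
}

# Chord of a constant-curvature arc of arc length L whose tangent angle runs
# linearly from tau0 to tau1 (radians). Closed form
#   ( (L/d)(cos tau0 - cos tau1), (L/d)(sin tau1 - sin tau0) ), d = tau1-tau0
# rewritten via half-angle identities as L * sinc(d/2) * (sin m, cos m) with
# m = (tau0+tau1)/2, which is exact and cancellation-free.
arc_chord <- function(tau0, tau1, L) {
  m <- (tau0 + tau1) / 2
  f <- L * sinc_((tau1 - tau0) / 2)
  c(f * sin(m), f * cos(m))
}

#' Reconstruct a 2D spine curve from five tilt angles
#'
#' Builds the sagittal spine curve as six ordered 2D points: a base point `P0`
#' and five sensor positions `P1` .. `P5`, with `P1` pinned to the origin.
#' Consecutive sensor positions are joined by constant-curvature circular arcs
#' of fixed arc length `L` whose tangent angle interpolates linearly between
#' the two sensors' tilt angles; the base point extends straight down from
#' `P1` along sensor 1's tangent.
#'
#' @param angles Numeric vector of the five forward tilt angles in degrees,
#'   sensor 1 (lowest) first.
#' @param L Arc length of each inter-sensor segment, in model units
#'   (default 1). All downstream geometry scales linearly with `L`.
#' @return An object of class `spine_curve`: a list with `points` (6 x 2
#'   matrix, rows `P0` .. `P5`, columns `x`, `y`), `angles` (the input,
#'   degrees) and `L`.
#' @examples
#' reconstruct_curve(c(0, 0, 0, 0, 0))$points   # a vertical line
#' @export
reconstruct_curve <- function(angles, L = 1) {
  if (length(angles) != 5L || !all(is.finite(angles)))
    stop("angles must be 5 finite values (degrees)")
  if (!is.finite(L) || L <= 0) stop("L must be a positive model length")
  tau <- deg2rad(as.numeric(angles))
  pts <- matrix(0, 6, 2, dimnames = list(paste0("P", 0:5), c("x", "y")))
  pts["P0", ] <- -L * c(sin(tau[1]), cos(tau[1]))
  for (i in 1:4)
    pts[i + 2, ] <- pts[i + 1, ] + arc_chord(tau[i], tau[i + 1], L)
  # P1 is the origin by construction; subtract it anyway so the pinning
  # survives any change to the accumulation above
  pts <- sweep(pts, 2, pts["P1", ])
  structure(list(points = pts, angles = as.numeric(angles), L = L),
            class = "spine_curve")
}

#' Offset spine shape of a posture pair
#'
#' Feeds the per-sensor angle differences (guided minus unguided,
#' `t1 - t0`) back through [reconstruct_curve()], yielding a curve that shows
#' the postural change as horizontal offsets from a vertical line: a pair
#' with no change maps to a vertical segment. Each point's x-coordinate is
#' annotated with its sign: `"+"` anterior offset, `"-"` posterior, `"o"`
#' within `zero_tol` of zero.
#'
#' @param t0_angles,t1_angles Five tilt angles (degrees) of the unguided and
#'   guided snapshot. Alternatively pass a single `posture_pairs` row via
#'   [offset_shapes()].
#' @param L Segment arc length (model units).
#' @param zero_tol Half-width of the zero band for the sign annotation
#'   (model units; default `1e-9`, so `"o"` marks exact zeros only).
#' @param pair_id Optional identifier carried through to profiling.
#' @return Object of class `offset_shape`: list with `points` (6 x 2 matrix,
#'   rows ordered `P0` .. `P5`, i.e. by increasing y for moderate angle
#'   differences), `signs` (character vector over `+`, `o`, `-`), `delta`
#'   (the angle differences, degrees) and `pair_id`.
#' @export
offset_shape <- function(t0_angles, t1_angles, L = 1, zero_tol = 1e-9,
                         pair_id = NA_character_) {
  delta <- as.numeric(t1_angles) - as.numeric(t0_angles)
  curve <- reconstruct_curve(delta, L)
  x <- curve$points[, "x"]
  signs <- ifelse(x > zero_tol, "+", ifelse(x < -zero_tol, "-", "o"))
  structure(list(points = curve$points, signs = unname(signs), delta = delta,
                 pair_id = pair_id),
            class = "offset_shape")
}

#' Offset spine shapes for every pair in a table
#'
#' @param pairs A `posture_pairs` data.frame (see [extract_pairs()]).
#' @param L,zero_tol As in [offset_shape()].
#' @return Named list of `offset_shape` objects, one per row, named by
#'   `pair_id`.
#' @export
offset_shapes <- function(pairs, L = 1, zero_tol = 1e-9) {
  t0 <- as.matrix(pairs[paste0("t0_", ANGLE_COLS)])
  t1 <- as.matrix(pairs[paste0("t1_", ANGLE_COLS)])
  out <- lapply(seq_len(nrow(pairs)), function(i)
    offset_shape(t0[i, ], t1[i, ], L = L, zero_tol = zero_tol,
                 pair_id = pairs$pair_id[i]))
  stats::setNames(out, pairs$pair_id)
}

#' @export
print.spine_curve <- function(x, ...) {
  cat("spine_curve: L =", x$L, "model units, angles (deg):",
      paste(format(x$angles), collapse = ", "), "\n")
  print(round(x$points, 4))
  invisible(x)
}

#' @export
as.data.frame.spine_curve <- function(x, ...) {
  data.frame(point = rownames(x$points), x = x$points[, "x"],
             y = x$points[, "y"], row.names = NULL)
}

#' @export
as.data.frame.offset_shape <- function(x, ...) {
  data.frame(pair_id = x$pair_id, point = rownames(x$points),
             x = x$points[, "x"], y = x$points[, "y"], sign = x$signs,
             row.names = NULL)
}
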