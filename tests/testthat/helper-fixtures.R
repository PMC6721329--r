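# Shared fixtures: tiny snapshot tables built in code, and the independent
# numeric-integration oracle for arc geometry.

snapshot_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "user_id,position,guidance,timestamp,angle_1,angle_2,angle_3,angle_4,angle_5"
  writeLines(c(header, rows), path)
  path
}

make_snapshots <- function(user_id, position, guidance, timestamp, angles) {
  d <- data.frame(user_id = user_id, position = position, guidance = guidance,
                  timestamp = as.POSIXct(timestamp, tz = "UTC"),
                  stringsAsFactors = FALSE)
  if (!is.matrix(angles)) angles <- matrix(angles, nrow(d), 5)
  d[paste0("angle_", 1:5)] <- as.data.frame(angles)
  as_snapshots(d)
}

# Independent oracle for the arc chord: numerically integrate the tangent
# field (sin theta(s), cos theta(s)) with theta linear in arc length, by
# composite Simpson quadrature (exact to ~1e-12 at 2000 panels).
integrate_chord <- function(tau0, tau1, L, n_panels = 2000L) {
  s <- seq(0, L, length.out = 2L * n_panels + 1L)
  theta <- tau0 + (tau1 - tau0) * s / L
  wts <- c(1, rep(c(4, 2), n_panels - 1L), 4, 1) * (s[2] - s[1]) / 3
  c(sum(wts * sin(theta)), sum(wts * cos(theta)))
}

# well-separated planted change archetypes: large, differently oriented
# displacements at every curve level; within-archetype SD 1 degree,
# between-template separation >= 27x that
separated_archetypes <- function() {
  list(archetype("anterior_shift",  c( 10,  8,  8,  8,  8), sd = 1),
       archetype("posterior_shift", c(-10, -8, -8, -8, -8), sd = 1),
       archetype("tilt_reversal",   c( 10,  6, -2, -10, -12), sd = 1))
}
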