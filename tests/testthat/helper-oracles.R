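# Independent oracles and fixture builders used across the suite.

# Brute-force circular mean: argmax over mu of sum(cos(theta_i - mu)),
# evaluated by direct summation on a coarse 0.5-degree grid and refined on a
# 0.001-degree grid around the coarse winner (the objective is a single
# sinusoid in mu, so the refinement cannot miss the global maximum).
grid_circ_mean <- function(angles_deg) {
  obj <- function(mu) {
    vapply(mu, function(m) sum(cos((angles_deg - m) * pi / 180)), 0)
  }
  coarse <- seq(-180, 179.5, by = 0.5)
  m0 <- coarse[which.max(obj(coarse))]
  fine <- seq(m0 - 1, m0 + 1, by = 0.001)
  fine[which.max(obj(fine))]
}

# Subjects x items matrix with exchangeable inter-item correlation r:
# x_ij = sqrt(r) z_i + sqrt(1 - r) e_ij (unit-variance items).
exchangeable_matrix <- function(n, k, r) {
  z <- rnorm(n)
  sqrt(r) * matrix(z, n, k) + sqrt(1 - r) * matrix(rnorm(n * k), n, k)
}

# Minimal hand-built session: one participant-day with the given trials.
make_test_session <- function(trials, roster = default_roster(),
                              day = 1, participant_id = "p1", ...) {
  pointing_session(
    participant_id = participant_id, day = day, trials = trials,
    roster = roster, layout = room_layout(), ...
  )
}

# Trial data.frame from angle vectors (one row per angle).
trials_from_angles <- function(azimuth_deg, elevation_deg, target,
                               condition = "EO", day = 1,
                               facing_heading_deg = 0) {
  v <- angles_to_vector(azimuth_deg, elevation_deg, facing_heading_deg)
  n <- length(azimuth_deg)
  data.frame(
    index = seq_len(n), day = day, condition = condition,
    target = target, repetition = stats::ave(seq_len(n), target,
                                             FUN = seq_along),
    e = v[, "e"], n = v[, "n"], u = v[, "u"], flags = "",
    stringsAsFactors = FALSE
  )
}
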