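# Independent oracles used across the suite.

# stationary distribution of a CTMC generator by eigen-decomposition
# (independent of the package's linear-solve route)
eigen_stationary <- function(q) {
  ev <- eigen(t(q))
  v <- Re(ev$vectors[, which.min(abs(ev$values))])
  v / sum(v)
}

# brute-force bond coverage from a known retained-ion set
oracle_coverage <- function(ladder, n_bonds) {
  kept_bonds <- unique(ladder$bond[ladder$kept])
  length(kept_bonds) / n_bonds
}

# piecewise-linear track built from (phase, duration_s, slope_um_per_min)
# rows, sampled at dt
make_piecewise_track <- function(segments, dt = 2, l0 = 5,
                                 track_id = "pw", condition = "test") {
  t_end <- cumsum(segments$duration)
  t <- seq(0, sum(segments$duration), by = dt)
  l <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    li <- l0
    remaining <- ti
    for (j in seq_len(nrow(segments))) {
      step <- min(remaining, segments$duration[j])
      li <- li + segments$slope[j] / 60 * step
      remaining <- remaining - step
      if (remaining <= 0) break
    }
    l[i] <- li
  }
  data.frame(track_id = track_id, time_s = t, length_um = l,
             condition = condition, stringsAsFactors = FALSE)
}

# random valid peptide sequence
random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}
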