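# Small builders used across the suite; every fixture is generated in code.

make_poi <- function(label = "p", n = 5L, d = 2L, t = seq_len(n) - 1L,
                     coords = NULL) {
  if (is.null(coords))
    coords <- matrix(seq_len(n * d), n, d)
  poi_trajectory(label, t, coords)
}

make_leg <- function(n = 10L) {
  t <- seq_len(n) - 1L
  element("leg", list(
    poi_trajectory("heel", t, cbind(x = t, y = rep(0, n))),
    poi_trajectory("toe", t, cbind(x = t + 1, y = rep(0, n)))))
}

sine_trace <- function(f = 5, fs = 1000, duration = 2, amp = 1, phase = 0,
                       label = "s") {
  t <- (seq_len(duration * fs) - 1L) / fs
  signal_trace(label, t, amp * sin(2 * pi * f * t + phase))
}

# independent exhaustive DTW oracle: plain memoised recursion over the full
# alignment lattice, no band
oracle_dtw <- function(a, b) {
  memo <- matrix(NA_real_, length(a), length(b))
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == 1L && j == 1L) abs(a[1L] - b[1L]) else
      abs(a[i] - b[j]) + min(
        if (i > 1L) rec(i - 1L, j) else Inf,
        if (j > 1L) rec(i, j - 1L) else Inf,
        if (i > 1L && j > 1L) rec(i - 1L, j - 1L) else Inf)
    memo[i, j] <<- v
    v
  }
  rec(length(a), length(b))
}

# all pairwise inter-POI distances for one frame index
frame_distances <- function(e, i) {
  m <- do.call(rbind, lapply(e$pois, function(p) p$coords[i, ]))
  as.numeric(stats::dist(m))
}
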