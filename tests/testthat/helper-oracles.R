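# Shared fixtures and independent oracles, built in code at test time.

# quick recording constructor: positions + times, everything valid unless
# stated otherwise
make_recording <- function(t_ms, x, y, pupil_l = 3, pupil_r = 3,
                           valid = TRUE, screen = c(1920, 1080),
                           rate_hz = NULL) {
  n <- length(t_ms)
  gaze_recording(data.frame(
    t_ms = t_ms, x = rep_len(x, n), y = rep_len(y, n),
    pupil_l = rep_len(pupil_l, n), pupil_r = rep_len(pupil_r, n),
    valid_l = rep_len(valid, n), valid_r = rep_len(valid, n)),
    rate_hz = rate_hz, screen = screen)
}

# a randomized gaze stream mixing dwells, jumps, invalid samples and time
# gaps; exercises every branch of the I-VT classifier
random_stream <- function(n, dt = 4, p_jump = 0.05, p_invalid = 0.03,
                          p_timegap = 0.02, screen = c(1920, 1080)) {
  t <- cumsum(c(0, ifelse(stats::runif(n - 1) < p_timegap,
                          stats::runif(n - 1, 100, 400), dt)))
  x <- numeric(n); y <- numeric(n)
  x[1] <- stats::runif(1, 0, screen[1]); y[1] <- stats::runif(1, 0, screen[2])
  for (i in 2:n) {
    if (stats::runif(1) < p_jump) {
      x[i] <- stats::runif(1, 0, screen[1]); y[i] <- stats::runif(1, 0, screen[2])
    } else {
      x[i] <- min(max(x[i - 1] + stats::rnorm(1, 0, 0.3), 0), screen[1])
      y[i] <- min(max(y[i - 1] + stats::rnorm(1, 0, 0.3), 0), screen[2])
    }
  }
  valid <- stats::runif(n) >= p_invalid
  valid[c(1, n)] <- TRUE
  gaze_recording(data.frame(t_ms = t, x = x, y = y, pupil_l = 3, pupil_r = 3,
                            valid_l = valid, valid_r = valid),
                 screen = screen)
}

# brute-force I-VT oracle: explicit sample-by-sample scan over the valid
# subsequence, grouping consecutive below-threshold steps
oracle_ivt <- function(recording, threshold = 0.42, min_fix_ms = 60,
                       max_gap_ms = 75) {
  s <- recording$samples
  ok <- (s$valid_l | s$valid_r) & is.finite(s$x) & is.finite(s$y)
  idx <- which(ok)
  runs <- list()
  cur <- idx[1]
  for (k in seq(2, length(idx))) {
    i_prev <- cur[length(cur)]
    i <- idx[k]
    dtk <- s$t_ms[i] - s$t_ms[i_prev]
    v <- sqrt((s$x[i] - s$x[i_prev])^2 + (s$y[i] - s$y[i_prev])^2) / dtk
    if (dtk <= max_gap_ms && v < threshold) {
      cur <- c(cur, i)
    } else {
      runs[[length(runs) + 1]] <- cur
      cur <- i
    }
  }
  runs[[length(runs) + 1]] <- cur
  rows <- lapply(runs, function(r) {
    if (length(r) < 2) return(NULL)
    span <- s$t_ms[r[length(r)]] - s$t_ms[r[1]]
    if (span < min_fix_ms) return(NULL)
    data.frame(onset_ms = s$t_ms[r[1]], offset_ms = s$t_ms[r[length(r)]],
               duration_ms = span, cx = mean(s$x[r]), cy = mean(s$y[r]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), cx = numeric(0), cy = numeric(0)))
  }
  do.call(rbind, rows)
}

# exhaustive permutation p-value for the Kruskal-Wallis statistic at tiny N,
# using stats::kruskal.test as the independent statistic
kw_perm_p <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  g_obs <- rep(seq_along(sizes), sizes)
  H_obs <- unname(stats::kruskal.test(x, factor(g_obs))$statistic)
  N <- length(x)
  # enumerate assignments of indices to groups 1..k
  assignments <- list()
  build <- function(pool, gi, acc) {
    if (gi == length(sizes)) {
      assignments[[length(assignments) + 1]] <<- c(acc, list(pool))
      return(invisible(NULL))
    }
    for (cc in utils::combn(pool, sizes[gi], simplify = FALSE)) {
      build(setdiff(pool, cc), gi + 1, c(acc, list(cc)))
    }
  }
  build(seq_len(N), 1, list())
  H_all <- vapply(assignments, function(a) {
    g <- integer(N)
    for (gi in seq_along(a)) g[a[[gi]]] <- gi
    unname(stats::kruskal.test(x, factor(g))$statistic)
  }, numeric(1))
  mean(H_all >= H_obs - 1e-9)
}

# default study scenario shared across simulation-based tests
test_scenario <- function(seed = 1) default_scenario(seed = seed)
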