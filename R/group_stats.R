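check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least 2 numeric samples")
  }
  if (any(lengths(groups) == 0L)) stop("each group must be nonempty")
  if (!all(vapply(groups, is.numeric, logical(1L)))) {
    stop("all groups must be numeric")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("Group", seq_along(groups))
  }
  groups
}

# sum over tied values of (t^3 - t), the tie term shared by the
# Kruskal-Wallis correction and the Dunn standard error
tie_term <- function(x) {
  tt <- table(x)
  sum(tt^3 - tt)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis omnibus test that k independent samples come
#' from one distribution.  With pooled midranks and group mean ranks
#' \eqn{\bar r_i},
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar r_i - \tfrac{N+1}{2})^2
#'        \Big/ \Big(1 - \frac{\sum_v (t_v^3 - t_v)}{N^3 - N}\Big),}
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors, one per group (e.g. one per AOI,
#'   holding per-participant percent fixation metrics).
#' @return Object of class `kw_result`: list with `H`, `df`, `N`, `p` and
#'   the tie term \eqn{\sum (t^3 - t)}.
#' @examples
#' kruskal_wallis(list(g1 = c(1, 2), g2 = c(3, 4), g3 = c(5, 6)))  # H = 32/7
#' @export
kruskal_wallis <- function(groups) {
  groups <- check_groups(groups)
  n_i <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  g <- rep(seq_along(groups), n_i)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  H0 <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  tt <- tie_term(x)
  C <- 1 - tt / (N^3 - N)
  H <- if (C > 0) H0 / C else 0      # all observations identical
  p <- if (C > 0) stats::pchisq(H, df = length(groups) - 1L, lower.tail = FALSE) else 1
  structure(list(H = H, df = length(groups) - 1L, N = N, p = p, tie_term = tt),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d, %d) = %.3f, p = %.4g\n", x$df, x$N, x$H, x$p))
  invisible(x)
}

#' Dunn post-hoc standard error
#'
#' Standard error of the difference in pooled mean ranks between two groups
#' in Dunn's pairwise post-hoc test,
#' \deqn{se = \sqrt{\Big(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N - 1)}\Big) \Big(\frac{1}{n_i} + \frac{1}{n_j}\Big)}.}
#' For a balanced tie-free three-group design with 22 observations per group
#' (N = 66) this evaluates to 5.788 (3 dp) for every pair.
#'
#' @param N total pooled observations.
#' @param n_i,n_j group sizes.
#' @param tie_term \eqn{\sum (t^3 - t)} over tied values; 0 when tie-free.
#' @return The standard error, in mean-rank units.
#' @examples
#' dunn_se(66, 22, 22)  # 5.788
#' @export
dunn_se <- function(N, n_i, n_j, tie_term = 0) {
  if (n_i <= 0 || n_j <= 0) stop("group sizes must be positive")
  if (N < n_i + n_j) stop("`N` must be at least n_i + n_j")
  sqrt((N * (N + 1) / 12 - tie_term / (12 * (N - 1))) * (1 / n_i + 1 / n_j))
}

#' Dunn pairwise post-hoc comparisons
#'
#' Rank-based pairwise comparisons following a Kruskal-Wallis omnibus test:
#' for each unordered pair of groups, the difference in pooled mean ranks,
#' its standard error ([dunn_se()] with the pooled tie term), the
#' standardized statistic z = diff/se, the two-sided normal p, and the
#' Bonferroni-adjusted p with multiplier m = number of pairs.  Rows are
#' ordered by ascending group mean rank (the conventional report layout, in
#' which every printed mean-rank difference is negative).
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return Data frame of class `dunn_table`: `group_a`, `group_b`, `pair`,
#'   `rank_diff`, `se`, `z`, `p`, `p_adj`.
#' @examples
#' dunn_pairwise(list(g1 = c(1, 2), g2 = c(3, 4), g3 = c(5, 6)))
#' @export
dunn_pairwise <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- check_groups(groups)
  n_i <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  g <- rep(seq_along(groups), n_i)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  tt <- tie_term(x)

  ord <- order(rbar)                       # ascending mean rank
  pairs <- utils::combn(seq_along(ord), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- ord[pairs[1L, k]]
    b <- ord[pairs[2L, k]]
    se <- dunn_se(N, n_i[a], n_i[b], tie_term = tt)
    diff <- rbar[[a]] - rbar[[b]]
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = names(groups)[a], group_b = names(groups)[b],
               pair = paste(names(groups)[a], "-", names(groups)[b]),
               rank_diff = diff, se = se, z = z, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "bonferroni") pmin(1, m * out$p) else out$p
  rownames(out) <- NULL
  class(out) <- c("dunn_table", "data.frame")
  out
}

#' Compare an expert against the novice cohort
#'
#' For each AOI (and each percent metric), summarises the novice cohort by
#' mean and sample standard deviation and locates the expert inside that
#' distribution by the z-position (expert - novice mean)/sd.
#'
#' @param novice_rows AOI metrics rows ([percent_metrics()]) for the novice
#'   cohort, one set of region rows per participant, row-bound.
#' @param expert_rows AOI metrics rows for the expert over the same AOI
#'   scheme and window.
#' @param metrics which percent columns to compare.
#' @return Data frame: `aoi`, `metric`, `novice_mean`, `novice_sd`,
#'   `expert`, `z`.  With fewer than 2 novices the sd (and z) are `NA` with
#'   a warning.
#' @export
compare_expert_novices <- function(novice_rows, expert_rows,
                                   metrics = c("pct_duration", "pct_count")) {
  nv <- as.data.frame(novice_rows)
  ex <- as.data.frame(expert_rows)
  if (!setequal(unique(nv$aoi), unique(ex$aoi))) {
    stop("novice and expert rows must cover the same AOI scheme")
  }
  wn <- unique(nv[c("window_start_ms", "window_end_ms")])
  we <- unique(ex[c("window_start_ms", "window_end_ms")])
  if (nrow(wn) != 1L || nrow(we) != 1L || !all(wn == we)) {
    stop("novice and expert rows must share one analysis window")
  }
  n_novices <- max(table(nv$aoi))
  if (n_novices < 2L) {
    warning("fewer than 2 novices: standard deviation (and z) undefined")
  }
  out <- do.call(rbind, lapply(metrics, function(mcol) {
    do.call(rbind, lapply(unique(ex$aoi), function(a) {
      v <- nv[[mcol]][nv$aoi == a]
      e <- ex[[mcol]][ex$aoi == a]
      mu <- mean(v)
      sdev <- if (length(v) >= 2L) stats::sd(v) else NA_real_
      data.frame(aoi = a, metric = mcol, novice_mean = mu, novice_sd = sdev,
                 expert = e, z = (e - mu) / sdev)
    }))
  }))
  rownames(out) <- NULL
  out
}
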