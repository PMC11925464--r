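# Independent oracles used across the test files. Each deliberately takes
# the dumbest correct route (scalar queues, full enumeration, quadrature)
# so it shares no code path with the implementation it checks.

# Scalar-queue flood fill: pixels connected to seed with
# |I - I(seed)| <= tol.
flood_fill_oracle <- function(frame, seed, tol, connectivity = 8L) {
  h <- nrow(frame); w <- ncol(frame)
  sv <- frame[seed[1L], seed[2L]]
  nb <- if (connectivity == 4L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  seen <- matrix(FALSE, h, w)
  seen[seed[1L], seed[2L]] <- TRUE
  queue <- list(seed)
  out <- NULL
  while (length(queue)) {
    p <- queue[[1L]]; queue <- queue[-1L]
    out <- rbind(out, p)
    for (d in nb) {
      q <- p + d
      if (q[1L] >= 1L && q[1L] <= h && q[2L] >= 1L && q[2L] <= w &&
          !seen[q[1L], q[2L]] && abs(frame[q[1L], q[2L]] - sv) <= tol) {
        seen[q[1L], q[2L]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# Exhaustive minimum-cost assignment of rows to columns of `cost`
# (n x m, n <= m, Inf = forbidden). Returns the column index per row
# (NA = unassigned allowed only via Inf edges being avoided: unmatched
# rows are modelled by the caller). Small sizes only.
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

min_cost_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 8L)
  best <- NULL; best_cost <- Inf
  for (perm in all_permutations(seq_len(m))) {
    sel <- perm[seq_len(n)]
    s <- sum(cost[cbind(seq_len(n), sel)])
    if (s < best_cost) { best_cost <- s; best <- sel }
  }
  list(assignment = best, cost = best_cost)
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Two-sided pooled-variance t-test p by numerical quadrature of the t
# density.
t_quad_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::integrate(function(u) stats::dt(u, df), lower = abs(tstat),
                       upper = Inf, rel.tol = 1e-12)$value
}

# Jaccard overlap of two closed intervals c(start, end).
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2L], b[2L]) - max(a[1L], b[1L]))
  uni <- max(a[2L], b[2L]) - min(a[1L], b[1L])
  if (uni <= 0) return(0)
  inter / uni
}

# Shoelace area via fan triangulation from the first vertex.
fan_triangulation_area <- function(v) {
  s <- 0
  for (k in 2:(nrow(v) - 1L)) {
    a <- v[1L, ]; b <- v[k, ]; c_ <- v[k + 1L, ]
    s <- s + abs((b[1L] - a[1L]) * (c_[2L] - a[2L]) -
                   (c_[1L] - a[1L]) * (b[2L] - a[2L])) / 2
  }
  s
}
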