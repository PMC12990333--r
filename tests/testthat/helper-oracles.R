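# Independent oracles used across the test files.

# exhaustive optimal open-path ordering for <= 8 points
brute_force_open_path <- function(points) {
  n <- nrow(points)
  stopifnot(n <= 8L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  path_len <- function(ord) {
    p <- points[ord, , drop = FALSE]
    sum(sqrt(rowSums(diff(p)^2)))
  }
  best <- NULL; best_len <- Inf
  for (ord in perms(seq_len(n))) {
    l <- path_len(ord)
    if (l < best_len) { best_len <- l; best <- ord }
  }
  list(order = best, length = best_len)
}

# points on a circular arc (radius r, centred at ctr), angles in radians
circle_points <- function(theta, r = 300, ctr = c(0, 0)) {
  cbind(x = ctr[1] + r * cos(theta), y = ctr[2] + r * sin(theta))
}

# exact two-sided Mann-Whitney p-value by complete enumeration of group
# assignments (small n, no ties)
mw_exact_p <- function(x0, x1) {
  all_v <- c(x0, x1)
  n0 <- length(x0)
  idx <- utils::combn(length(all_v), n0)
  u_obs <- sum(outer(x0, x1, ">")) + 0.5 * sum(outer(x0, x1, "=="))
  us <- apply(idx, 2L, function(i) {
    a <- all_v[i]; b <- all_v[-i]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  mu <- n0 * length(x1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# per-eye measurement of a rendered cohort through the full pipeline
measure_cohort <- function(annotations) {
  aggregate_eyes(measure_annotations(annotations))
}
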