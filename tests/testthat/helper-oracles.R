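# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and, where the package delegates to a library, that library):
# quantiles are interpolated by hand, AUC is counted over all
# positive-negative pairs, the SVR optimum is found by direct minimization
# of the primal objective.

# Type-7 quantile: linear interpolation between order statistics. The
# shared rule includes the convex-combination form (1-f)*lo + f*hi; outlier
# fences sit on knife edges for grid-valued data, so the interpolation form
# matters to the last ulp.
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  f <- h - lo
  (1 - f) * xs[lo] + f * xs[hi]
}

oracle_outlier_fraction <- function(x, factor = 1.5) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  iqr <- q3 - q1
  sum(x < q1 - factor * iqr | x > q3 + factor * iqr) / length(x)
}

oracle_quartile_skewness <- function(x) {
  q1 <- oracle_quantile7(x, 0.25)
  q2 <- oracle_quantile7(x, 0.50)
  q3 <- oracle_quantile7(x, 0.75)
  if (q3 == q1) return(0.5)
  (q2 - q1) / (q3 - q1)
}

oracle_histogram <- function(x, bins = 4, range = c(0, 0.5)) {
  edges <- seq(range[1], range[2], length.out = bins + 1)
  counts <- integer(bins)
  for (v in x) {
    for (k in seq_len(bins)) {
      if (v >= edges[k] && v < edges[k + 1]) counts[k] <- counts[k] + 1L
    }
  }
  counts / length(x)
}

oracle_vde <- function(press, release) {
  n <- length(press)
  if (n < 2) return(0)
  total <- 0
  for (i in seq_len(n - 1)) {
    ov <- release[i] - press[i + 1]
    total <- total + max(ov, 0)
  }
  total / (n - 1)
}

# AUC by exhaustive pair counting, ties count one half.
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Fast rank-based AUC (Mann-Whitney), used inside bootstrap loops where the
# O(n^2) oracle would dominate runtime; agrees with oracle_auc exactly.
rank_auc <- function(scores, is_pos) {
  r <- rank(scores)
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Primal objective of linear eps-SVR.
svr_primal <- function(w, b, x, y, C, eps) {
  resid <- abs(y - (as.matrix(x) %*% w + b)) - eps
  0.5 * sum(w^2) + C * sum(pmax(resid, 0))
}

# Direct minimization of the primal over (w, b): coarse grid then
# Nelder-Mead polish with restarts (the objective is convex).
oracle_svr <- function(x, y, C, eps, span = 3) {
  x <- as.matrix(x)
  d <- ncol(x)
  obj <- function(par) svr_primal(par[1:d], par[d + 1], x, y, C, eps)
  starts <- list(rep(0, d + 1))
  if (d == 1) {
    grid <- expand.grid(w = seq(-span, span, by = 0.1),
                        b = seq(min(y) - 1, max(y) + 1, by = 0.05))
    vals <- mapply(function(w, b) obj(c(w, b)), grid$w, grid$b)
    starts <- c(starts, list(as.numeric(grid[which.min(vals), ])))
  }
  best <- NULL
  for (s in starts) {
    cur <- s
    for (rep in 1:6) {
      fit <- stats::optim(cur, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
      cur <- fit$par
    }
    if (is.null(best) || obj(cur) < obj(best)) best <- cur
  }
  list(w = best[1:d], b = best[d + 1], value = obj(best))
}

# Small event-table constructor for hand-built fixtures.
make_events <- function(subject_id, key, press, release) {
  tibble::tibble(
    subject_id = subject_id,
    key = key,
    key_class = classify_key(key),
    press_time = press,
    release_time = release
  )
}

# A small synthetic cohort for unit tests (short to keep the suite fast).
tiny_cohort <- function(seed = 1, n_pd = 4, n_control = 4, ...) {
  simulate_cohort(sim_config(n_pd = n_pd, n_control = n_control,
                             seed = seed, ...))
}
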