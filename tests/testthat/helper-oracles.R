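# Independent oracles used to validate the package's implementations.
# These deliberately use naive, brute-force mechanics.

# interpolated PR-AUC by literal definition: for each recall level k/P scan
# every threshold from scratch
oracle_iauc <- function(scores, labels) {
  truth <- as.character(labels) == "relevant"
  P <- sum(truth)
  stopifnot(P >= 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pr <- t(vapply(thresholds, function(t) {
    sel <- scores >= t
    c(precision = sum(truth & sel) / sum(sel), recall = sum(truth & sel) / P)
  }, c(precision = 0, recall = 0)))
  mean(vapply(seq_len(P) / P, function(r) {
    max(pr[pr[, "recall"] >= r - 1e-12, "precision"])
  }, numeric(1)))
}

# exact sign-flip permutation p-value by depth-first enumeration
oracle_permutation_p <- function(a, b, tails = "one") {
  d <- a - b
  obs <- mean(d)
  count <- 0L
  total <- 0L
  recurse <- function(i, acc) {
    if (i > length(d)) {
      m <- acc / length(d)
      total <<- total + 1L
      hit <- if (tails == "one") m >= obs - 1e-12 else abs(m) >= abs(obs) - 1e-12
      if (hit) count <<- count + 1L
      return(invisible())
    }
    recurse(i + 1L, acc + d[i])
    recurse(i + 1L, acc - d[i])
  }
  recurse(1L, 0)
  count / total
}

# Bernoulli Naive Bayes log posterior-odds by direct likelihood evaluation
oracle_nb_log_odds <- function(x_train, y_train, x_test, alpha) {
  pos <- y_train == "relevant"
  th <- function(rows) (colSums(x_train[rows, , drop = FALSE]) + alpha) /
    (sum(rows) + 2 * alpha)
  th_pos <- th(pos)
  th_neg <- th(!pos)
  loglik <- function(x, th) sum(log(ifelse(x == 1, th, 1 - th)))
  apply(x_test, 1, function(row) {
    loglik(row, th_pos) + log(sum(pos)) - loglik(row, th_neg) - log(sum(!pos))
  })
}

# Gaussian-naive posterior log-odds with shared per-feature pooled variances
oracle_gaussian_nb_log_odds <- function(x_train, y_train, x_test, gamma) {
  pos <- y_train == "relevant"
  mu_p <- colMeans(x_train[pos, , drop = FALSE])
  mu_n <- colMeans(x_train[!pos, , drop = FALSE])
  ss <- colSums(sweep(x_train[pos, , drop = FALSE], 2, mu_p)^2) +
    colSums(sweep(x_train[!pos, , drop = FALSE], 2, mu_n)^2)
  v <- ss / (nrow(x_train) - 2)
  v <- (1 - gamma) * v + gamma * mean(v)
  apply(x_test, 1, function(row) {
    sum(stats::dnorm(row, mu_p, sqrt(v), log = TRUE)) -
      sum(stats::dnorm(row, mu_n, sqrt(v), log = TRUE)) +
      log(sum(pos) / sum(!pos))
  })
}

# penalized logistic regression by generic optimization of the C-form
# objective 0.5 ||w||^2 + C sum log(1 + exp(-y s))
oracle_logistic_fit <- function(x, y01, C) {
  obj <- function(par) {
    w <- par[-1]
    s <- drop(x %*% w) + par[1]
    ys <- ifelse(y01 == 1, s, -s)
    0.5 * sum(w^2) + C * sum(log1p(exp(-ys)))
  }
  fit <- stats::optim(rep(0, ncol(x) + 1), obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(bias = fit$par[1], weights = fit$par[-1])
}

# greedy longest-first dictionary matcher written as a transparent loop over
# every entry at every position
oracle_count_matches <- function(tokens, entry_list) {
  count <- 0L
  i <- 1L
  while (i <= length(tokens)) {
    best <- 0L
    for (e in entry_list) {
      L <- length(e)
      if (L > best && i + L - 1L <= length(tokens) &&
          all(tokens[i:(i + L - 1L)] == e)) {
        best <- L
      }
    }
    if (best > 0L) {
      count <- count + 1L
      i <- i + best
    } else i <- i + 1L
  }
  count
}
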