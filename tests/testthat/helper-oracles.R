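# Shared fixtures and independent oracles for the test suite. Everything here
# is deliberately written in plain arithmetic, independent of the package's
# vectorised implementations.

# small long-format panel data.frame
toy_long <- function() {
  data.frame(
    id = rep(c("a", "b", "c"), each = 3),
    wave = rep(0:2, 3),
    depression = c(0, 1, NA, 1, 1, 0, 0, NA, 1),
    anxiety = c(0, 0, 0, NA, 1, 1, 0, 0, NA),
    sex = rep(c("f", "m", "f"), each = 3),
    stringsAsFactors = FALSE
  )
}

# random panel generator for property-style tests (independent of the
# package's synthetic module)
random_panel_df <- function(n = 8, T = 4, p_miss = 0.35, two_channels = TRUE) {
  ids <- sprintf("s%02d", seq_len(n))
  df <- expand.grid(wave = 0:(T - 1), id = ids,
                    stringsAsFactors = FALSE)[, c("id", "wave")]
  draw <- function() {
    y <- rbinom(nrow(df), 1, 0.3)
    y[runif(nrow(df)) < p_miss] <- NA
    y
  }
  df$depression <- draw()
  if (two_channels) df$anxiety <- draw()
  # guarantee every subject at least one observed wave per channel
  for (ch in intersect(c("depression", "anxiety"), names(df))) {
    for (i in ids) {
      rows <- which(df$id == i)
      if (all(is.na(df[[ch]][rows]))) df[[ch]][rows[1]] <- 0
    }
  }
  df$grp <- rep(sample(c("x", "y"), n, replace = TRUE), each = T)
  df
}

# brute-force mixture log-likelihood: plain loops over subjects and groups
brute_loglik <- function(Y, beta, pi) {
  total <- 0
  for (i in seq_len(nrow(Y))) {
    mix <- 0
    for (j in seq_along(pi)) {
      lik <- 1
      for (t in seq_len(ncol(Y))) {
        y <- Y[i, t]
        if (is.na(y)) next
        eta <- sum(beta[j, ] * (t - 1)^(seq_len(ncol(beta)) - 1))
        p <- 1 / (1 + exp(-eta))
        lik <- lik * if (y == 1) p else 1 - p
      }
      mix <- mix + pi[j] * lik
    }
    total <- total + log(mix)
  }
  total
}

# hand Bayes-rule posterior, plain loops
brute_posterior <- function(Y, beta, pi) {
  P <- matrix(0, nrow(Y), length(pi))
  for (i in seq_len(nrow(Y))) {
    w <- numeric(length(pi))
    for (j in seq_along(pi)) {
      lik <- 1
      for (t in seq_len(ncol(Y))) {
        y <- Y[i, t]
        if (is.na(y)) next
        eta <- sum(beta[j, ] * (t - 1)^(seq_len(ncol(beta)) - 1))
        p <- 1 / (1 + exp(-eta))
        lik <- lik * if (y == 1) p else 1 - p
      }
      w[j] <- pi[j] * lik
    }
    P[i, ] <- w / sum(w)
  }
  P
}

# brute-force dual log-likelihood: double sum over group pairs
brute_dual_loglik <- function(Y1, Y2, beta1, beta2, Pi) {
  subj_lik <- function(y, beta_j) {
    lik <- 1
    for (t in seq_along(y)) {
      if (is.na(y[t])) next
      eta <- sum(beta_j * (t - 1)^(seq_along(beta_j) - 1))
      p <- 1 / (1 + exp(-eta))
      lik <- lik * if (y[t] == 1) p else 1 - p
    }
    lik
  }
  total <- 0
  for (i in seq_len(nrow(Y1))) {
    mix <- 0
    for (j in seq_len(nrow(Pi))) {
      for (k in seq_len(ncol(Pi))) {
        mix <- mix + Pi[j, k] * subj_lik(Y1[i, ], beta1[j, ]) *
          subj_lik(Y2[i, ], beta2[k, ])
      }
    }
    total <- total + log(mix)
  }
  total
}

# direct maximization of a 2-group, order-0 mixture likelihood over
# (p1, p2, w): coarse grid then Nelder-Mead refinement from the best grid
# points, on an unconstrained (logit) scale
brute_max_loglik_2g0 <- function(Y) {
  obj <- function(par) {
    w <- plogis(par[3])
    -brute_loglik(Y, rbind(par[1], par[2]), c(w, 1 - w))
  }
  probs <- c(1e-6, 1e-4, 0.002, 0.01, seq(0.04, 0.96, by = 0.08),
             0.99, 0.998, 0.9999, 0.999999)
  grid <- expand.grid(q1 = qlogis(probs), q2 = qlogis(probs),
                      qw = qlogis(seq(0.05, 0.95, by = 0.1)))
  vals <- apply(grid, 1, obj)
  best <- -Inf
  best_par <- NULL
  for (r in order(vals)[1:40]) {
    opt <- optim(as.numeric(grid[r, ]), obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-13))
    if (-opt$value > best) {
      best <- -opt$value
      best_par <- opt$par
    }
  }
  opt2 <- optim(best_par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-13))
  max(best, -opt2$value)
}

# brute-force maximum for a 1-group order-0 model: closed form p = mean(y)
brute_max_loglik_1g0 <- function(Y) {
  y <- Y[!is.na(Y)]
  p <- mean(y)
  if (p == 0 || p == 1) 0 else sum(y) * log(p) + sum(1 - y) * log(1 - p)
}
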