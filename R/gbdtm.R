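#' Dual trajectory parameters
#'
#' Parameters of a dual (two-channel) trajectory model: each channel has its
#' own set of group trajectory coefficients, and the two channels are linked
#' by a J x K joint group-membership matrix `joint_pi` whose entries sum
#' to 1. Channel outcomes are conditionally independent given the group pair.
#'
#' @param beta1 J x (order+1) logit coefficients for channel 1.
#' @param beta2 K x (order+1) logit coefficients for channel 2.
#' @param joint_pi J x K joint membership probability matrix.
#' @return object of class `dual_params`.
#' @export
dual_params <- function(beta1, beta2, joint_pi) {
  beta1 <- as.matrix(beta1); beta2 <- as.matrix(beta2)
  joint_pi <- as.matrix(joint_pi)
  if (nrow(joint_pi) != nrow(beta1) || ncol(joint_pi) != nrow(beta2)) {
    stop("joint_pi must be J x K matching the coefficient matrices")
  }
  if (any(joint_pi < 0) || abs(sum(joint_pi) - 1) > 1e-8) {
    stop("joint_pi entries must be >= 0 and sum to 1")
  }
  structure(list(J = nrow(beta1), K = nrow(beta2),
                 order = ncol(beta1) - 1L,
                 beta1 = beta1, beta2 = beta2, joint_pi = joint_pi),
            class = "dual_params")
}

# Flattened joint structure helpers: column (k-1)*J + j of an N x (J*K)
# matrix corresponds to group pair (j, k).
joint_index <- function(J, K) {
  list(j = rep(seq_len(J), times = K), k = rep(seq_len(K), each = J))
}

dual_logjoint <- function(params, panel, channels) {
  logf1 <- cond_loglik_matrix(outcome_matrix(panel, channels[1]),
                              params$beta1)
  logf2 <- cond_loglik_matrix(outcome_matrix(panel, channels[2]),
                              params$beta2)
  J <- params$J; K <- params$K
  ix <- joint_index(J, K)
  logf1[, ix$j, drop = FALSE] + logf2[, ix$k, drop = FALSE] +
    rep(log(pmax(as.vector(params$joint_pi), 1e-300)),
        each = nrow(logf1))
}

#' Dual-model log-likelihood
#'
#' Observed-data log-likelihood of the dual trajectory model:
#' `sum_i log sum_jk Pi_jk L1_i(j) L2_i(k)`, where `Lc_i` is subject i's
#' conditional likelihood on channel c over its observed waves. When
#' `joint_pi` is the outer product of its margins this equals the sum of the
#' two single-channel mixture log-likelihoods.
#'
#' @param params a [dual_params] object.
#' @param panel a [panel_data] object with both channels.
#' @param channels length-2 character vector naming channel 1 and channel 2;
#'   defaults to the panel's first two channels.
#' @return scalar log-likelihood.
#' @export
dual_loglik <- function(params, panel, channels = panel$channels[1:2]) {
  if (length(channels) != 2L || !all(channels %in% panel$channels)) {
    stop("panel must contain both modeled channels")
  }
  sum(row_logsumexp(dual_logjoint(params, panel, channels)))
}

#' Joint posterior over group pairs
#'
#' @inheritParams dual_loglik
#' @return N x J x K array; each subject's slice sums to 1.
#' @export
dual_posterior <- function(params, panel, channels = panel$channels[1:2]) {
  a <- dual_logjoint(params, panel, channels)
  W <- exp(a - row_logsumexp(a))
  array(W, dim = c(nrow(W), params$J, params$K),
        dimnames = list(panel$subjects, NULL, NULL))
}

# One dual-EM run from initial (beta1, beta2, joint_pi).
dual_em_engine <- function(Y1, Y2, beta1, beta2, Pi, order, tol, max_iter,
                           freeze_curves = FALSE) {
  N <- nrow(Y1)
  J <- nrow(beta1); K <- nrow(beta2)
  ix <- joint_index(J, K)
  B <- poly_basis(ncol(Y1), order)
  obs1 <- !is.na(Y1); obs2 <- !is.na(Y2)
  Y10 <- ifelse(obs1, Y1, 0); Y20 <- ifelse(obs2, Y2, 0)
  O1 <- matrix(as.numeric(obs1), N, ncol(Y1))
  O2 <- matrix(as.numeric(obs2), N, ncol(Y2))

  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    logf1 <- cond_loglik_matrix(Y1, beta1)
    logf2 <- cond_loglik_matrix(Y2, beta2)
    a <- logf1[, ix$j, drop = FALSE] + logf2[, ix$k, drop = FALSE] +
      rep(log(pmax(as.vector(Pi), 1e-300)), each = N)
    lse <- row_logsumexp(a)
    ll <- sum(lse)
    W <- exp(a - lse)                 # N x (J*K)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll) + 1e-3)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_prev <- ll

    Pi <- matrix(colMeans(W), J, K)
    W1 <- vapply(seq_len(J),
                 function(j) rowSums(W[, ix$j == j, drop = FALSE]),
                 numeric(N))
    W2 <- vapply(seq_len(K),
                 function(k) rowSums(W[, ix$k == k, drop = FALSE]),
                 numeric(N))
    if (!freeze_curves) {
      S1 <- crossprod(Y10, W1); T1 <- crossprod(O1, W1)
      for (j in seq_len(J)) {
        beta1[j, ] <- wlogit_fit(B, S1[, j], T1[, j], start = beta1[j, ])
      }
      S2 <- crossprod(Y20, W2); T2 <- crossprod(O2, W2)
      for (k in seq_len(K)) {
        beta2[k, ] <- wlogit_fit(B, S2[, k], T2[, k], start = beta2[k, ])
      }
    }
  }
  list(beta1 = beta1, beta2 = beta2, joint_pi = Pi, loglik = ll, W = W,
       trace = trace, converged = converged, n_iter = it)
}

#' Fit a dual trajectory model by EM
#'
#' Joint model for two binary outcome channels linked by a joint
#' group-membership matrix. By default the model is initialized from separate
#' single-channel fits — coefficients taken as-is, the joint matrix from the
#' cross-tabulated marginal assignments smoothed with `1/(J K)` pseudo-mass —
#' plus additional random starts; the best log-likelihood wins. Both
#' channels' curves are re-estimated inside the EM unless
#' `freeze_curves = TRUE` (the cheaper two-stage variant). Groups are
#' relabeled canonically per channel (ascending mean fitted probability).
#'
#' @param panel a [panel_data] object with both channels.
#' @param J,K number of groups for channel 1 and channel 2.
#' @param order polynomial order (default 1, linear).
#' @param channels length-2 channel names; defaults to the panel's first two.
#' @param init optional list of two `gbtm_fit` objects (marginal fits for the
#'   two channels, group counts matching `J` and `K`).
#' @param n_starts total number of starts; when `init` is omitted the first
#'   start is built from internally fitted marginal models and the rest are
#'   random.
#' @param tol,max_iter EM convergence control.
#' @param seed integer seed.
#' @param freeze_curves if `TRUE`, only `joint_pi` is updated by EM.
#' @return object of class `dual_fit`: `params` ([dual_params]), `loglik`,
#'   `n_params`, `N`, `joint_posterior` (N x J x K), per-channel `posterior1`
#'   / `posterior2`, `assignment1` / `assignment2`, `app1` / `app2`,
#'   conditional matrices `cond_2_given_1` and `cond_1_given_2`, information
#'   criteria, `converged`, `n_iter`, `loglik_trace`, `channels`.
#' @export
dual_fit <- function(panel, J, K, order = 1L,
                     channels = panel$channels[1:2], init = NULL,
                     n_starts = 3L, tol = 1e-6, max_iter = 500L,
                     seed = NULL, freeze_curves = FALSE) {
  if (length(channels) != 2L || !all(channels %in% panel$channels)) {
    stop("panel must contain both modeled channels")
  }
  Y1 <- outcome_matrix(panel, channels[1])
  Y2 <- outcome_matrix(panel, channels[2])
  N <- nrow(Y1)
  seeds <- derive_seeds(seed, n_starts + 2L)

  if (!is.null(init)) {
    if (init[[1]]$params$J != J || init[[2]]$params$J != K) {
      stop("init group counts must match J and K")
    }
    m1 <- init[[1]]; m2 <- init[[2]]
  } else {
    m1 <- gbtm_fit(panel, channels[1], J, order = order, seed = seeds[n_starts + 1L])
    m2 <- gbtm_fit(panel, channels[2], K, order = order, seed = seeds[n_starts + 2L])
  }

  # marginal-fit start: smoothed cross-tab of marginal assignments
  tab <- matrix(0, J, K)
  for (i in seq_len(N)) {
    tab[m1$assignment[i], m2$assignment[i]] <- tab[m1$assignment[i], m2$assignment[i]] + 1
  }
  Pi0 <- tab / N + 1 / (J * K)
  Pi0 <- Pi0 / sum(Pi0)

  best <- NULL
  for (s in seq_len(n_starts)) {
    if (s == 1L) {
      run <- dual_em_engine(Y1, Y2, m1$params$beta, m2$params$beta, Pi0,
                            order, tol, max_iter, freeze_curves)
    } else {
      set.seed(seeds[s])
      sa1 <- sample.int(J, N, replace = TRUE); sa1[sample.int(N, J)] <- seq_len(J)
      sa2 <- sample.int(K, N, replace = TRUE); sa2[sample.int(N, K)] <- seq_len(K)
      B <- poly_basis(ncol(Y1), order)
      b1 <- matrix(0, J, order + 1L); b2 <- matrix(0, K, order + 1L)
      P1 <- matrix(0, N, J); P1[cbind(seq_len(N), sa1)] <- 1
      P2 <- matrix(0, N, K); P2[cbind(seq_len(N), sa2)] <- 1
      o1 <- matrix(as.numeric(!is.na(Y1)), N); o2 <- matrix(as.numeric(!is.na(Y2)), N)
      y1 <- ifelse(is.na(Y1), 0, Y1); y2 <- ifelse(is.na(Y2), 0, Y2)
      S1 <- crossprod(y1, P1); T1 <- crossprod(o1, P1)
      for (j in seq_len(J)) b1[j, ] <- wlogit_fit(B, S1[, j], T1[, j])
      S2 <- crossprod(y2, P2); T2 <- crossprod(o2, P2)
      for (k in seq_len(K)) b2[k, ] <- wlogit_fit(B, S2[, k], T2[, k])
      tabr <- matrix(0, J, K)
      for (i in seq_len(N)) tabr[sa1[i], sa2[i]] <- tabr[sa1[i], sa2[i]] + 1
      Pir <- (tabr / N + 1 / (J * K)); Pir <- Pir / sum(Pir)
      run <- dual_em_engine(Y1, Y2, b1, b2, Pir, order, tol, max_iter,
                            freeze_curves)
    }
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  ord1 <- canonical_order(best$beta1, ncol(Y1))
  ord2 <- canonical_order(best$beta2, ncol(Y2))
  beta1 <- best$beta1[ord1, , drop = FALSE]
  beta2 <- best$beta2[ord2, , drop = FALSE]
  Pi <- best$joint_pi[ord1, ord2, drop = FALSE]

  params <- dual_params(beta1, beta2, Pi / sum(Pi))
  Warr <- array(best$W, dim = c(N, J, K))[, ord1, ord2, drop = FALSE]
  dimnames(Warr) <- list(panel$subjects, NULL, NULL)
  P1 <- apply(Warr, c(1, 2), sum)
  P2 <- apply(Warr, c(1, 3), sum)
  assignment1 <- max.col(P1, ties.method = "first")
  assignment2 <- max.col(P2, ties.method = "first")
  app1 <- vapply(seq_len(J), function(j) {
    m <- assignment1 == j; if (!any(m)) NA_real_ else mean(P1[m, j])
  }, numeric(1))
  app2 <- vapply(seq_len(K), function(k) {
    m <- assignment2 == k; if (!any(m)) NA_real_ else mean(P2[m, k])
  }, numeric(1))

  k_params <- J * (order + 1L) + K * (order + 1L) + (J * K - 1L)
  ic <- information_criteria(best$loglik, k_params, N)

  fit <- structure(c(list(
    params = params,
    loglik = best$loglik,
    n_params = k_params,
    N = N,
    joint_posterior = Warr,
    posterior1 = P1, posterior2 = P2,
    assignment1 = assignment1, assignment2 = assignment2,
    app1 = app1, app2 = app2
  ), ic, list(
    converged = best$converged,
    n_iter = best$n_iter,
    loglik_trace = best$trace,
    channels = channels
  )), class = "dual_fit")
  fit$cond_2_given_1 <- conditional_probs(fit, "2|1")
  fit$cond_1_given_2 <- conditional_probs(fit, "1|2")
  fit
}

#' Conditional group-membership probabilities
#'
#' Row-stochastic conditionals derived from the joint membership matrix:
#' direction `"2|1"` gives P(channel-2 group k | channel-1 group j) as row j,
#' `"1|2"` the reverse. A zero marginal row is reported as `NA`.
#'
#' @param fit a `dual_fit`, [dual_params], or J x K joint probability matrix.
#' @param direction `"2|1"` or `"1|2"`.
#' @return row-stochastic matrix (J x K for `"2|1"`, K x J for `"1|2"`).
#' @export
conditional_probs <- function(fit, direction = c("2|1", "1|2")) {
  direction <- match.arg(direction)
  Pi <- if (is.matrix(fit)) fit else fit$params$joint_pi
  if (direction == "2|1") {
    marg <- rowSums(Pi)
    out <- sweep(Pi, 1, marg, `/`)
    out[marg == 0, ] <- NA_real_
  } else {
    marg <- colSums(Pi)
    out <- sweep(t(Pi), 1, marg, `/`)
    out[marg == 0, ] <- NA_real_
  }
  out
}

#' Marginal group probabilities of a dual model
#'
#' @param fit a `dual_fit`, [dual_params], or J x K joint probability matrix.
#' @return list with `channel1` (row sums, length J) and `channel2`
#'   (column sums, length K); each sums to 1.
#' @export
marginal_probs <- function(fit) {
  Pi <- if (is.matrix(fit)) fit else fit$params$joint_pi
  list(channel1 = rowSums(Pi), channel2 = colSums(Pi))
}

#' @export
print.dual_fit <- function(x, ...) {
  cat(sprintf(
    "dual_fit: %d x %d groups, order %d, channels '%s' & '%s'\n  loglik %.3f  bic %.3f  (N = %d, k = %d)\n",
    x$params$J, x$params$K, x$params$order, x$channels[1], x$channels[2],
    x$loglik, x$bic_traj, x$N, x$n_params))
  m <- marginal_probs(x)
  cat("  margins 1:", paste(sprintf("%.3f", m$channel1), collapse = " "), "\n")
  cat("  margins 2:", paste(sprintf("%.3f", m$channel2), collapse = " "), "\n")
  invisible(x)
}
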