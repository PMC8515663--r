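#' Trajectory mixture parameters
#'
#' Parameters of a J-group latent class growth model for a binary outcome:
#' each group follows its own polynomial trajectory on the logit scale, and
#' subjects belong to group j with probability `pi[j]`.
#'
#' @param beta J x (order+1) matrix of logit-scale polynomial coefficients
#'   (columns: intercept, slope in wave index, ...).
#' @param pi length-J vector of group membership probabilities (positive,
#'   summing to 1).
#' @return object of class `traj_params`.
#' @export
traj_params <- function(beta, pi) {
  beta <- as.matrix(beta)
  if (!all(is.finite(beta))) stop("beta must be finite")
  if (length(pi) != nrow(beta)) stop("length(pi) must equal nrow(beta)")
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be positive and sum to 1")
  }
  structure(list(J = nrow(beta), order = ncol(beta) - 1L,
                 beta = beta, pi = as.numeric(pi)),
            class = "traj_params")
}

#' Trajectory probability at a wave
#'
#' Evaluates one group's outcome probability `logistic(b0 + b1 t + ...)` at
#' wave index `t`.
#'
#' @param beta_j coefficient vector (intercept first).
#' @param t wave index (scalar or vector, `t >= 0`).
#' @return probability in (0, 1).
#' @export
group_prob <- function(beta_j, t) {
  eta <- outer(t, seq_along(beta_j) - 1L, `^`) %*% beta_j
  as.numeric(stats::plogis(eta))
}

# Per-subject conditional log-likelihood matrix: entry (i, j) is
# log P(subject i's observed outcomes | group j). Y is N x T with NA.
cond_loglik_matrix <- function(Y, beta) {
  n_waves <- ncol(Y)
  B <- poly_basis(n_waves, ncol(beta) - 1L)
  eta <- B %*% t(beta)                       # T x J
  lp <- stats::plogis(eta, log.p = TRUE)     # log p
  lq <- stats::plogis(-eta, log.p = TRUE)    # log(1-p)
  obs <- !is.na(Y)
  Y0 <- ifelse(obs, Y, 0)
  Om <- matrix(as.numeric(obs), nrow(Y), n_waves)
  Y0 %*% lp + (Om - Y0) %*% lq
}

#' Mixture log-likelihood of a panel channel
#'
#' Observed-data log-likelihood of a trajectory mixture: for each subject the
#' product over that subject's non-missing waves of Bernoulli terms, mixed
#' over groups, computed stably in log space. Missing waves are omitted from
#' the product (valid under missing-at-random).
#'
#' @param params a [traj_params] object.
#' @param panel a [panel_data] object.
#' @param channel outcome channel name.
#' @return scalar log-likelihood.
#' @export
gbtm_loglik <- function(params, panel, channel) {
  Y <- outcome_matrix(panel, channel)
  if (nrow(Y) > 0 && any(rowSums(!is.na(Y)) == 0)) {
    stop("subject with zero observed waves; drop before computing likelihood")
  }
  logf <- cond_loglik_matrix(Y, params$beta)
  sum(row_logsumexp(sweep(logf, 2, log(params$pi), `+`)))
}

#' Posterior group-membership probabilities
#'
#' Bayes-rule posterior probability that each subject belongs to each group,
#' given the subject's observed outcome pattern. A subject with no observed
#' waves gets the prior `pi` as its posterior row.
#'
#' @inheritParams gbtm_loglik
#' @return N x J matrix with rows summing to 1.
#' @export
gbtm_posterior <- function(params, panel, channel) {
  Y <- outcome_matrix(panel, channel)
  logf <- cond_loglik_matrix(Y, params$beta)
  a <- sweep(logf, 2, log(params$pi), `+`)
  P <- exp(a - row_logsumexp(a))
  rownames(P) <- panel$subjects
  P
}

#' Information criteria in both sign conventions
#'
#' The trajectory literature reports `BIC = loglik - 0.5 k log N` and
#' `AIC = loglik - k` (larger is better, negative in practice); the standard
#' statistical convention is `-2 loglik + penalty` (smaller is better). Both
#' are returned.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters k.
#' @param N number of subjects.
#' @return list with `bic_traj`, `aic_traj`, `bic_standard`, `aic_standard`.
#' @export
information_criteria <- function(loglik, n_params, N) {
  stopifnot(N >= 1, n_params >= 1)
  list(
    bic_traj = loglik - 0.5 * n_params * log(N),
    aic_traj = loglik - n_params,
    bic_standard = -2 * loglik + n_params * log(N),
    aic_standard = -2 * loglik + 2 * n_params
  )
}

# One EM run from a hard initial assignment (or from explicit parameter
# values, used to resume a short run). Returns params, loglik, trace.
gbtm_em_engine <- function(Y, J, order, tol, max_iter, start_assign = NULL,
                           start_params = NULL) {
  N <- nrow(Y)
  n_waves <- ncol(Y)
  B <- poly_basis(n_waves, order)
  obs <- !is.na(Y)
  Y0 <- ifelse(obs, Y, 0)
  Om <- matrix(as.numeric(obs), N, n_waves)

  if (!is.null(start_params)) {
    beta <- start_params$beta
    pi <- start_params$pi
  } else {
    P <- matrix(0, N, J)
    P[cbind(seq_len(N), start_assign)] <- 1
    pi <- colMeans(P)
    beta <- matrix(0, J, order + 1L)
    Sm <- crossprod(Y0, P)   # T x J weighted successes
    Wm <- crossprod(Om, P)   # T x J weighted trials
    for (j in seq_len(J)) {
      beta[j, ] <- wlogit_fit(B, Sm[, j], Wm[, j], start = NULL)
    }
  }

  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    logf <- cond_loglik_matrix(Y, beta)
    a <- sweep(logf, 2, log(pmax(pi, 1e-300)), `+`)
    lse <- row_logsumexp(a)
    ll <- sum(lse)
    P <- exp(a - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll) + 1e-3)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_prev <- ll
    pi <- colMeans(P)
    {
      Sm <- crossprod(Y0, P)
      Wm <- crossprod(Om, P)
      for (j in seq_len(J)) {
        beta[j, ] <- wlogit_fit(B, Sm[, j], Wm[, j], start = beta[j, ])
      }
    }
  }
  list(beta = beta, pi = pi, loglik = ll, posterior = P, trace = trace,
       converged = converged, n_iter = it)
}

# Per-subject summary features for initialization: observed event rates over
# early / middle / late thirds of the panel plus the overall rate. Missing
# thirds fall back to the subject's overall rate.
subject_features <- function(Y) {
  n_waves <- ncol(Y)
  cuts <- unique(round(seq(0, n_waves, length.out = 4)))
  overall <- rowMeans(Y, na.rm = TRUE)
  parts <- lapply(seq_len(length(cuts) - 1L), function(b) {
    cols <- (cuts[b] + 1L):cuts[b + 1L]
    r <- rowMeans(Y[, cols, drop = FALSE], na.rm = TRUE)
    ifelse(is.nan(r), overall, r)
  })
  cbind(do.call(cbind, parts), overall)
}

# Hard start assignment from k-means on event-timing features; falls back to
# a random partition when there are fewer distinct feature rows than groups.
kmeans_start <- function(Y, J) {
  f <- subject_features(Y)
  n_distinct <- nrow(unique(f))
  if (n_distinct < J) return(NULL)
  km <- tryCatch(
    stats::kmeans(f, centers = J, nstart = 10, iter.max = 50),
    error = function(e) NULL
  )
  if (is.null(km)) NULL else km$cluster
}

# Canonical group order: ascending mean fitted probability over the wave
# grid, ties broken by intercept. Defeats label switching.
canonical_order <- function(beta, n_waves) {
  B <- poly_basis(n_waves, ncol(beta) - 1L)
  meanp <- colMeans(stats::plogis(B %*% t(beta)))
  order(meanp, beta[, 1])
}

#' Fit a group-based trajectory model by EM
#'
#' Finite mixture of logistic polynomial trajectories for one binary outcome
#' channel, estimated by EM: the E-step computes posterior group-membership
#' probabilities, the M-step updates `pi` as posterior means and each group's
#' coefficients by posterior-weighted logistic regression (IRLS) of the
#' observed outcomes on the polynomial time basis. The observed-data
#' log-likelihood is non-decreasing across iterations. Several random
#' initializations are run and the best retained; fitted groups are relabeled
#' in ascending order of mean fitted probability.
#'
#' @param panel a [panel_data] object.
#' @param channel outcome channel name.
#' @param J number of trajectory groups (>= 1).
#' @param order polynomial order of the logit trajectories (0-3; default 1,
#'   i.e. linear).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of random initializations.
#' @param seed integer seed controlling the initializations.
#' @param prev_fit optional `gbtm_fit` with J-1 groups (e.g. from a grid
#'   search); its groups are split to seed additional starts, which helps EM
#'   find small groups. Without it a quick internal J-1 partition is used.
#' @return object of class `gbtm_fit`: `params` ([traj_params]), `loglik`,
#'   `n_params`, `N`, `posterior`, `assignment`, `app` (per-group average
#'   posterior probability of assigned members), the four information
#'   criteria, `converged`, `n_iter`, `n_starts`, `loglik_trace` (best
#'   start's per-iteration log-likelihood) and `channel`.
#' @export
gbtm_fit <- function(panel, channel, J, order = 1L, tol = 1e-6,
                     max_iter = 500L, n_starts = 10L, seed = NULL,
                     prev_fit = NULL) {
  Y <- outcome_matrix(panel, channel)
  N <- nrow(Y)
  if (J < 1L) stop("J must be >= 1")
  if (J > N) stop("J (", J, ") exceeds the number of subjects (", N, ")")
  if (any(rowSums(!is.na(Y)) == 0)) {
    stop("subject with zero observed waves; drop before fitting")
  }

  # emEM search: many short EM runs from diverse starts, then run the most
  # promising few to convergence. Start 1 is k-means on event-timing features
  # (finds small groups with distinctive patterns); the rest are random
  # partitions.
  n_short <- 2L * n_starts
  short_iter <- min(40L, max_iter)
  n_deep <- min(3L, n_short)
  seeds <- derive_seeds(seed, n_short + 1L)
  shorts <- vector("list", n_short)
  for (s in seq_len(n_short)) {
    set.seed(seeds[s])
    sa <- if (s == 1L) kmeans_start(Y, J) else NULL
    if (is.null(sa)) {
      sa <- sample.int(J, N, replace = TRUE)
      sa[sample.int(N, J)] <- seq_len(J)  # every group seeded
    }
    shorts[[s]] <- gbtm_em_engine(Y, J, order, tol, short_iter, sa)
  }
  # ordered starts: cut subjects ranked by observed event rate into J blocks
  # at several split fractions; seeds boundary components (e.g. a small
  # all-zero group) that random partitions essentially never isolate
  rate_order <- order(rowMeans(Y, na.rm = TRUE))
  for (frac in c(0.03, 0.1, 0.25, 0.5, 0.75, 0.9, 0.97)) {
    # first J-1 blocks share the lowest-rate subjects up to frac*N; the last
    # block takes the remainder
    bounds <- unique(round(c(0, seq_len(J - 1) * frac * N / (J - 1), N)))
    if (length(bounds) != J + 1L) next
    sa <- integer(N)
    for (b in seq_len(J)) {
      sa[rate_order[(bounds[b] + 1):bounds[b + 1]]] <- b
    }
    shorts[[length(shorts) + 1L]] <-
      gbtm_em_engine(Y, J, order, tol, short_iter, sa)
  }

  # split starts: take a J-1 partition and split each of its groups in two;
  # effective at seeding small groups that random partitions never isolate
  if (J > 1L) {
    set.seed(seeds[n_short + 1L])
    base <- if (!is.null(prev_fit) && prev_fit$params$J == J - 1L) {
      prev_fit$assignment
    } else if (J == 2L) {
      rep(1L, N)
    } else {
      sa0 <- kmeans_start(Y, J - 1L)
      if (is.null(sa0)) sa0 <- sample.int(J - 1L, N, replace = TRUE)
      max.col(gbtm_em_engine(Y, J - 1L, order, tol, 60L, sa0)$posterior,
              ties.method = "first")
    }
    feats <- subject_features(Y)
    for (g in seq_len(J - 1L)) {
      memb <- which(base == g)
      fm <- feats[memb, , drop = FALSE]
      if (length(memb) < 2L * J || nrow(unique(fm)) < 2L) next
      km <- tryCatch(stats::kmeans(fm, 2, nstart = 5),
                     error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < 2L) next
      sa <- base
      sa[memb[km$cluster == 2L]] <- J
      shorts[[length(shorts) + 1L]] <-
        gbtm_em_engine(Y, J, order, tol, short_iter, sa)
    }
  }
  top <- order(vapply(shorts, `[[`, numeric(1), "loglik"),
               decreasing = TRUE)[seq_len(n_deep)]
  best <- NULL
  for (s in top) {
    run <- if (shorts[[s]]$converged) shorts[[s]] else
      gbtm_em_engine(Y, J, order, tol, max_iter,
                     start_params = list(beta = shorts[[s]]$beta,
                                         pi = shorts[[s]]$pi))
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  ord <- canonical_order(best$beta, ncol(Y))
  beta <- best$beta[ord, , drop = FALSE]
  pi <- best$pi[ord]
  P <- best$posterior[, ord, drop = FALSE]
  rownames(P) <- panel$subjects

  if (any(pi < 1e-8)) {
    warning("empty trajectory group (pi < 1e-8) in ", J, "-group fit")
  }

  assignment <- max.col(P, ties.method = "first")
  app <- vapply(seq_len(J), function(j) {
    m <- assignment == j
    if (!any(m)) NA_real_ else mean(P[m, j])
  }, numeric(1))

  k <- J * (order + 1L) + (J - 1L)
  ic <- information_criteria(best$loglik, k, N)

  structure(c(list(
    params = traj_params(beta, pi),
    loglik = best$loglik,
    n_params = k,
    N = N,
    posterior = P,
    assignment = assignment,
    app = app
  ), ic, list(
    converged = best$converged,
    n_iter = best$n_iter,
    n_starts = n_starts,
    loglik_trace = best$trace,
    channel = channel
  )), class = "gbtm_fit")
}

#' Average posterior probability of assignment
#'
#' Classification-adequacy diagnostic: for each group, the mean posterior
#' membership probability among the subjects assigned to it (conventional
#' adequacy threshold 0.7). Empty groups are reported as `NA`.
#'
#' @param fit a `gbtm_fit` object (or any list with `posterior` and
#'   `assignment`).
#' @return numeric vector of length J.
#' @export
avg_posterior_prob <- function(fit) {
  P <- fit$posterior
  assignment <- fit$assignment
  vapply(seq_len(ncol(P)), function(j) {
    m <- assignment == j
    if (!any(m)) NA_real_ else mean(P[m, j])
  }, numeric(1))
}

#' @export
print.gbtm_fit <- function(x, ...) {
  cat(sprintf(
    "gbtm_fit: %d groups, order %d, channel '%s'\n  loglik %.3f  bic %.3f  aic %.3f  (N = %d, k = %d)\n",
    x$params$J, x$params$order, x$channel, x$loglik, x$bic_traj, x$aic_traj,
    x$N, x$n_params))
  cat("  pi:", paste(sprintf("%.3f", x$params$pi), collapse = " "), "\n")
  cat("  APP:", paste(sprintf("%.3f", x$app), collapse = " "), "\n")
  if (!x$converged) cat("  (did not converge)\n")
  invisible(x)
}
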