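# Internal numerical helpers shared across modules.

# Row-wise log-sum-exp of a numeric matrix; stable for large negative entries.
row_logsumexp <- function(a) {
  m <- do.call(pmax, as.data.frame(a))
  # guard rows that are all -Inf (cannot occur for valid mixtures)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(a - m)))
}

# Polynomial time basis: rows are waves 0..T-1, columns 1, t, t^2, ...
poly_basis <- function(n_waves, order) {
  outer(seq_len(n_waves) - 1, 0:order, `^`)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going up (the convention used in
#' printed epidemiological tables), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Weighted logistic regression of aggregated successes/trials on a basis
# matrix, via IRLS (glm.fit). `succ` and `trials` are per-wave posterior-
# weighted counts; rows with zero weight are dropped. Returns a coefficient
# vector; falls back to `start` when the group carries no mass.
wlogit_fit <- function(basis, succ, trials, start = NULL) {
  keep <- trials > 1e-12
  if (sum(keep) == 0L) {
    return(if (is.null(start)) rep(0, ncol(basis)) else start)
  }
  y <- succ[keep] / trials[keep]
  fit <- suppressWarnings(stats::glm.fit(
    x = basis[keep, , drop = FALSE], y = y, weights = trials[keep],
    family = stats::quasibinomial(), start = start
  ))
  co <- fit$coefficients
  if (anyNA(co)) {
    if (!is.null(start)) return(start)
    co[is.na(co)] <- 0
  }
  co
}

# All permutations of 1..n (n small); used for canonical group matching.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Match fitted trajectory groups to reference groups
#'
#' Finds the permutation of fitted groups that minimises the summed squared
#' distance between fitted and reference probability curves over the wave
#' grid. Useful for comparing a fit against the generative truth of a
#' simulation, where group labels are arbitrary.
#'
#' @param beta_fit J x (order+1) fitted logit coefficients.
#' @param beta_ref J x (order+1) reference logit coefficients.
#' @param n_waves number of waves defining the comparison grid (0..T-1).
#' @return integer vector `perm` such that fitted group `perm[j]` corresponds
#'   to reference group `j`.
#' @export
match_groups <- function(beta_fit, beta_ref, n_waves) {
  stopifnot(nrow(beta_fit) == nrow(beta_ref))
  J <- nrow(beta_fit)
  B_fit <- poly_basis(n_waves, ncol(beta_fit) - 1L)
  B_ref <- poly_basis(n_waves, ncol(beta_ref) - 1L)
  p_fit <- stats::plogis(B_fit %*% t(beta_fit))
  p_ref <- stats::plogis(B_ref %*% t(beta_ref))
  perms <- permutations(J)
  cost <- apply(perms, 1, function(pm) sum((p_fit[, pm] - p_ref)^2))
  perms[which.min(cost), ]
}

#' Match fitted groups to reference groups by assignment overlap
#'
#' Finds the permutation of fitted group labels that maximises agreement with
#' reference (e.g. generative ground-truth) labels — the standard way to
#' resolve label switching when comparing a fit to simulation truth.
#'
#' @param ref_labels integer reference group per subject (1..J).
#' @param fit_labels integer fitted group per subject (1..J).
#' @param J number of groups.
#' @return integer vector `perm` such that fitted group `perm[j]` corresponds
#'   to reference group `j`.
#' @export
match_groups_by_labels <- function(ref_labels, fit_labels, J) {
  tab <- table(factor(ref_labels, seq_len(J)), factor(fit_labels, seq_len(J)))
  perms <- permutations(J)
  agree <- apply(perms, 1, function(pm) sum(diag(tab[, pm, drop = FALSE])))
  perms[which.max(agree), ]
}

# Deterministic child seeds below 2^31 derived from one user seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max, n))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
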