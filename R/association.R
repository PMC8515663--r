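#' Cross-tabulate a covariate against trajectory groups
#'
#' Counts and within-group (column) percentages, the layout of baseline
#' characteristic tables in trajectory studies. Subjects with a missing
#' covariate are excluded from the table and counted per group.
#'
#' @param labels per-subject group labels (factor or coercible).
#' @param covariate per-subject covariate category (missing allowed).
#' @param covariate_name optional name carried in the result.
#' @return object of class `crosstab`: `counts` (categories x groups),
#'   `col_pct` (column percentages, rounded half-up to 1 decimal), `col_n`
#'   (column totals), `n_excluded` (per group, for missing covariate),
#'   `covariate` name.
#' @export
crosstab <- function(labels, covariate, covariate_name = NULL) {
  if (length(labels) != length(covariate)) {
    stop("labels and covariate must have the same length")
  }
  if (length(labels) == 0L) stop("empty input")
  labels <- factor(labels)
  if (anyNA(labels)) stop("missing group labels are not allowed")
  covariate <- factor(covariate)
  excl <- is.na(covariate)
  n_excluded <- as.integer(table(labels[excl]))
  names(n_excluded) <- levels(labels)
  counts <- table(droplevels(covariate[!excl]),
                  factor(labels[!excl], levels = levels(labels)))
  counts <- unclass(counts)
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  col_n <- colSums(counts)
  col_pct <- sweep(counts, 2, pmax(col_n, 1), `/`) * 100
  col_pct <- round_half_up(col_pct, 1)
  structure(list(counts = counts, col_pct = col_pct, col_n = col_n,
                 n_excluded = n_excluded,
                 covariate = covariate_name %||% deparse(substitute(covariate))),
            class = "crosstab")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson chi-square test of a cross-tabulation
#'
#' Pearson chi-square (no continuity correction) with df = (r-1)(c-1); cells
#' with expected count below 5 are counted and flagged.
#'
#' @param x a [crosstab] or a counts matrix.
#' @return list with `statistic`, `df`, `p_value`, `expected`,
#'   `n_expected_lt_5`.
#' @export
chisq_test <- function(x) {
  counts <- if (inherits(x, "crosstab")) x$counts else as.matrix(x)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate margins: a row or column of the table is all zero")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected,
       n_expected_lt_5 = sum(ct$expected < 5))
}

# Newton-Raphson multinomial logistic regression on the full likelihood.
# y: factor with reference = first level; X: model matrix.
multinom_newton <- function(X, y, max_iter = 200L, tol = 1e-12) {
  N <- nrow(X); p <- ncol(X)
  G <- nlevels(y)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design: aliased column(s) ",
         paste(aliased, collapse = ", "))
  }
  gi <- as.integer(y)          # 1 = reference
  Yind <- matrix(0, N, G - 1L)
  sel <- gi > 1L
  Yind[cbind(which(sel), gi[sel] - 1L)] <- 1
  theta <- matrix(0, G - 1L, p)

  loglik_at <- function(theta) {
    Eta <- X %*% t(theta)
    m <- pmax(0, do.call(pmax, as.data.frame(Eta)))
    den <- m + log(exp(-m) + rowSums(exp(Eta - m)))
    sum(Eta * Yind) - sum(den)
  }

  ll <- loglik_at(theta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Eta <- X %*% t(theta)
    m <- pmax(0, do.call(pmax, as.data.frame(Eta)))
    den <- m + log(exp(-m) + rowSums(exp(Eta - m)))
    P <- exp(Eta - den)        # N x (G-1)
    grad <- as.vector(crossprod(X, Yind - P))  # stacked by group
    H <- matrix(0, (G - 1L) * p, (G - 1L) * p)
    for (g in seq_len(G - 1L)) {
      for (h in seq_len(G - 1L)) {
        w <- if (g == h) P[, g] * (1 - P[, g]) else -P[, g] * P[, h]
        blk <- crossprod(X, X * w)
        H[((g - 1) * p + 1):(g * p), ((h - 1) * p + 1):(h * p)] <- -blk
      }
    }
    step <- tryCatch(solve(H, -grad), error = function(e) NULL)
    if (is.null(step)) break
    # step along theta + s*delta with halving if the likelihood drops
    s <- 1
    repeat {
      theta_new <- theta + matrix(step * s, G - 1L, p, byrow = TRUE)
      ll_new <- loglik_at(theta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      s <- s / 2
      if (s < 1e-8) { theta_new <- theta; ll_new <- ll; break }
    }
    improved <- ll_new - ll
    theta <- theta_new
    ll <- ll_new
    if (abs(improved) < tol * (abs(ll) + 1) && max(abs(grad)) < 1e-6) {
      converged <- TRUE
      break
    }
  }
  # observed information at the optimum for Wald inference
  Eta <- X %*% t(theta)
  m <- pmax(0, do.call(pmax, as.data.frame(Eta)))
  den <- m + log(exp(-m) + rowSums(exp(Eta - m)))
  P <- exp(Eta - den)
  H <- matrix(0, (G - 1L) * p, (G - 1L) * p)
  for (g in seq_len(G - 1L)) {
    for (h in seq_len(G - 1L)) {
      w <- if (g == h) P[, g] * (1 - P[, g]) else -P[, g] * P[, h]
      H[((g - 1) * p + 1):(g * p), ((h - 1) * p + 1):(h * p)] <-
        -crossprod(X, X * w)
    }
  }
  vc <- tryCatch(solve(-H), error = function(e) {
    matrix(NA_real_, nrow(H), ncol(H))
  })
  se <- matrix(sqrt(pmax(diag(vc), 0)), G - 1L, p, byrow = TRUE)
  dimnames(theta) <- list(levels(y)[-1], colnames(X))
  dimnames(se) <- dimnames(theta)
  list(coef = theta, se = se, vcov = vc, loglik = ll, converged = converged,
       n_iter = it)
}

#' Multinomial logistic regression of trajectory membership
#'
#' Models assigned trajectory group against baseline covariates with a named
#' reference group, by Newton-Raphson on the full multinomial likelihood.
#' Reports odds ratios with Wald 95% confidence intervals and p-values for
#' every non-reference group and non-reference covariate level. Coefficients
#' whose magnitude exceeds 15 indicate (quasi-)complete separation and are
#' flagged instead of being reported as finite odds ratios.
#'
#' @param labels per-subject group labels.
#' @param covariates data.frame of categorical predictors (one column per
#'   covariate; first factor level = reference level).
#' @param reference_group group used as the reference outcome (default: first
#'   factor level of `labels`).
#' @param conf_level confidence level for the Wald intervals.
#' @return object of class `or_table`: data.frame with columns `group`,
#'   `term`, `or`, `ci_low`, `ci_high`, `p_value`, `flagged`; attributes
#'   `coef`, `se`, `loglik`, `converged`, `n_used`, `n_dropped`.
#' @export
multinomial_logit <- function(labels, covariates, reference_group = NULL,
                              conf_level = 0.95) {
  labels <- factor(labels)
  if (!is.null(reference_group)) {
    if (!reference_group %in% levels(labels)) {
      stop("reference group '", reference_group, "' not among labels")
    }
    labels <- stats::relevel(labels, ref = as.character(reference_group))
  }
  if (sum(labels == levels(labels)[1]) == 0L) {
    stop("reference group is empty")
  }
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    if (!is.factor(covariates[[nm]])) {
      covariates[[nm]] <- factor(covariates[[nm]])
    }
  }
  ok <- stats::complete.cases(covariates) & !is.na(labels)
  n_dropped <- sum(!ok)
  y <- droplevels(labels[ok])
  X <- stats::model.matrix(~ ., data = covariates[ok, , drop = FALSE])

  fit <- multinom_newton(X, y)
  if (!fit$converged) {
    warning("multinomial logit did not converge in Newton-Raphson")
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- setdiff(colnames(X), "(Intercept)")
  rows <- list()
  for (g in rownames(fit$coef)) {
    for (tm in terms) {
      co <- fit$coef[g, tm]; se <- fit$se[g, tm]
      flagged <- abs(co) > 15
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, term = tm,
        or = if (flagged) NA_real_ else exp(co),
        ci_low = if (flagged) NA_real_ else exp(co - z * se),
        ci_high = if (flagged) NA_real_ else exp(co + z * se),
        p_value = if (flagged) NA_real_ else
          2 * stats::pnorm(-abs(co / se)),
        flagged = flagged,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("or_table", "data.frame"),
            coef = fit$coef, se = fit$se, vcov = fit$vcov,
            loglik = fit$loglik, converged = fit$converged,
            n_used = sum(ok), n_dropped = n_dropped,
            reference_group = levels(y)[1])
}

#' Univariate odds-ratio screen
#'
#' Runs [multinomial_logit()] one covariate at a time (the layout of
#' univariate supplementary tables); failures for individual covariates are
#' isolated and reported in place of that covariate's table.
#'
#' @inheritParams multinomial_logit
#' @return named list of `or_table` objects (or `try-error`-like condition
#'   messages for failed covariates), in input column order.
#' @export
univariate_screen <- function(labels, covariates, reference_group = NULL,
                              conf_level = 0.95) {
  covariates <- as.data.frame(covariates)
  out <- lapply(names(covariates), function(nm) {
    tryCatch(
      multinomial_logit(labels, covariates[nm],
                        reference_group = reference_group,
                        conf_level = conf_level),
      error = function(e) structure(conditionMessage(e), class = "fit_error")
    )
  })
  names(out) <- names(covariates)
  out
}

#' Baseline characteristics by trajectory group
#'
#' Stacks [crosstab()]s of every requested covariate against the assigned
#' trajectory groups, with a Pearson chi-square p-value per covariate — the
#' layout of baseline tables in trajectory studies.
#'
#' @param panel a [panel_data] object (source of the covariates).
#' @param labels per-subject group labels aligned with `panel$subjects`.
#' @param covariates character vector of covariate names; default all panel
#'   covariates.
#' @return object of class `baseline_table`: `table` (one row per covariate
#'   category with per-group `n_` and `pct_` columns), `tests` (covariate,
#'   statistic, df, p_value, n_expected_lt_5), `col_n` (group sizes),
#'   `excluded` (per covariate x group missing-covariate counts).
#' @export
baseline_table <- function(panel, labels,
                           covariates = setdiff(names(panel$covariates), "id")) {
  labels <- factor(labels)
  stopifnot(length(labels) == length(panel$subjects))
  groups <- levels(labels)
  rows <- list(); tests <- list(); excl <- list()
  for (cv in covariates) {
    ct <- crosstab(labels, panel$covariates[[cv]], covariate_name = cv)
    ts <- tryCatch(chisq_test(ct), error = function(e) {
      list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
           n_expected_lt_5 = NA_integer_)
    })
    df <- data.frame(covariate = cv, category = rownames(ct$counts),
                     stringsAsFactors = FALSE)
    for (g in groups) {
      df[[paste0("n_", g)]] <- ct$counts[, g]
      df[[paste0("pct_", g)]] <- ct$col_pct[, g]
    }
    rows[[cv]] <- df
    tests[[cv]] <- data.frame(covariate = cv, statistic = ts$statistic,
                              df = ts$df, p_value = ts$p_value,
                              n_expected_lt_5 = ts$n_expected_lt_5,
                              stringsAsFactors = FALSE)
    excl[[cv]] <- ct$n_excluded
  }
  structure(list(
    table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
    col_n = table(labels),
    excluded = do.call(rbind, excl)
  ), class = "baseline_table")
}

#' @export
print.baseline_table <- function(x, ...) {
  cat("baseline_table: group sizes",
      paste(names(x$col_n), as.integer(x$col_n), sep = "=", collapse = ", "),
      "\n")
  print(x$table, row.names = FALSE)
  cat("\nchi-square tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
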