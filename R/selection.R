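#' Fit a grid of group counts for one channel
#'
#' Fits [gbtm_fit()] for every group count in `J_range` (default 2-5, the
#' conventional grid) under a shared seed policy and assembles a
#' goodness-of-fit table with trajectory-convention BIC/AIC and the minimum
#' per-group average posterior probability. A failing fit marks its row
#' failed rather than aborting the grid.
#'
#' @inheritParams gbtm_fit
#' @param J_range integer vector of group counts to try.
#' @param ... further arguments passed to [gbtm_fit()] (`tol`, `max_iter`,
#'   `n_starts`).
#' @return object of class `selection_table`: a list with `table` (one row
#'   per J: `channel`, `J`, `loglik`, `n_params`, `bic_traj`, `aic_traj`,
#'   `min_app`, `converged`, `failed`, `error`) and `fits` (named list of
#'   `gbtm_fit` objects).
#' @export
fit_grid <- function(panel, channel, J_range = 2:5, order = 1L,
                     seed = NULL, ...) {
  if (length(J_range) == 0L) stop("J_range must be non-empty")
  seeds <- derive_seeds(seed, length(J_range))
  fits <- vector("list", length(J_range))
  names(fits) <- as.character(J_range)
  rows <- vector("list", length(J_range))
  prev <- NULL
  for (i in seq_along(J_range)) {
    J <- J_range[i]
    res <- tryCatch(
      gbtm_fit(panel, channel, J, order = order, seed = seeds[i],
               prev_fit = if (!is.null(prev) && prev$params$J == J - 1L)
                 prev else NULL, ...),
      error = function(e) e
    )
    if (!inherits(res, "error")) prev <- res
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        channel = channel, J = J, loglik = NA_real_, n_params = NA_integer_,
        bic_traj = NA_real_, aic_traj = NA_real_, min_app = NA_real_,
        converged = NA, failed = TRUE, error = conditionMessage(res),
        stringsAsFactors = FALSE
      )
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(
        channel = channel, J = J, loglik = res$loglik,
        n_params = res$n_params, bic_traj = res$bic_traj,
        aic_traj = res$aic_traj, min_app = min(res$app, na.rm = TRUE),
        converged = res$converged, failed = FALSE, error = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 channel = channel),
            class = "selection_table")
}

#' Select the best group count from a criteria table
#'
#' Returns the group count maximizing a trajectory-convention criterion
#' (equivalently, minimizing the standard-convention one). Ties go to the
#' smaller J; the result does not depend on row order.
#'
#' @param table a `selection_table`, or any data.frame with columns `J` and
#'   the chosen criterion (e.g. a published goodness-of-fit table).
#' @param criterion `"bic_traj"` (default) or `"aic_traj"`.
#' @return the selected integer group count.
#' @export
select_best <- function(table, criterion = c("bic_traj", "aic_traj")) {
  criterion <- match.arg(criterion)
  df <- if (inherits(table, "selection_table")) table$table else table
  if (!is.null(df$failed)) df <- df[!df$failed, , drop = FALSE]
  df <- df[is.finite(df[[criterion]]), , drop = FALSE]
  if (nrow(df) == 0L) stop("no successful fits to select from")
  df <- df[order(df$J), , drop = FALSE]
  df$J[which.max(df[[criterion]])]
}

#' @export
print.selection_table <- function(x, ...) {
  cat("selection_table, channel '", x$channel, "':\n", sep = "")
  print(x$table[c("J", "loglik", "bic_traj", "aic_traj", "min_app",
                  "converged", "failed")], row.names = FALSE)
  invisible(x)
}
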