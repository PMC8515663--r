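#' Pipeline configuration
#'
#' One object describing a full analysis run: panel source, channels, group
#' grid, missing-data mode, covariate sets and output directory.
#'
#' @param panel a [panel_data] object or a path to a long-format CSV.
#' @param channels the two outcome channels (channel 1 first).
#' @param J_range group-count grid searched per channel.
#' @param order polynomial order of the trajectories.
#' @param seed integer seed controlling every stochastic stage.
#' @param missing_mode `"mar_omit"` (omit missing waves from the likelihood;
#'   default), `"impute"` (single posterior-predictive imputation from an
#'   initial mar_omit fit, then refit on the completed panel), or
#'   `"complete_case"` (keep only subjects observed at every wave — the
#'   sensitivity analysis).
#' @param covariates covariate names entering the baseline tables and
#'   regression models; default: all panel covariates.
#' @param out_dir output directory for artifacts.
#' @param n_starts,max_iter,tol EM control passed to the fitting stages.
#' @param schema optional column mapping passed to [read_panel()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(panel, channels = c("depression", "anxiety"),
                            J_range = 2:5, order = 1L, seed = 1L,
                            missing_mode = c("mar_omit", "impute",
                                             "complete_case"),
                            covariates = NULL, out_dir = tempfile("dualtraj_"),
                            n_starts = 5L, max_iter = 500L, tol = 1e-6,
                            schema = NULL) {
  missing_mode <- match.arg(missing_mode)
  if (is.character(panel) && !file.exists(panel)) {
    stop("panel file does not exist: ", panel)
  }
  structure(list(
    panel = panel, channels = channels, J_range = J_range, order = order,
    seed = as.integer(seed), missing_mode = missing_mode,
    covariates = covariates, out_dir = out_dir, n_starts = n_starts,
    max_iter = max_iter, tol = tol, schema = schema
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields named as in [pipeline_config()].
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$J_range) && length(y$J_range) == 2L) {
    y$J_range <- seq(y$J_range[1], y$J_range[2])
  }
  do.call(pipeline_config, y)
}

# single posterior-predictive imputation of missing outcome cells from a
# mar_omit fit of each channel
impute_panel <- function(panel, J_range, order, seed, n_starts, max_iter, tol) {
  out <- panel
  seeds <- derive_seeds(seed, length(panel$channels) * 2L)
  for (ci in seq_along(panel$channels)) {
    ch <- panel$channels[ci]
    grid <- fit_grid(panel, ch, J_range, order = order, seed = seeds[ci],
                     n_starts = n_starts, max_iter = max_iter, tol = tol)
    J <- select_best(grid)
    fit <- grid$fits[[as.character(J)]]
    Y <- outcome_matrix(panel, ch)
    B <- poly_basis(ncol(Y), order)
    pmat <- stats::plogis(B %*% t(fit$params$beta))   # T x J
    set.seed(seeds[length(panel$channels) + ci])
    for (i in seq_len(nrow(Y))) {
      miss <- which(is.na(Y[i, ]))
      if (!length(miss)) next
      g <- sample.int(J, 1, prob = fit$posterior[i, ])
      Y[i, miss] <- as.numeric(stats::runif(length(miss)) < pmat[miss, g])
    }
    out$outcomes[[ch]] <- Y
  }
  out
}

#' Run the full dual-trajectory pipeline
#'
#' Orchestrates the analysis from one configuration: group-count selection
#' per channel, dual-model fit at the selected counts, conditional membership
#' probabilities in both directions, observed/predicted trajectory curves,
#' baseline characteristic tables with chi-square tests, and univariate plus
#' multivariate odds-ratio tables (the multivariate model includes the other
#' channel's assigned group as a predictor). All artifacts are written under
#' `config$out_dir` and listed in a JSON manifest together with the seed and
#' a config hash; results are reproducible from the seed.
#'
#' @param config a [pipeline_config] object.
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read_panel"
  art <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    art <<- c(art, name)
    p
  }
  withCallingHandlers({
    panel <- if (is.character(config$panel)) {
      read_panel(config$panel, schema = config$schema,
                 channels = config$channels)
    } else config$panel
    n_full <- n_subjects(panel)

    stage <- "missing_mode"
    if (config$missing_mode == "complete_case") {
      panel <- complete_cases_panel(panel)
    } else if (config$missing_mode == "impute") {
      panel <- impute_panel(panel, config$J_range, config$order, config$seed,
                            config$n_starts, config$max_iter, config$tol)
    }

    seeds <- derive_seeds(config$seed, 4L)
    chosen <- list()
    grids <- list()
    for (ci in 1:2) {
      ch <- config$channels[ci]
      stage <- paste0("fit_grid:", ch)
      grid <- fit_grid(panel, ch, config$J_range, order = config$order,
                       seed = seeds[ci], n_starts = config$n_starts,
                       max_iter = config$max_iter, tol = config$tol)
      grids[[ch]] <- grid
      emit(grid$table, paste0("selection_", ch, ".csv"))
      chosen[[ch]] <- select_best(grid)
    }

    stage <- "dual_fit"
    Jstar <- chosen[[config$channels[1]]]
    Kstar <- chosen[[config$channels[2]]]
    dfit <- dual_fit(panel, Jstar, Kstar, order = config$order,
                     channels = config$channels,
                     init = list(grids[[config$channels[1]]]$fits[[as.character(Jstar)]],
                                 grids[[config$channels[2]]]$fits[[as.character(Kstar)]]),
                     n_starts = config$n_starts, seed = seeds[3],
                     max_iter = config$max_iter, tol = config$tol)

    dump <- list(
      channels = config$channels, J = Jstar, K = Kstar,
      order = config$order,
      beta1 = dfit$params$beta1, beta2 = dfit$params$beta2,
      joint_pi = dfit$params$joint_pi,
      loglik = dfit$loglik, n_params = dfit$n_params, N = dfit$N,
      bic_traj = dfit$bic_traj, aic_traj = dfit$aic_traj,
      app1 = dfit$app1, app2 = dfit$app2, converged = dfit$converged
    )
    jsonlite::write_json(dump, file.path(config$out_dir, "dual_fit.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    art <- c(art, "dual_fit.json")

    stage <- "conditional_probs"
    emit(as.data.frame(conditional_probs(dfit, "2|1")),
         paste0("cond_", config$channels[2], "_given_",
                config$channels[1], ".csv"))
    emit(as.data.frame(conditional_probs(dfit, "1|2")),
         paste0("cond_", config$channels[1], "_given_",
                config$channels[2], ".csv"))

    stage <- "trajectory_curves"
    curves1 <- trajectory_curves(
      list(params = traj_params(dfit$params$beta1,
                                marginal_probs(dfit)$channel1),
           posterior = dfit$posterior1, assignment = dfit$assignment1),
      panel, config$channels[1])
    emit(curves1, paste0("curves_", config$channels[1], ".csv"))
    curves2 <- trajectory_curves(
      list(params = traj_params(dfit$params$beta2,
                                marginal_probs(dfit)$channel2),
           posterior = dfit$posterior2, assignment = dfit$assignment2),
      panel, config$channels[2])
    emit(curves2, paste0("curves_", config$channels[2], ".csv"))

    stage <- "association"
    covs <- config$covariates %||%
      setdiff(names(panel$covariates), "id")
    labels1 <- factor(dfit$assignment1)
    labels2 <- factor(dfit$assignment2)
    if (length(covs)) {
      bt1 <- baseline_table(panel, labels1, covs)
      emit(bt1$table, paste0("baseline_", config$channels[1], ".csv"))
      emit(bt1$tests, paste0("baseline_tests_", config$channels[1], ".csv"))
      bt2 <- baseline_table(panel, labels2, covs)
      emit(bt2$table, paste0("baseline_", config$channels[2], ".csv"))
      emit(bt2$tests, paste0("baseline_tests_", config$channels[2], ".csv"))

      X1 <- cbind(panel$covariates[covs],
                  other_group = labels2)
      X2 <- cbind(panel$covariates[covs],
                  other_group = labels1)
      mv1 <- tryCatch(multinomial_logit(labels1, X1), error = function(e) NULL)
      if (!is.null(mv1)) emit(as.data.frame(mv1),
                              paste0("or_multivariate_", config$channels[1], ".csv"))
      mv2 <- tryCatch(multinomial_logit(labels2, X2), error = function(e) NULL)
      if (!is.null(mv2)) emit(as.data.frame(mv2),
                              paste0("or_multivariate_", config$channels[2], ".csv"))

      uv1 <- univariate_screen(labels1, X1)
      uv1_ok <- uv1[vapply(uv1, inherits, TRUE, "or_table")]
      if (length(uv1_ok)) {
        uv_df <- do.call(rbind, Map(function(nm, t) cbind(covariate = nm,
                                                          as.data.frame(t)),
                                    names(uv1_ok), uv1_ok))
        emit(uv_df, paste0("or_univariate_", config$channels[1], ".csv"))
      }
    }

    stage <- "manifest"
    cfg_for_hash <- config
    cfg_for_hash$panel <- if (is.character(config$panel)) config$panel else
      "in-memory panel"
    cfg_for_hash$out_dir <- NULL  # location must not affect the run's identity
    cfg_json <- jsonlite::toJSON(unclass(cfg_for_hash), auto_unbox = TRUE,
                                 digits = NA, null = "null", force = TRUE)
    tmp <- file.path(config$out_dir, "config.json")
    writeLines(as.character(cfg_json), tmp)
    art <- c(art, "config.json")
    manifest <- list(
      seed = config$seed,
      missing_mode = config$missing_mode,
      config_md5 = unname(tools::md5sum(tmp)),
      n_subjects_input = n_full,
      n_subjects_analyzed = n_subjects(panel),
      chosen_groups = chosen,
      artifacts = sort(art)
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Observed and predicted trajectory curves
#'
#' For each group and wave: the observed outcome proportion among subjects
#' assigned to the group with a non-missing value at that wave, the number of
#' such subjects, and the model-predicted probability — the data behind the
#' classic observed-vs-predicted trajectory figure. A group-wave cell with no
#' observed subjects gets `NA` observed; the prediction is still emitted.
#'
#' @param fit a `gbtm_fit` (or a list with `params` and `assignment`).
#' @param panel a [panel_data] object.
#' @param channel outcome channel name.
#' @return data.frame with columns `group`, `wave`, `n_observed`, `observed`,
#'   `predicted`.
#' @export
trajectory_curves <- function(fit, panel, channel) {
  Y <- outcome_matrix(panel, channel)
  beta <- fit$params$beta
  J <- nrow(beta)
  assignment <- fit$assignment
  B <- poly_basis(ncol(Y), ncol(beta) - 1L)
  pred <- stats::plogis(B %*% t(beta))
  rows <- list()
  for (j in seq_len(J)) {
    Yj <- Y[assignment == j, , drop = FALSE]
    n_obs <- colSums(!is.na(Yj))
    obs <- ifelse(n_obs > 0, colMeans(Yj, na.rm = TRUE), NA_real_)
    rows[[j]] <- data.frame(group = j, wave = 0:(ncol(Y) - 1L),
                            n_observed = n_obs, observed = obs,
                            predicted = pred[, j])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
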