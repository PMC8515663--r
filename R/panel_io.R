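#' Longitudinal binary-outcome panel
#'
#' Container for subjects x waves binary outcome observations (with
#' missingness) plus baseline covariates. One or two outcome channels (e.g.
#' annual indicators of health-service use for depression and anxiety) are
#' stored as N x T matrices of 0/1/NA, all on a common wave grid 0..T-1.
#'
#' @param data long-format data.frame with columns `id`, `wave`, one column
#'   per outcome channel (values 0, 1 or NA), and optionally one column per
#'   baseline covariate (constant within subject).
#' @param channels character vector naming the outcome columns. Defaults to
#'   the intersection of `c("depression", "anxiety")` with `names(data)`.
#' @param n_waves total number of waves `T`; defaults to `max(wave) + 1`.
#' @param align_entry_to_baseline if `TRUE`, each subject's waves are shifted
#'   so that their first observed wave becomes wave 0 (the re-indexing used
#'   when a refresh cohort enters a panel study late). Default `FALSE`
#'   because the shift is not invertible for intermittently missing data.
#' @return object of class `panel_data` with elements `subjects` (ids),
#'   `n_waves`, `channels`, `outcomes` (named list of N x T matrices),
#'   `covariates` (data.frame, one row per subject) and `n_dropped` (subjects
#'   removed for having no observed wave on some channel).
#' @export
panel_data <- function(data, channels = NULL, n_waves = NULL,
                       align_entry_to_baseline = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c("id", "wave")
  if (!all(need %in% names(data))) {
    stop("panel data needs columns 'id' and 'wave'")
  }
  if (is.null(channels)) {
    channels <- intersect(c("depression", "anxiety"), names(data))
  }
  if (length(channels) < 1L && nrow(data) > 0L) {
    stop("no outcome channel columns found")
  }
  missing_ch <- setdiff(channels, names(data))
  if (length(missing_ch)) {
    stop("channel column(s) not present: ", paste(missing_ch, collapse = ", "))
  }
  covariate_cols <- setdiff(names(data), c("id", "wave", channels))

  if (nrow(data) == 0L) {
    out <- structure(list(
      subjects = character(0),
      n_waves = if (is.null(n_waves)) 0L else as.integer(n_waves),
      channels = channels,
      outcomes = stats::setNames(
        lapply(channels, function(ch) matrix(NA_real_, 0, 0)), channels),
      covariates = data.frame(id = character(0)),
      n_dropped = 0L
    ), class = "panel_data")
    return(out)
  }

  data$id <- as.character(data$id)
  wv <- suppressWarnings(as.numeric(data$wave))
  bad <- which(is.na(wv) | wv != floor(wv) | wv < 0)
  if (length(bad)) {
    stop("malformed wave index at data row ", bad[1],
         " (value '", data$wave[bad[1]], "')")
  }
  data$wave <- as.integer(wv)

  for (ch in channels) {
    v <- data[[ch]]
    if (is.character(v)) {
      v[!nzchar(trimws(v))] <- NA
      v <- suppressWarnings(as.numeric(v))
      if (any(is.na(v) & nzchar(trimws(data[[ch]])) & !is.na(data[[ch]]))) {
        bad <- which(is.na(v) & !is.na(data[[ch]]) & nzchar(trimws(data[[ch]])))
        stop("non-binary outcome value for '", ch, "' at data row ", bad[1],
             " (value '", data[[ch]][bad[1]], "')")
      }
    } else {
      v <- as.numeric(v)
    }
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad)) {
      stop("non-binary outcome value for '", ch, "' at data row ", bad[1],
           " (value '", data[[ch]][bad[1]], "')")
    }
    data[[ch]] <- v
  }

  if (align_entry_to_baseline) {
    obs_any <- Reduce(`|`, lapply(channels, function(ch) !is.na(data[[ch]])))
    first_obs <- tapply(ifelse(obs_any, data$wave, NA_integer_), data$id,
                        function(w) suppressWarnings(min(w, na.rm = TRUE)))
    first_obs[!is.finite(first_obs)] <- 0
    data$wave <- data$wave - as.integer(first_obs[data$id])
    data <- data[data$wave >= 0, , drop = FALSE]
  }

  dup <- duplicated(data[c("id", "wave")])
  if (any(dup)) {
    d <- which(dup)[1]
    stop("duplicate (id, wave) pair at data row ", d, " (id '", data$id[d],
         "', wave ", data$wave[d], ")")
  }

  if (is.null(n_waves)) n_waves <- max(data$wave) + 1L
  n_waves <- as.integer(n_waves)
  if (any(data$wave >= n_waves)) {
    bad <- which(data$wave >= n_waves)[1]
    stop("wave index out of range at data row ", bad)
  }

  subjects <- unique(data$id)
  N <- length(subjects)
  idx_i <- match(data$id, subjects)
  idx_t <- data$wave + 1L

  outcomes <- lapply(channels, function(ch) {
    m <- matrix(NA_real_, N, n_waves,
                dimnames = list(subjects, NULL))
    m[cbind(idx_i, idx_t)] <- data[[ch]]
    m
  })
  names(outcomes) <- channels

  covariates <- data.frame(id = subjects, stringsAsFactors = FALSE)
  for (cv in covariate_cols) {
    vraw <- as.character(data[[cv]])
    vraw[!is.na(vraw) & !nzchar(trimws(vraw))] <- NA_character_
    vals <- tapply(vraw, idx_i, function(v) {
      u <- unique(v[!is.na(v)])
      if (length(u) > 1L) {
        stop("covariate '", cv, "' varies within a subject", call. = FALSE)
      }
      if (length(u) == 0L) NA_character_ else u
    })
    covariates[[cv]] <- as.character(vals[as.character(seq_len(N))])
  }

  # drop subjects with no observed wave on any modeled channel
  keep <- rep(TRUE, N)
  for (ch in channels) {
    keep <- keep & rowSums(!is.na(outcomes[[ch]])) > 0
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " subject(s) dropped: no observed outcome wave")
    subjects <- subjects[keep]
    outcomes <- lapply(outcomes, function(m) m[keep, , drop = FALSE])
    covariates <- covariates[keep, , drop = FALSE]
    rownames(covariates) <- NULL
  }

  structure(list(
    subjects = subjects,
    n_waves = n_waves,
    channels = channels,
    outcomes = outcomes,
    covariates = covariates,
    n_dropped = n_dropped
  ), class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("panel_data:", length(x$subjects), "subjects x", x$n_waves, "waves;",
      "channels:", paste(x$channels, collapse = ", "), "\n")
  for (ch in x$channels) {
    m <- x$outcomes[[ch]]
    if (length(m)) {
      cat(sprintf("  %s: %.1f%% observed, prevalence %.3f\n", ch,
                  100 * mean(!is.na(m)), mean(m, na.rm = TRUE)))
    }
  }
  cv <- setdiff(names(x$covariates), "id")
  if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a panel
#' @param panel a [panel_data] object.
#' @return integer subject count.
#' @export
n_subjects <- function(panel) length(panel$subjects)

#' Extract one channel's outcome matrix
#' @param panel a [panel_data] object.
#' @param channel channel name.
#' @return N x T numeric matrix of 0/1/NA.
#' @export
outcome_matrix <- function(panel, channel) {
  if (!channel %in% panel$channels) {
    stop("channel '", channel, "' not present in panel")
  }
  panel$outcomes[[channel]]
}

#' Read a long-format panel CSV
#'
#' Expects a header row and one row per subject-wave with columns `id`,
#' `wave`, the outcome channels, and any baseline covariates. Outcome cells
#' are 0, 1 or blank (blank = not observed). Subjects with no observed wave
#' on a modeled channel are dropped with a message stating the count.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping package column names
#'   to file column names, e.g. `c(id = "pid", wave = "year_idx")`.
#' @inheritParams panel_data
#' @return a [panel_data] object.
#' @export
read_panel <- function(path, schema = NULL, channels = NULL, n_waves = NULL,
                       align_entry_to_baseline = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    for (nm in names(schema)) {
      if (!schema[[nm]] %in% names(df)) {
        stop("schema column '", schema[[nm]], "' not found in ", path)
      }
      names(df)[names(df) == schema[[nm]]] <- nm
    }
  }
  panel_data(df, channels = channels, n_waves = n_waves,
             align_entry_to_baseline = align_entry_to_baseline)
}

#' Convert a panel back to long format
#' @param x a [panel_data] object.
#' @param ... unused.
#' @return long data.frame with one row per (subject, wave), missing outcomes
#'   as NA.
#' @export
as.data.frame.panel_data <- function(x, ...) {
  N <- length(x$subjects)
  if (N == 0L) {
    cols <- c("id", "wave", x$channels,
              setdiff(names(x$covariates), "id"))
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  out <- data.frame(
    id = rep(x$subjects, each = x$n_waves),
    wave = rep(0:(x$n_waves - 1L), times = N),
    stringsAsFactors = FALSE
  )
  for (ch in x$channels) {
    out[[ch]] <- as.vector(t(x$outcomes[[ch]]))
  }
  for (cv in setdiff(names(x$covariates), "id")) {
    out[[cv]] <- rep(x$covariates[[cv]], each = x$n_waves)
  }
  out
}

#' Write a panel to CSV
#'
#' Writes the full subject x wave grid (missing outcomes as blank cells) so
#' that [read_panel()] reproduces the panel exactly, including the
#' missingness pattern and the number of waves.
#'
#' @param panel a [panel_data] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a panel to given subjects
#' @param panel a [panel_data] object.
#' @param ids subject ids to keep.
#' @return a [panel_data] object.
#' @export
subset_panel <- function(panel, ids) {
  keep <- panel$subjects %in% ids
  out <- panel
  out$subjects <- panel$subjects[keep]
  out$outcomes <- lapply(panel$outcomes, function(m) m[keep, , drop = FALSE])
  out$covariates <- panel$covariates[keep, , drop = FALSE]
  rownames(out$covariates) <- NULL
  out
}

#' Complete-case restriction
#'
#' Keeps only subjects observed at every wave on every channel — the
#' restriction used for a complete-data sensitivity analysis.
#'
#' @param panel a [panel_data] object.
#' @return a [panel_data] object containing the fully observed subjects.
#' @export
complete_cases_panel <- function(panel) {
  if (length(panel$subjects) == 0L) return(panel)
  full <- rep(TRUE, length(panel$subjects))
  for (ch in panel$channels) {
    full <- full & rowSums(is.na(panel$outcomes[[ch]])) == 0
  }
  subset_panel(panel, panel$subjects[full])
}
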