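# Readers and writers for choice data, fits and prediction-error reports.
# CSV dialect: comma-separated, UTF-8, '.' decimal, mandatory header.

.required_choice_cols <- c("participant_id", "run", "r_imm", "r_del",
                           "delay_days", "choice")

#' Read a choice CSV into per-participant records
#'
#' Expects columns `participant_id`, `run`, `r_imm`, `r_del`,
#' `delay_days`, `choice` (optionally `condition`, `target_p`, `rt_s`).
#' Malformed rows are rejected with row-number diagnostics.
#'
#' @param path Path to a CSV file.
#' @return Nested list: `records[[participant]][[run]]` is a choice data
#'   frame.
#' @export
read_choice_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty choice file: ", path)
  missing <- setdiff(.required_choice_cols, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!(df$choice %in% c(0, 1)))
  if (length(bad) > 0L)
    stop("non-binary choice in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(df$r_del <= 0 | df$r_imm < 0 | df$delay_days < 0)
  if (length(bad) > 0L)
    stop("invalid reward/delay in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  lapply(split(df, df$participant_id),
         function(d) lapply(split(d, d$run), function(r) {
           rownames(r) <- NULL
           r
         }))
}

#' Write a trial or choice data frame as CSV
#'
#' @param df Data frame; money columns are written with 2 decimals.
#' @param path Output path.
#' @export
write_choice_csv <- function(df, path) {
  for (col in intersect(c("r_imm", "r_del"), names(df)))
    df[[col]] <- sprintf("%.2f", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  spec <- attr(fit$params, "spec")
  jsonlite::write_json(list(
    model = fit$model,
    values = fit$params[spec$param_names],
    lower = as.list(spec$lower), upper = as.list(spec$upper),
    neg_log_lik = fit$neg_log_lik, n_params = fit$n_params,
    n_starts = fit$n_starts, converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialised fit result
#'
#' @param path Path written by [write_fit_json()].
#' @return A `fit_result`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path)
  params <- do.call(param_vector,
                    c(list(model_spec(x$model)),
                      lapply(x$values, as.numeric)))
  structure(list(params = params,
                 neg_log_lik = as.numeric(x$neg_log_lik),
                 n_params = as.integer(x$n_params),
                 n_starts = as.integer(x$n_starts),
                 converged = isTRUE(x$converged),
                 model = x$model), class = "fit_result")
}

#' Write a prediction-error report as CSV (+ JSON summary)
#'
#' Rows are ordered deterministically (participant, model, direction);
#' re-reading the CSV reproduces the written values.
#'
#' @param report A `pe_report` from [cross_run_pe()].
#' @param path CSV output path; a `.json` summary (mean PE per model and
#'   direction) is written alongside.
#' @export
write_pe_report <- function(report, path) {
  stopifnot(inherits(report, "pe_report"))
  pe <- report$pe
  if (is.null(pe)) pe <- data.frame(participant = character(0),
                                    model = character(0),
                                    direction = character(0),
                                    deviance = numeric(0),
                                    n_trials = integer(0))
  pe <- pe[order(pe$participant, pe$model, pe$direction), ]
  utils::write.csv(pe, path, row.names = FALSE, quote = FALSE)
  if (nrow(pe) > 0) {
    summ <- stats::aggregate(deviance ~ model + direction, data = pe,
                             FUN = mean)
    jsonlite::write_json(summ, sub("\\.csv$", ".json", path),
                         digits = NA)
  }
  invisible(path)
}

#' Read a prediction-error CSV back into a data frame
#'
#' @param path CSV written by [write_pe_report()].
#' @return Data frame with the PE rows.
#' @export
read_pe_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant = "character"))
}

#' Serialise a design grid to JSON
#'
#' @param grid A [design_grid()].
#' @param path Output path.
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "design_grid"))
  jsonlite::write_json(list(
    delays = grid$delays, delayed_rewards = grid$delayed_rewards,
    targets = grid$targets,
    representative_params = lapply(grid$representative_params, as.list)
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a design grid from JSON
#'
#' @param path Path written by [write_grid_json()].
#' @return A [design_grid()].
#' @export
read_grid_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design_grid(delays = x$delays, delayed_rewards = x$delayed_rewards,
              targets = x$targets,
              representative_params = lapply(
                seq_len(nrow(x$representative_params)),
                function(i) unlist(x$representative_params[i, ])))
}
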