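#' Read a trial-level discrimination table
#'
#' The trial table is a delimited file with one row per subject x
#' mixture-pair 3-AFC judgment and (at least) the columns
#' `subject_id`, `N`, `O`, `pair_id`, `correct`.  Extra columns are kept.
#'
#' @param path file path.
#' @param delim field delimiter; `","` (default) or `"\t"`.
#' @return a tibble validated against the schema; per-row violations are
#'   reported with their line numbers.
#' @export
read_trials <- function(path, delim = ",") {
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("subject_id", "N", "O", "pair_id", "correct")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  validate_trials(tab, origin = path)
}

validate_trials <- function(tab, origin = "trial table") {
  line <- seq_len(nrow(tab)) + 1L  # header is line 1 in the file
  problems <- character(0)
  bad <- which(!tab$correct %in% c(0, 1))
  if (length(bad)) {
    problems <- c(problems, paste0(
      "line ", bad[1] + 1L, ": correct must be 0 or 1 (got ",
      tab$correct[bad[1]], ")"))
  }
  bad <- which(tab$O < 0 | tab$O > tab$N)
  if (length(bad)) {
    problems <- c(problems, paste0(
      "line ", bad[1] + 1L, ": overlap O=", tab$O[bad[1]],
      " outside [0, N=", tab$N[bad[1]], "]"))
  }
  if (anyDuplicated(tab[, c("subject_id", "pair_id")])) {
    d <- which(duplicated(tab[, c("subject_id", "pair_id")]))[1]
    problems <- c(problems, paste0(
      "line ", d + 1L, ": duplicate (subject_id, pair_id) = (",
      tab$subject_id[d], ", ", tab$pair_id[d], ")"))
  }
  if (length(problems)) {
    stop("invalid ", origin, ":\n  ", paste(problems, collapse = "\n  "))
  }
  tibble::as_tibble(tab)
}

#' Write a trial table
#'
#' @param table a trial tibble (see [read_trials] for the schema).
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path, delim = ",") {
  readr::write_delim(table, path, delim = delim)
  invisible(path)
}

#' Aggregate trials into performance records
#'
#' Collapses the trial table along one of its two testing axes:
#'
#' * `axis = "pair"`: one record per mixture pair; `trials` is the
#'   number of subjects who tested that pair, `successes` the number who
#'   answered correctly (the subject count `S` is the sample size).
#' * `axis = "subject"`: one record per subject x mixture class;
#'   `trials` is the number of pairs of that class the subject was
#'   tested on (the per-class test count `T` is the sample size).
#'
#' @param table a trial tibble.
#' @param axis `"pair"` or `"subject"`.
#' @return a tibble of performance records with columns `N`, `O`,
#'   `unit`, `successes`, `trials`, `fraction_correct`,
#'   `percent_overlap`.
#' @export
summarize_trials <- function(table, axis = c("pair", "subject")) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) {
    stop("empty trial table")
  }
  key <- if (axis == "pair") "pair_id" else "subject_id"
  table |>
    dplyr::group_by(.data$N, .data$O, unit = .data[[key]]) |>
    dplyr::summarise(
      successes = sum(.data$correct),
      trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction_correct = .data$successes / .data$trials,
      percent_overlap = 100 * .data$O / .data$N
    ) |>
    dplyr::arrange(.data$N, .data$O, .data$unit)
}

#' Assemble a run configuration
#'
#' Captures every parameter the estimate is sensitive to, so results can
#' carry full provenance.
#'
#' @param ... named parameter overrides.
#' @return a named list with class `run_config`; defaults follow the
#'   canonical analysis (`alpha = 0.05`, `chance = 1/3`, `axis = "pair"`,
#'   `correction = "none"`, `method = "significance"`,
#'   `threshold = 0.5`, `C = 128`, `T = 20`, `S = 26`).
#' @export
run_config <- function(...) {
  cfg <- list(
    alpha = 0.05, chance = 1/3, axis = "pair", correction = "none",
    method = "significance", threshold = 0.5, theta = NA_real_,
    C = 128, T = 20, S = 26, interp = "log", seed = NA_integer_
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write results with embedded provenance
#'
#' Serializes a result object together with the configuration that
#' produced it and the package version, with deterministic field order,
#' so that identical inputs give byte-identical files.
#'
#' @param results a list or data frame.
#' @param path output path.
#' @param config a [run_config].
#' @param format `"json"` or `"csv"` (data frames only).
#' @return `path`, invisibly.
#' @export
report_results <- function(results, path, config = run_config(),
                           format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    stopifnot(is.data.frame(results))
    header <- paste0("# odorspace ",
                     as.character(utils::packageVersion("odorspace")),
                     " config: ",
                     jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA))
    writeLines(header, path)
    readr::write_csv(results, path, append = TRUE, col_names = TRUE)
  } else {
    payload <- list(
      package = "odorspace",
      version = as.character(utils::packageVersion("odorspace")),
      config = unclass(config),
      results = results
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}
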