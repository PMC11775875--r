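#' Long-format results table
#'
#' Canonical long format for quantified responses: one row per
#' participant x task x condition x location x measure. The key columns
#' (all except `value`) must identify a row uniquely.
#'
#' @param ... vectors for columns `participant`, `task`, `emotion`,
#'   `intensity`, `roi`, `channel`, `measure`, `harmonic`, `value`;
#'   missing key columns are filled with `NA`.
#' @return data.frame of class `fpvs_results`.
#' @export
results_table <- function(...) {
  cols <- list(...)
  keys <- c("participant", "task", "emotion", "intensity", "roi",
            "channel", "measure", "harmonic")
  if (is.null(cols$value)) stop("a value column is required")
  n <- length(cols$value)
  df <- data.frame(row.names = seq_len(n))
  for (k in keys)
    df[[k]] <- if (!is.null(cols[[k]])) cols[[k]] else rep(NA, n)
  df$value <- cols$value
  if (!all(is.finite(df$value))) stop("values must be finite")
  check_result_keys(df)
  class(df) <- c("fpvs_results", "data.frame")
  df
}

check_result_keys <- function(df) {
  keys <- setdiff(names(df), "value")
  key <- do.call(paste, c(df[keys], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate key tuples in results table")
  invisible(df)
}

#' Concatenate results tables
#'
#' @param tables list of `fpvs_results` (or compatible data.frames).
#' @return single `fpvs_results`; errors on schema mismatch or duplicate
#'   key tuples.
#' @export
concat_tables <- function(tables) {
  tables <- Filter(function(t) nrow(t) > 0, tables)
  if (length(tables) == 0L) return(results_table(value = numeric(0)))
  schema <- names(tables[[1]])
  for (t in tables[-1])
    if (!identical(names(t), schema))
      stop("schema mismatch between results tables")
  out <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(out) <- NULL
  check_result_keys(out)
  class(out) <- c("fpvs_results", "data.frame")
  out
}
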