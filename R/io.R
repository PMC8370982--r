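#' Read time series from a delimited text file
#'
#' Expects a header row with a `time` column, one column per variable, and an
#' optional `regime` column holding the regime labels. Empty fields become
#' missing values (`NA`); lines starting with `#` are metadata comments and
#' are skipped.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return Without a `regime` column (or with a single label): a named list of
#'   [regime_series()], one per variable column. With two labels: a
#'   [regime_pair()]. More than two labels is an error.
#' @export
read_series <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("input must have a `time` column")
  if (is.unsorted(df$time, strictly = TRUE)) {
    stop("`time` column must be strictly increasing")
  }
  vars <- setdiff(names(df), c("time", "regime"))
  if (length(vars) == 0L) stop("no variable columns found")
  for (v in vars) {
    if (!is.numeric(df[[v]])) stop(sprintf("variable column `%s` is not numeric", v))
  }
  build <- function(d, label) {
    stats::setNames(lapply(vars, function(v) {
      regime_series(d[[v]], d$time, regime = label, variable = v)
    }), vars)
  }
  if (!"regime" %in% names(df) || length(unique(df$regime)) == 1L) {
    lab <- if ("regime" %in% names(df)) unique(df$regime) else "A"
    return(build(df, lab))
  }
  labs <- unique(df$regime)
  if (length(labs) != 2L) {
    stop("`regime` column must hold one or two labels, found: ",
         paste(labs, collapse = ", "))
  }
  regime_pair(build(df[df$regime == labs[1], , drop = FALSE], labs[1]),
              build(df[df$regime == labs[2], , drop = FALSE], labs[2]))
}

#' Write time series to a delimited text file
#'
#' Writes aligned series as a header + data table readable by
#' [read_series()], with optional `#`-prefixed metadata comment lines (seed,
#' parameters) before the header.
#'
#' @param series A [regime_series()] or named list of aligned
#'   `regime_series`.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @param metadata Optional character vector written as `# `-prefixed comment
#'   lines.
#' @param regime_column Include a `regime` label column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, delim = ",", metadata = NULL,
                         regime_column = TRUE) {
  if (inherits(series, "regime_series")) series <- list(series)
  names(series) <- vapply(series, function(s) s$variable, "")
  tt <- series[[1]]$times
  for (s in series) {
    if (!isTRUE(all.equal(s$times, tt))) stop("series must share a time grid")
  }
  df <- data.frame(time = tt)
  for (s in series) df[[s$variable]] <- s$values
  if (regime_column) df$regime <- series[[1]]$regime
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) writeLines(paste("#", metadata), con)
  utils::write.table(df, con, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a regime test result as a flat JSON record
#'
#' @param x A `regime_test_result`.
#' @return A single-line JSON string with all scalar fields.
#' @export
format_regime_test_json <- function(x) {
  stopifnot(inherits(x, "regime_test_result"))
  fields <- c("target_regime", "library_regime", "mode", "mape_within",
              "mape_across", "observed_difference", "p_value", "significant",
              "alpha", "n_within", "n_across", "n_permutations", "seed",
              "E_within", "E_across")
  enc <- vapply(fields, function(f) {
    v <- x[[f]]
    s <- if (is.null(v)) "null"
    else if (is.character(v)) sprintf("\"%s\"", v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15)
    sprintf("\"%s\": %s", f, s)
  }, "")
  paste0("{", paste(enc, collapse = ", "), "}")
}
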