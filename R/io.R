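#' @include pipeline.R
NULL

#' Read / write behavioral trial tables as TSV
#'
#' @param trials a trial table data.frame.
#' @param path file path.
#' @return \code{readTrialTable} returns the data.frame;
#'   \code{writeTrialTable} returns \code{path} invisibly.
#' @export
writeTrialTable <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a StatTable to TSV or JSON
#'
#' @param table a StatTable data.frame (from [rmAnova2x2()],
#'   [baselineContrastTable()], [congruencyTable()] or
#'   [behavioralAnova()]).
#' @param path output path; the extension selects the format
#'   (\code{.json} writes JSON, anything else tab-separated text).
#' @return \code{path}, invisibly.
#' @export
writeStatTable <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write component loadings to TSV
#'
#' One row per variable (electrode or timepoint), one column per extracted
#' component, rotated loadings.
#'
#' @param model a [ComponentModel-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLoadings <- function(model, path) {
  L <- componentLoadings(model, rotated = TRUE)
  df <- data.frame(variable = model@variables, L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1L] <- model@componentNames
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
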