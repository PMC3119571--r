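#' Write a tabular report
#'
#' Serialises a list of flat key-value records (or a data.frame) to CSV
#' (RFC 4180, '.' decimal, header row) or JSON (array of objects). All
#' records must share one key set.
#'
#' @param records list of named lists sharing a key set, or a data.frame.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @param schema character vector of column names, required when writing an
#'   empty record set (header-only CSV / empty JSON array).
#' @return number of records written, invisibly.
#' @export
write_report <- function(records, path, format = c("csv", "json"), schema = NULL) {
  format <- match.arg(format)
  if (is.data.frame(records)) {
    df <- records
  } else if (!length(records)) {
    if (is.null(schema)) abort_usage("empty record set needs an explicit schema")
    df <- as.data.frame(setNames(rep(list(logical(0)), length(schema)), schema))
  } else {
    keys <- lapply(records, function(r) sort(names(r)))
    ref <- keys[[1]]
    for (i in seq_along(keys)) {
      if (!identical(keys[[i]], ref)) {
        diffs <- union(setdiff(keys[[i]], ref), setdiff(ref, keys[[i]]))
        abort_schema("record %d has a different key set (differing keys: %s)",
                     i, paste(diffs, collapse = ", "))
      }
    }
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r[names(records[[1]])])))
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(nrow(df))
}
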