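# AIRR Rearrangement TSV input/output.

#' Read an AIRR Rearrangement TSV
#'
#' Reads a tab-separated rearrangement table and checks that every required
#' column is present. Logical columns use the AIRR `T`/`F` convention;
#' custom columns (`subject_id`, `tissue`, `group`, `phix`,
#' `c_region_mismatches`, `clone_id`) are carried when present.
#'
#' @param path file path.
#' @return data.frame of rearrangement records (possibly 0 rows).
#' @export
readAirr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", na.strings = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(AIRR_REQUIRED, names(tab))
  if (length(missing))
    stop("missing required AIRR column(s): ", paste(missing, collapse = ", "))
  for (col in c("duplicate_count", "consensus_count", "c_region_mismatches"))
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  for (col in c("productive", "phix"))
    if (col %in% names(tab)) tab[[col]] <- tab[[col]] %in% c("T", "TRUE", "true")
  tab
}

#' Write an AIRR Rearrangement TSV
#'
#' Inverse of [readAirr()]: `readAirr(writeAirr(x, f))` is the identity on
#' all required columns. Logical columns are written as `T`/`F`.
#'
#' @param records record data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAirr <- function(records, path) {
  out <- records
  for (col in names(out))
    if (is.logical(out[[col]])) out[[col]] <- ifelse(out[[col]], "T", "F")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
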