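#' Render a validation report
#'
#' Formats `validationRecords` the way published validation tables are laid
#' out: published SNP, QTL code, its p-value in the subset scan, the best
#' candidate SNP with its p-value, the physical distance (printed with
#' thousands separators), and the LD r-squared — `"Same SNP"` when criterion
#' 1 fired and `"No"` when LD was not computable — plus a `validated`
#' column standing in for the usual row highlighting. Optionally writes two
#' files: `<path>` with the machine-readable records (plain numbers, `NA`
#' for undefined) and `<path>.txt` with the formatted table.
#'
#' @param records a `validationRecords` data.frame from [validateQtls()].
#' @param summary optional `crossSetSummary` appended to the text report.
#' @param path optional output TSV path.
#' @return the formatted data.frame, invisibly when `path` is given.
#' @export
renderReport <- function(records, summary = NULL, path = NULL) {
  fmt <- data.frame(
    snp = records$snp,
    qtl = records$qtl,
    p_published = signif(records$p_published, 3),
    candidate_snp = ifelse(is.na(records$candidate_snp), "",
                           records$candidate_snp),
    candidate_p = ifelse(is.na(records$candidate_p), "",
                         signif(records$candidate_p, 3)),
    distance_bp = ifelse(is.na(records$distance_bp), "",
                         format(records$distance_bp, big.mark = ",",
                                trim = TRUE, scientific = FALSE)),
    ld_r2 = ifelse(records$criterion == "same_snp", "Same SNP",
                   ifelse(is.na(records$r2), "No",
                          format(round(records$r2, 2), nsmall = 2))),
    validated = records$validated,
    stringsAsFactors = FALSE)
  if (nrow(records) == 0L) fmt <- fmt[0L, ]
  if (!is.null(path)) {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    txt <- paste0(path, ".txt")
    con <- file(txt, "w")
    on.exit(close(con))
    writeLines(capture_table(fmt), con)
    if (!is.null(summary)) {
      writeLines("", con)
      writeLines(utils::capture.output(print(summary)), con)
    }
    return(invisible(fmt))
  }
  fmt
}

capture_table <- function(df) {
  if (!nrow(df)) return(paste(names(df), collapse = "\t"))
  utils::capture.output(print(df, row.names = FALSE))
}
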