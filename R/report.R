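# JSON run reports with conservation-checked read accounting.

#' Build a decontamination run report
#'
#' One report per input sample. Construction enforces the conservation
#' invariant `reads_in = reads_out + reads_removed`; a violation is a hard
#' error, never silently serialized.
#'
#' @param fastq1,fastq2 input path(s).
#' @param reads_in,reads_out,reads_removed read-unit counts for the sample.
#' @param aligner backend name (`"short"`/`"long"`).
#' @param index_name name of the reference index used.
#' @param rename,threads,min_chain_score run options echoed in the report.
#' @return object of class `decontam_report`.
#' @export
decontam_report <- function(fastq1, fastq2 = NULL, reads_in, reads_out,
                            reads_removed, aligner, index_name,
                            rename = FALSE, threads = 1L,
                            min_chain_score = 40L) {
  reads_in <- as.double(reads_in)
  reads_out <- as.double(reads_out)
  reads_removed <- as.double(reads_removed)
  if (reads_in != reads_out + reads_removed || reads_out < 0 || reads_removed < 0) {
    hs_conservation(
      "read conservation violated: reads_in (%s) != reads_out (%s) + reads_removed (%s)",
      reads_in, reads_out, reads_removed)
  }
  prop <- if (reads_in == 0) 0 else reads_removed / reads_in
  structure(
    list(
      version = as.character(utils::packageVersion("hostsweep")),
      aligner = aligner,
      aligner_version = binary_version("minimap2"),
      index_name = index_name,
      options = list(rename = rename, threads = as.integer(threads),
                     min_chain_score = as.integer(min_chain_score)),
      fastq1 = fastq1, fastq2 = fastq2,
      reads_in = reads_in, reads_out = reads_out,
      reads_removed = reads_removed,
      reads_removed_proportion = signif(prop, 10L)
    ),
    class = "decontam_report"
  )
}

#' Serialize run reports as JSON
#'
#' A list of reports (one per input sample) is always emitted, even for a
#' single sample; key order is stable and floats carry 10 significant
#' digits, so identical runs serialize byte-identically.
#'
#' @param reports a `decontam_report` or list of them.
#' @param path output file, or `NULL` to write to stdout.
#' @return the JSON string, invisibly.
#' @export
write_report <- function(reports, path = NULL) {
  if (inherits(reports, "decontam_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, TRUE, "decontam_report")))
  for (r in reports) {
    if (r$reads_in != r$reads_out + r$reads_removed) {
      hs_conservation("refusing to write report: conservation violated for %s", r$fastq1)
    }
  }
  payload <- lapply(reports, function(r) {
    r <- unclass(r)
    r$fastq2 <- r$fastq2 %||% NA
    r
  })
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10L,
                           pretty = TRUE, na = "null")
  if (is.null(path)) cat(json, "\n") else writeLines(json, path)
  invisible(as.character(json))
}
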