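# Streaming FASTQ I/O on plain or gzip-compressed files.
#
# Records are handled as plain data.frames with columns id / seq / qual so
# chunks can flow through the filter engine without materializing whole
# files. gzfile() transparently reads both plain and gzip input; output is
# always gzip (zlib writes a fixed header with zero mtime, so re-runs are
# byte-identical).

FASTQ_CHUNK <- 20000L

fastq_connection <- function(path, mode = "rt") {
  if (mode == "rt" && !file.exists(path)) hs_io("cannot open FASTQ file: %s", path)
  gzfile(path, mode)
}

# Read up to n records from an open text connection. Returns NULL at EOF.
fastq_read_chunk <- function(con, n = FASTQ_CHUNK, path = "<fastq>") {
  lines <- readLines(con, n = 4L * n)
  if (length(lines) == 0L) return(NULL)
  if (length(lines) %% 4L != 0L) {
    hs_format("truncated FASTQ record at end of %s (%d trailing lines)",
              path, length(lines) %% 4L)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    hs_format("malformed FASTQ header in %s (record %d does not start with '@')",
              path, bad[[1L]])
  }
  data.frame(
    id = substring(hdr, 2L),
    seq = lines[idx + 1L],
    qual = lines[idx + 3L],
    stringsAsFactors = FALSE
  )
}

#' Read a whole FASTQ file
#'
#' Convenience (non-streaming) reader used by the simulators and tests.
#' @param path FASTQ file, plain or gzip-compressed.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- fastq_connection(path)
  on.exit(close(con))
  out <- list()
  repeat {
    chunk <- fastq_read_chunk(con, path = path)
    if (is.null(chunk)) break
    out[[length(out) + 1L]] <- chunk
  }
  if (length(out) == 0L) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

fastq_write_chunk <- function(con, records) {
  if (nrow(records) == 0L) return(invisible())
  lines <- character(4L * nrow(records))
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", records$id)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- records$seq
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <- records$qual
  writeLines(lines, con)
  invisible()
}

#' Write a FASTQ file
#'
#' @param records data.frame with columns `id`, `seq`, `qual`.
#' @param path output path; written gzip-compressed when it ends in `.gz`,
#'   plain text otherwise.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb", compression = 6L) else file(path, "wb")
  on.exit(close(con))
  fastq_write_chunk(con, records)
  invisible(path)
}

# Count FASTQ records without loading sequences into memory.
count_fastq_records <- function(path) {
  con <- fastq_connection(path)
  on.exit(close(con))
  n <- 0L
  repeat {
    got <- length(readLines(con, n = 4L * FASTQ_CHUNK))
    if (got == 0L) break
    if (got %% 4L != 0L) hs_format("truncated FASTQ record at end of %s", path)
    n <- n + got %/% 4L
  }
  n
}
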