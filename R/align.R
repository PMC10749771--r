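# Aligner backend planning and streaming SAM consumption.
#
# The short backend is minimap2's sr preset and the long backend minimap2's
# map-ont preset; both enforce the minimum chaining score via -m (default
# 40). Secondary alignments are suppressed (--secondary=no) so at most one
# primary alignment per read is reported — the removal decision needs no
# more. argv construction lives in one place (plan_alignment) and is pinned
# by a golden test.

#' Describe an aligner invocation
#'
#' @param backend `"short"` (Illumina, minimap2 sr) or `"long"` (ONT,
#'   minimap2 map-ont).
#' @param index_path path to the index built by [build_index()] (a FASTA
#'   also works; minimap2 indexes on the fly).
#' @param threads worker threads (>= 1). Determinism of output ordering is
#'   only guaranteed with `threads = 1`.
#' @param preset mapping preset for the long backend (default `"map-ont"`).
#' @param min_chain_score minimum chaining score required as host-removal
#'   evidence; default 40, applied to both backends.
#' @param extra_args additional argv tokens appended verbatim.
#' @return an object of class `aligner_spec`.
#' @export
aligner_spec <- function(backend = c("short", "long"), index_path,
                         threads = 1L, preset = "map-ont",
                         min_chain_score = 40L, extra_args = character()) {
  backend <- match.arg(backend)
  threads <- as.integer(threads)
  min_chain_score <- as.integer(min_chain_score)
  if (is.na(threads) || threads < 1L) hs_usage("threads must be >= 1")
  if (is.na(min_chain_score) || min_chain_score < 0L) {
    hs_usage("min_chain_score must be >= 0")
  }
  structure(
    list(backend = backend, index_path = index_path, threads = threads,
         preset = preset, min_chain_score = min_chain_score,
         extra_args = as.character(extra_args)),
    class = "aligner_spec"
  )
}

#' Plan an alignment command
#'
#' Builds the exact argv for the backend, streaming SAM to stdout. Paired
#' input is only valid with the short backend (long-read data are
#' single-end).
#'
#' @param spec an [aligner_spec()].
#' @param fastq1 first (or only) FASTQ path.
#' @param fastq2 optional mate FASTQ path (short backend only).
#' @return an object of class `command_plan` with fields `argv`,
#'   `stdout_contract` (`"SAM stream"`) and `paired`.
#' @export
plan_alignment <- function(spec, fastq1, fastq2 = NULL) {
  stopifnot(inherits(spec, "aligner_spec"))
  if (!is.null(fastq2) && spec$backend == "long") {
    hs_usage("paired FASTQ input is not supported by the long backend")
  }
  if (!file.exists(spec$index_path)) {
    hs_env("aligner index not found: %s (build it with build_index())", spec$index_path)
  }
  preset <- if (spec$backend == "short") "sr" else spec$preset
  argv <- c(
    "minimap2", "-a",
    "-x", preset,
    "-m", as.character(spec$min_chain_score),
    "--secondary=no",
    "-t", as.character(spec$threads),
    spec$extra_args,
    spec$index_path,
    fastq1, fastq2
  )
  structure(
    list(argv = argv, stdout_contract = "SAM stream",
         paired = !is.null(fastq2), spec = spec),
    class = "command_plan"
  )
}

# --- SAM parsing -------------------------------------------------------------

#' Parse SAM alignment lines into removal-relevant records
#'
#' Header lines (`@`-prefixed) are skipped. Each alignment line is reduced
#' to the fields the removal decision needs: query name, flag-derived
#' booleans and the minimap2 chaining-score tag (`s1:i:`), absent for the
#' records that lack it.
#'
#' @param lines character vector of SAM lines.
#' @param first_line_no 1-based number of `lines[1]` in the overall stream,
#'   used in parse-error messages.
#' @return data.frame with columns `qname`, `flag`, `mapped`, `paired`,
#'   `first_mate`, `second_mate`, `secondary`, `supplementary`,
#'   `chain_score`, `target`.
#' @export
parse_sam_lines <- function(lines, first_line_no = 1L) {
  keep <- !startsWith(lines, "@") & nzchar(lines)
  line_no <- first_line_no + which(keep) - 1L
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    i <- which(nf < 11L)[[1L]]
    hs_format("malformed SAM line %d: %d fields (expected >= 11)", line_no[[i]], nf[[i]])
  }
  qname <- vapply(parts, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(flag)) {
    i <- which(is.na(flag))[[1L]]
    hs_format("malformed SAM line %d: non-integer FLAG field", line_no[[i]])
  }
  target <- vapply(parts, `[[`, "", 3L)
  has_s1 <- grepl("\ts1:i:-?[0-9]+", lines)
  chain_score <- rep(NA_integer_, length(lines))
  chain_score[has_s1] <- as.integer(sub(".*\ts1:i:(-?[0-9]+).*", "\\1", lines[has_s1]))
  data.frame(
    qname = qname,
    flag = flag,
    mapped = bitwAnd(flag, 4L) == 0L,
    paired = bitwAnd(flag, 1L) > 0L,
    first_mate = bitwAnd(flag, 64L) > 0L,
    second_mate = bitwAnd(flag, 128L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    chain_score = chain_score,
    target = ifelse(bitwAnd(flag, 4L) == 0L, target, NA_character_),
    stringsAsFactors = FALSE
  )
}

empty_alignments <- function() {
  data.frame(
    qname = character(), flag = integer(), mapped = logical(),
    paired = logical(), first_mate = logical(), second_mate = logical(),
    secondary = logical(), supplementary = logical(),
    chain_score = integer(), target = character(),
    stringsAsFactors = FALSE
  )
}

# --- SAM sources -------------------------------------------------------------
# A sam_source yields raw SAM lines chunk by chunk so downstream consumers
# keep bounded memory. Sources: a live aligner subprocess, a SAM file
# (--offline-sam), or an in-memory character vector (tests).

SAM_CHUNK_LINES <- 100000L

sam_source_connection <- function(con, name, finalize = NULL) {
  line_no <- 0L
  closed <- FALSE
  list(
    name = name,
    read_lines = function(n = SAM_CHUNK_LINES) {
      lines <- readLines(con, n = n)
      if (length(lines) == 0L) return(NULL)
      first <- line_no + 1L
      line_no <<- line_no + length(lines)
      attr(lines, "first_line_no") <- first
      lines
    },
    close = function() {
      if (closed) return(invisible())
      closed <<- TRUE
      status <- withCallingHandlers(
        close(con),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (!is.null(finalize)) finalize(status)
      invisible()
    }
  )
}

sam_source_lines <- function(lines) {
  served <- FALSE
  list(
    name = "<in-memory SAM>",
    read_lines = function(n = SAM_CHUNK_LINES) {
      if (served || length(lines) == 0L) return(NULL)
      served <<- TRUE
      attr(lines, "first_line_no") <- 1L
      lines
    },
    close = function() invisible()
  )
}

as_sam_source <- function(sam) {
  if (is.list(sam) && all(c("read_lines", "close") %in% names(sam))) return(sam)
  if (inherits(sam, "connection")) return(sam_source_connection(sam, "<connection>"))
  if (is.character(sam) && length(sam) == 1L && file.exists(sam)) {
    return(sam_source_connection(gzfile(sam, "rt"), sam))
  }
  if (is.character(sam)) return(sam_source_lines(sam))
  hs_usage("cannot interpret SAM input of class %s", class(sam)[[1L]])
}

#' Run a planned alignment, streaming parsed records
#'
#' Launches the backend subprocess and returns a streaming source of SAM
#' lines; the full SAM never touches disk or memory at once. The subprocess
#' exit status is checked when the stream is closed, and a nonzero status
#' raises a pipeline error carrying the tail of the backend's stderr.
#'
#' @param plan a [plan_alignment()] result.
#' @return a `sam_source` (list with `read_lines(n)` and `close()`)
#'   consumable by [decide_reads()].
#' @export
run_alignment <- function(plan) {
  stopifnot(inherits(plan, "command_plan"))
  bin <- plan$argv[[1L]]
  if (!nzchar(Sys.which(bin))) {
    hs_env("aligner binary '%s' not found on PATH", bin)
  }
  errfile <- tempfile("aligner_stderr_")
  cmd <- paste(c(vapply(plan$argv, shQuote, ""), "2>", shQuote(errfile)),
               collapse = " ")
  con <- pipe(cmd, "rt")
  finalize <- function(status) {
    status <- if (is.null(status)) 0L else as.integer(status)
    if (!is.na(status) && status != 0L) {
      tail_err <- tryCatch(utils::tail(readLines(errfile, warn = FALSE), 10L),
                           error = function(e) character())
      unlink(errfile)
      hs_abort("hs_pipeline_error", "aligner exited with status %d: %s",
               status, paste(tail_err, collapse = " | "))
    }
    unlink(errfile)
  }
  sam_source_connection(con, paste(plan$argv, collapse = " "), finalize)
}

#' Collect all alignment records from a SAM input
#'
#' Non-streaming convenience used by tests and oracles.
#' @param sam a path, character vector of lines, connection or sam_source.
#' @return data.frame of parsed records (see [parse_sam_lines()]).
#' @export
collect_alignments <- function(sam) {
  src <- as_sam_source(sam)
  on.exit(src$close())
  out <- list()
  repeat {
    lines <- src$read_lines()
    if (is.null(lines)) break
    out[[length(out) + 1L]] <- parse_sam_lines(lines, attr(lines, "first_line_no") %||% 1L)
  }
  if (length(out) == 0L) return(empty_alignments())
  do.call(rbind, out)
}
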