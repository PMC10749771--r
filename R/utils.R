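# Internal helpers: classed errors, id handling, reverse complement.

`%||%` <- function(x, y) if (is.null(x)) y else x

# data.table is used via :: only; opt in to data.table semantics.
.datatable.aware <- TRUE

#' @noRd
hs_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "hs_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

hs_usage <- function(msg, ...) hs_abort("hs_usage_error", msg, ...)
hs_env <- function(msg, ...) hs_abort("hs_environment_error", msg, ...)
hs_format <- function(msg, ...) hs_abort("hs_format_error", msg, ...)
hs_conservation <- function(msg, ...) hs_abort("hs_conservation_error", msg, ...)
hs_validation <- function(msg, ...) hs_abort("hs_validation_error", msg, ...)
hs_io <- function(msg, ...) hs_abort("hs_io_error", msg, ...)

#' Strip mate suffix / comment from a read id
#'
#' Drops everything after the first whitespace, then a trailing `/1` or `/2`
#' mate tag, yielding the id shared by both mates of a pair.
#' @param ids character vector of FASTQ read ids (without the leading `@`).
#' @return character vector of base ids.
#' @export
base_read_id <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

# Reverse complement for plain character vectors (A/C/G/T/N, case preserved
# via uppercase-only simulator output).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Version string of an external binary, or NA if unavailable.
binary_version <- function(bin) {
  if (!nzchar(Sys.which(bin))) return(NA_character_)
  out <- tryCatch(
    suppressWarnings(system2(bin, "--version", stdout = TRUE, stderr = TRUE)),
    error = function(e) NA_character_
  )
  if (length(out) == 0) NA_character_ else out[[1]]
}
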