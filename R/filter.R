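# The filter engine: classify alignment records, reduce them to one removal
# decision per read (pair-aware), and apply decisions to the FASTQ input in
# a single streaming pass.
#
# Subtractive semantics: only positive host evidence removes a read. Reads
# present in the FASTQ but absent from the SAM stream are kept.

#' Classify alignment records as host-removal evidence
#'
#' A record is removal evidence iff it is mapped and, for the long backend,
#' its chaining score (`s1` tag) meets the spec's minimum. A mapped long
#' record with no score tag is treated as evidence (fail-safe toward
#' removal; the threshold is enforced at invocation anyway). Secondary and
#' supplementary records are classified like any other; they contribute to
#' the per-read decision by logical OR in [decide_reads()].
#'
#' @param aln data.frame of parsed records ([parse_sam_lines()]); vectorized.
#' @param spec an [aligner_spec()].
#' @return logical vector, `TRUE` where the record supports removal.
#' @export
classify_alignment <- function(aln, spec) {
  stopifnot(inherits(spec, "aligner_spec"))
  if (nrow(aln) == 0L) return(logical())
  if (spec$backend == "short") {
    aln$mapped
  } else {
    aln$mapped & (is.na(aln$chain_score) | aln$chain_score >= spec$min_chain_score)
  }
}

# mate code: 0 = unpaired, 1/2 = mate flags
mate_code <- function(aln) {
  ifelse(aln$first_mate, 1L, ifelse(aln$second_mate, 2L, 0L))
}

#' Decide which reads to remove from an alignment stream
#'
#' Streams alignment records and produces one removal decision per distinct
#' read unit. In paired mode the unit is the read pair (ids matched after
#' stripping mate tags): if either mate has removal evidence both mates are
#' removed, the evidence-free mate with reason `mate_aligned`. Multiple
#' records per read (secondary, supplementary) OR together.
#'
#' @param alns SAM input: a path, character vector of SAM lines, connection
#'   or the source returned by [run_alignment()].
#' @param spec an [aligner_spec()].
#' @param paired logical; paired mode requires every record to carry a mate
#'   flag.
#' @return object of class `removal_decisions`: list with `decisions` (a
#'   data.frame `read_id`, `mate`, `remove`, `reason`), `removed_ids`
#'   (character vector of read/pair ids to drop) and `n_distinct_units`
#'   (distinct (read, mate) pairs observed in the stream).
#' @export
decide_reads <- function(alns, spec, paired = FALSE) {
  stopifnot(inherits(spec, "aligner_spec"))
  src <- as_sam_source(alns)
  on.exit(src$close(), add = TRUE)  # no-op after a normal close
  acc <- list()
  repeat {
    lines <- src$read_lines()
    if (is.null(lines)) break
    aln <- parse_sam_lines(lines, attr(lines, "first_line_no") %||% 1L)
    if (nrow(aln) == 0L) next
    if (paired && any(!aln$first_mate & !aln$second_mate)) {
      bad <- aln$qname[which(!aln$first_mate & !aln$second_mate)[[1L]]]
      src$close()
      hs_format("paired mode: record for read '%s' carries neither mate flag", bad)
    }
    dt <- data.table::data.table(
      read_id = base_read_id(aln$qname),
      mate = mate_code(aln),
      hit = classify_alignment(aln, spec)
    )
    acc[[length(acc) + 1L]] <- dt[, list(hit = any(hit)), by = c("read_id", "mate")]
  }
  src$close()

  if (length(acc) == 0L) {
    units <- data.table::data.table(read_id = character(), mate = integer(),
                                    hit = logical())
  } else {
    units <- data.table::rbindlist(acc)[, list(hit = any(hit)),
                                        by = c("read_id", "mate")]
  }
  data.table::setorderv(units, c("read_id", "mate"))

  if (paired) {
    pair_hit <- units[, list(any_hit = any(hit)), by = "read_id"]
    units <- merge(units, pair_hit, by = "read_id", sort = FALSE)
    remove <- units$any_hit
    reason <- ifelse(!remove, "none",
                     ifelse(units$hit, "self_aligned", "mate_aligned"))
  } else {
    remove <- units$hit
    reason <- ifelse(remove, "self_aligned", "none")
  }
  decisions <- data.frame(
    read_id = units$read_id, mate = units$mate,
    remove = remove, reason = reason, stringsAsFactors = FALSE
  )
  structure(
    list(decisions = decisions,
         removed_ids = unique(decisions$read_id[decisions$remove]),
         n_distinct_units = nrow(units)),
    class = "removal_decisions"
  )
}

removed_id_set <- function(decisions) {
  if (inherits(decisions, "removal_decisions")) return(decisions$removed_ids)
  if (is.character(decisions)) return(unique(decisions))
  if (is.data.frame(decisions)) {
    return(unique(decisions$read_id[decisions$remove]))
  }
  hs_usage("cannot interpret decisions of class %s", class(decisions)[[1L]])
}

#' Rename reads with incrementing integers
#'
#' Kept read (or pair) k gets the id `start + k - 1`; mates of a pair share
#' the integer and any `/1` `/2` suffix is dropped. Sequences and qualities
#' are untouched.
#'
#' @param reads a FASTQ record data.frame, or a list of two such
#'   data.frames for paired input (positionally matched mates).
#' @param start first integer id (default 1).
#' @return same shape as `reads`, with renamed ids.
#' @export
rename_reads <- function(reads, start = 1L) {
  if (is.data.frame(reads)) {
    if (nrow(reads)) reads$id <- as.character(seq(start, length.out = nrow(reads)))
    return(reads)
  }
  stopifnot(is.list(reads), length(reads) == 2L)
  n1 <- nrow(reads[[1L]]); n2 <- nrow(reads[[2L]])
  if (n1 != n2) hs_format("paired rename: %d vs %d records", n1, n2)
  ids <- as.character(seq(start, length.out = n1))
  if (n1) {
    reads[[1L]]$id <- ids
    reads[[2L]]$id <- ids
  }
  reads
}

clean_output_name <- function(fastq, out_dir, mate = 0L) {
  stem <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  suffix <- switch(as.character(mate),
                   "0" = ".clean.fastq.gz",
                   "1" = ".clean_1.fastq.gz",
                   "2" = ".clean_2.fastq.gz")
  file.path(out_dir, paste0(stem, suffix))
}

#' Apply removal decisions to FASTQ input
#'
#' Streams the input FASTQ(s) chunk by chunk, drops reads (and their mates)
#' whose id is in the removal set, optionally renames survivors with
#' incrementing integers, and writes gzip-compressed output. Input order is
#' preserved among kept reads; paired outputs always have equal record
#' counts with positionally matching ids.
#'
#' @param in1,in2 input FASTQ path(s); `in2 = NULL` for single-end.
#' @param decisions a [decide_reads()] result (or a character vector of
#'   read/pair ids to remove).
#' @param rename replace read names with incrementing integers.
#' @param out1,out2 output paths (gzip); defaults derived from the inputs.
#' @param out_dir directory for default output names.
#' @param rename_map_path optional TSV path recording original -> new ids.
#' @param chunk_size records per streamed chunk.
#' @return list of per-file and total counts: `reads_in`, `reads_out`,
#'   `reads_removed` (each a vector with one element per input file plus
#'   names), plus `out1`/`out2` paths.
#' @export
apply_decisions <- function(in1, in2 = NULL, decisions = character(),
                            rename = FALSE, out1 = NULL, out2 = NULL,
                            out_dir = dirname(in1), rename_map_path = NULL,
                            chunk_size = FASTQ_CHUNK) {
  paired <- !is.null(in2)
  removed <- removed_id_set(decisions)
  out1 <- out1 %||% clean_output_name(in1, out_dir, if (paired) 1L else 0L)
  out2 <- if (paired) out2 %||% clean_output_name(in2, out_dir, 2L) else NULL

  con_in1 <- fastq_connection(in1)
  con_out1 <- gzfile(out1, "wb", compression = 6L)
  on.exit({ close(con_in1); close(con_out1) }, add = TRUE)
  if (paired) {
    con_in2 <- fastq_connection(in2)
    con_out2 <- gzfile(out2, "wb", compression = 6L)
    on.exit({ close(con_in2); close(con_out2) }, add = TRUE)
  }
  map_con <- NULL
  if (!is.null(rename_map_path)) {
    map_con <- file(rename_map_path, "wt")
    on.exit(close(map_con), add = TRUE)
    writeLines("original_id\tnew_id", map_con)
  }

  n_in <- 0L; n_out <- 0L
  next_id <- 1L
  pos <- 0L
  repeat {
    c1 <- fastq_read_chunk(con_in1, chunk_size, in1)
    c2 <- if (paired) fastq_read_chunk(con_in2, chunk_size, in2) else NULL
    if (is.null(c1) && (!paired || is.null(c2))) break
    if (paired) {
      n1 <- if (is.null(c1)) 0L else nrow(c1)
      n2 <- if (is.null(c2)) 0L else nrow(c2)
      if (n1 != n2) {
        shorter <- if (n1 < n2) in1 else in2
        hs_format("paired FASTQ inputs have unequal lengths; %s ends first", shorter)
      }
      b1 <- base_read_id(c1$id)
      b2 <- base_read_id(c2$id)
      mism <- which(b1 != b2)
      if (length(mism)) {
        hs_format("read id mismatch at record %d: '%s' vs '%s'",
                  pos + mism[[1L]], c1$id[[mism[[1L]]]], c2$id[[mism[[1L]]]])
      }
      keep <- !(b1 %in% removed)
    } else {
      keep <- !(base_read_id(c1$id) %in% removed)
    }
    pos <- pos + nrow(c1)
    n_in <- n_in + nrow(c1)
    k1 <- c1[keep, , drop = FALSE]
    k2 <- if (paired) c2[keep, , drop = FALSE] else NULL
    if (rename && nrow(k1)) {
      new_ids <- as.character(seq(next_id, length.out = nrow(k1)))
      if (!is.null(map_con)) {
        writeLines(paste0(base_read_id(k1$id), "\t", new_ids), map_con)
      }
      k1$id <- new_ids
      if (paired) k2$id <- new_ids
      next_id <- next_id + nrow(k1)
    }
    n_out <- n_out + nrow(k1)
    fastq_write_chunk(con_out1, k1)
    if (paired) fastq_write_chunk(con_out2, k2)
  }

  per_file_in <- if (paired) c(n_in, n_in) else n_in
  per_file_out <- if (paired) c(n_out, n_out) else n_out
  files <- if (paired) c(in1, in2) else in1
  list(
    files = files,
    reads_in = stats::setNames(per_file_in, files),
    reads_out = stats::setNames(per_file_out, files),
    reads_removed = stats::setNames(per_file_in - per_file_out, files),
    total_in = sum(per_file_in), total_out = sum(per_file_out),
    total_removed = sum(per_file_in) - sum(per_file_out),
    out1 = out1, out2 = out2
  )
}
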