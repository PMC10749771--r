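# Reference database handling: construction, microbe-masking and aligner
# index building.

#' Describe a host reference database
#'
#' A lightweight record tying a database name to its FASTA file and, for
#' masked databases, the BED file of hard-masked intervals. Names follow the
#' convention of the default (`human-t2t-hla`) and masked
#' (`human-t2t-hla-argos985-mycob140`) databases: short, filesystem-safe
#' identifiers used to derive index file names.
#'
#' @param name short identifier; must contain no whitespace or path
#'   separators.
#' @param fasta_path path to the reference FASTA (plain or gzip).
#' @param masked logical; `TRUE` iff the FASTA was hard-masked and
#'   `mask_bed_path` records the masked intervals.
#' @param mask_bed_path path to a 3-column BED of masked intervals; required
#'   when `masked = TRUE`.
#' @return an object of class `reference_db`.
#' @export
reference_db <- function(name, fasta_path, masked = FALSE, mask_bed_path = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      grepl("[/\\\\[:space:]]", name)) {
    hs_validation("reference name must be a non-empty, filesystem-safe string: %s",
                  deparse(name))
  }
  if (isTRUE(masked) && is.null(mask_bed_path)) {
    hs_validation("a masked reference requires mask_bed_path")
  }
  structure(
    list(name = name, fasta_path = fasta_path, masked = isTRUE(masked),
         mask_bed_path = mask_bed_path),
    class = "reference_db"
  )
}

as_mask_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(x), all(c("seq_id", "start", "end") %in% names(x)))
  data.frame(seq_id = as.character(x$seq_id), start = as.integer(x$start),
             end = as.integer(x$end), stringsAsFactors = FALSE)
}

#' Merge mask intervals
#'
#' Sorts 0-based half-open intervals by (sequence, start) and merges
#' overlapping or bookended intervals on the same sequence, preserving the
#' union of covered bases exactly.
#'
#' @param intervals data.frame with columns `seq_id`, `start` (0-based
#'   inclusive), `end` (exclusive).
#' @return data.frame of disjoint sorted intervals with the same columns.
#' @export
merge_intervals <- function(intervals) {
  intervals <- as_mask_intervals(intervals)
  if (nrow(intervals) == 0L) return(intervals)
  bad <- which(!(intervals$start >= 0L & intervals$start < intervals$end))
  if (length(bad)) {
    b <- intervals[bad[[1L]], ]
    hs_validation("invalid mask interval %s:[%d,%d): start must satisfy 0 <= start < end",
                  b$seq_id, b$start, b$end)
  }
  gr <- GenomicRanges::GRanges(
    intervals$seq_id,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  out[order(out$seq_id, out$start), , drop = FALSE]
}

write_bed <- function(intervals, path) {
  intervals <- as_mask_intervals(intervals)
  data.table::fwrite(intervals, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("seq_id", "start", "end"))
  as_mask_intervals(as.data.frame(dt))
}

# --- similarity search routes ------------------------------------------------

# Exact shared-substring route: host positions whose 31-mer occurs in any
# microbe genome (either strand) are collected; runs of consecutive shared
# seeds spanning >= min_match_length bases become intervals. Needs no
# external binary; min_identity does not apply (matches are exact).
kmer_mask_intervals <- function(host, microbes, min_match_length) {
  k <- 31L
  if (min_match_length < k) {
    hs_validation("k-mer masking requires min_match_length >= %d", k)
  }
  micro_seqs <- unlist(lapply(microbes, function(s) c(s, revcomp_chr(s))))
  micro_kmers <- unique(unlist(lapply(micro_seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  })))
  out <- list()
  for (i in seq_along(host)) {
    s <- host[[i]]
    n <- nchar(s)
    if (n < k || length(micro_kmers) == 0L) next
    host_kmers <- substring(s, 1:(n - k + 1L), k:n)
    shared <- host_kmers %in% micro_kmers
    r <- rle(shared)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (j in hit) {
      covered <- r$lengths[[j]] + k - 1L
      if (covered >= min_match_length) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = names(host)[[i]],
          start = starts[[j]] - 1L,
          end = ends[[j]] + k - 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) return(as_mask_intervals(NULL))
  do.call(rbind, out)
}

# Genome-to-genome route: align microbe genomes (queries) against the host
# (target) with minimap2's assembly preset and harvest host-coordinate PAF
# hits above the length/identity thresholds.
minimap2_mask_intervals <- function(host_fasta, microbe_fastas,
                                    min_match_length, min_identity) {
  if (!nzchar(Sys.which("minimap2"))) {
    hs_env("minimap2 not found on PATH; install it or use method = \"kmer\"")
  }
  errfile <- tempfile("mm2_mask_err_")
  on.exit(unlink(errfile), add = TRUE)
  out <- suppressWarnings(system2(
    "minimap2",
    c("-x", "asm20", "-t", "1", shQuote(host_fasta), vapply(microbe_fastas, shQuote, "")),
    stdout = TRUE, stderr = errfile
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    tail_err <- utils::tail(readLines(errfile, warn = FALSE), 5L)
    hs_abort("hs_pipeline_error", "minimap2 masking search failed (exit %d): %s",
             status, paste(tail_err, collapse = " | "))
  }
  if (length(out) == 0L) return(as_mask_intervals(NULL))
  f <- data.table::fread(text = out, header = FALSE, sep = "\t", fill = TRUE)
  # PAF: V6 target name, V8/V9 target start/end (0-based half-open),
  # V10 matching bases, V11 alignment block length
  keep <- f$V11 >= min_match_length & (f$V10 / f$V11) >= min_identity
  f <- f[keep]
  as_mask_intervals(data.frame(seq_id = f$V6, start = f$V8, end = f$V9))
}

#' Hard-mask a host reference against microbe genomes
#'
#' Finds host regions locally similar to any genome in a microbe panel and
#' replaces them with `N`, producing the masked FASTA and a BED file of
#' masked intervals. This is the utility behind masked databases, which
#' prevent microbial reads from being removed as false-positive host hits.
#'
#' Two similarity-search routes are available: `"minimap2"` runs a
#' genome-to-genome alignment (asm20 preset) and keeps hits with block
#' length `>= min_match_length` and identity `>= min_identity`; `"kmer"` is
#' an exact shared-31-mer fallback needing no external binary (identity is
#' then 1 by construction). `"auto"` uses minimap2 when present.
#'
#' @param host_fasta path to the host reference FASTA.
#' @param microbe_fastas character vector of microbe genome FASTA paths; may
#'   be empty, in which case nothing is masked.
#' @param min_match_length minimum similar-region length in bp (default 100).
#' @param min_identity minimum alignment identity fraction (default 0.80).
#' @param out_fasta,out_bed output paths; defaults are derived from
#'   `host_fasta`.
#' @param method similarity-search route, see Details.
#' @return list with elements `fasta`, `bed`, `intervals` (merged
#'   data.frame) and `masked_bases`.
#' @export
mask_reference <- function(host_fasta, microbe_fastas = character(),
                           min_match_length = 100L, min_identity = 0.80,
                           out_fasta = NULL, out_bed = NULL,
                           method = c("auto", "minimap2", "kmer")) {
  method <- match.arg(method)
  if (!file.exists(host_fasta)) hs_io("host FASTA not found: %s", host_fasta)
  host_set <- tryCatch(Biostrings::readDNAStringSet(host_fasta),
                       error = function(e) hs_io("unreadable host FASTA %s: %s",
                                                 host_fasta, conditionMessage(e)))
  if (length(host_set) == 0L) hs_validation("host FASTA contains no sequences: %s", host_fasta)
  if (any(Biostrings::width(host_set) == 0L)) {
    hs_validation("host FASTA contains an empty sequence: %s",
                  names(host_set)[Biostrings::width(host_set) == 0L][[1L]])
  }
  names(host_set) <- sub("\\s.*$", "", names(host_set))
  stem <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", host_fasta)
  out_fasta <- out_fasta %||% paste0(stem, ".masked.fa")
  out_bed <- out_bed %||% paste0(stem, ".mask.bed")

  if (length(microbe_fastas) == 0L) {
    intervals <- as_mask_intervals(NULL)
  } else {
    missing_fa <- microbe_fastas[!file.exists(microbe_fastas)]
    if (length(missing_fa)) hs_io("microbe FASTA not found: %s", missing_fa[[1L]])
    if (method == "auto") {
      method <- if (nzchar(Sys.which("minimap2"))) "minimap2" else "kmer"
    }
    intervals <- if (method == "minimap2") {
      minimap2_mask_intervals(host_fasta, microbe_fastas, min_match_length, min_identity)
    } else {
      microbes <- unlist(lapply(microbe_fastas, function(p) {
        as.character(Biostrings::readDNAStringSet(p))
      }))
      kmer_mask_intervals(as.character(host_set), microbes, min_match_length)
    }
    unknown <- setdiff(unique(intervals$seq_id), names(host_set))
    if (length(unknown)) hs_format("mask interval on unknown sequence: %s", unknown[[1L]])
  }
  intervals <- merge_intervals(intervals)

  masked_set <- host_set
  for (sid in unique(intervals$seq_id)) {
    iv <- intervals[intervals$seq_id == sid, , drop = FALSE]
    at <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    masked_set[[sid]] <- Biostrings::replaceAt(
      host_set[[sid]], at,
      Biostrings::DNAStringSet(strrep("N", iv$end - iv$start))
    )
  }
  stopifnot(identical(Biostrings::width(masked_set), Biostrings::width(host_set)))
  Biostrings::writeXStringSet(masked_set, out_fasta, width = 60L)
  write_bed(intervals, out_bed)
  list(fasta = out_fasta, bed = out_bed, intervals = intervals,
       masked_bases = sum(intervals$end - intervals$start))
}

index_extension <- function(backend) {
  switch(backend, short = "sr.mmi", long = "map-ont.mmi",
         hs_usage("unknown backend: %s", backend))
}

#' Build an aligner index for a reference database
#'
#' Creates a minimap2 index under a deterministic name,
#' `<db name>.<preset>.mmi`, next to the FASTA (or in `out_dir`). A sidecar
#' `.src.md5` file records the FASTA checksum so rebuilding with an
#' unchanged FASTA is a no-op and a changed or deleted FASTA is detected as
#' a stale index.
#'
#' @param db a [reference_db()] object (or a FASTA path, from which a db is
#'   derived).
#' @param backend `"short"` (sr preset) or `"long"` (map-ont preset).
#' @param out_dir directory for the index; defaults to the FASTA's.
#' @return path to the index file.
#' @export
build_index <- function(db, backend = c("short", "long"), out_dir = NULL) {
  backend <- match.arg(backend)
  if (is.character(db)) {
    db <- reference_db(sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(db)), db)
  }
  stopifnot(inherits(db, "reference_db"))
  if (!file.exists(db$fasta_path)) hs_io("reference FASTA not found: %s", db$fasta_path)
  if (!nzchar(Sys.which("minimap2"))) {
    hs_env("minimap2 not found on PATH; install minimap2 to build %s indexes", backend)
  }
  out_dir <- out_dir %||% dirname(db$fasta_path)
  idx <- file.path(out_dir, paste0(db$name, ".", index_extension(backend)))
  sidecar <- paste0(idx, ".src.md5")
  md5 <- unname(tools::md5sum(db$fasta_path))
  if (file.exists(idx) && file.exists(sidecar) &&
      identical(readLines(sidecar, warn = FALSE)[[1L]], md5)) {
    return(idx)
  }
  preset <- if (backend == "short") "sr" else "map-ont"
  errfile <- tempfile("mm2_index_err_")
  on.exit(unlink(errfile), add = TRUE)
  status <- suppressWarnings(system2(
    "minimap2", c("-x", preset, "-d", shQuote(idx), shQuote(db$fasta_path)),
    stdout = FALSE, stderr = errfile
  ))
  if (status != 0L) {
    hs_abort("hs_pipeline_error", "minimap2 indexing failed (exit %d): %s", status,
             paste(utils::tail(readLines(errfile, warn = FALSE), 5L), collapse = " | "))
  }
  writeLines(md5, sidecar)
  idx
}

#' Check that an index is still backed by its source FASTA
#'
#' @param index_path path returned by [build_index()].
#' @param fasta_path the FASTA the index was built from.
#' @return `TRUE` invisibly; signals a stale-index error otherwise.
#' @export
validate_index <- function(index_path, fasta_path) {
  if (!file.exists(index_path)) hs_env("index not found: %s", index_path)
  sidecar <- paste0(index_path, ".src.md5")
  if (!file.exists(fasta_path)) {
    hs_abort("hs_stale_index_error", "source FASTA for index %s is missing: %s",
             index_path, fasta_path)
  }
  if (file.exists(sidecar) &&
      !identical(readLines(sidecar, warn = FALSE)[[1L]],
                 unname(tools::md5sum(fasta_path)))) {
    hs_abort("hs_stale_index_error",
             "index %s is stale: source FASTA checksum changed", index_path)
  }
  invisible(TRUE)
}
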