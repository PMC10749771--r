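# End-to-end decontamination: plan alignment -> stream SAM -> decide ->
# apply -> report, without ever writing an uncompressed FASTQ intermediate.

#' Decontaminate FASTQ reads against a host reference
#'
#' Runs the full subtractive-removal pipeline: reads are aligned to the
#' host index (short backend for Illumina, long backend for ONT), every
#' read with qualifying host evidence is removed — for paired data together
#' with its mate — survivors are optionally renamed with incrementing
#' integers, and gzip-compressed FASTQ plus a JSON accounting report are
#' written. The SAM stream is consumed incrementally and input FASTQ is
#' re-read in chunks, so no uncompressed intermediate ever touches disk.
#'
#' @param fastq1 input FASTQ (plain or gzip).
#' @param fastq2 optional mate FASTQ; implies the short backend layout.
#' @param index aligner index from [build_index()] (or a reference FASTA).
#' @param aligner `"short"` or `"long"`.
#' @param rename replace read names with incrementing integers (mates share
#'   the integer).
#' @param threads aligner threads; use 1 for byte-deterministic output.
#' @param out_dir output directory.
#' @param min_chain_score minimum chaining score counted as host evidence.
#' @param offline_sam optional pre-computed SAM path/lines used instead of
#'   running an aligner (hermetic testing and re-analysis).
#' @param report_path JSON report destination; `NULL` prints to stdout.
#' @param rename_map_path optional TSV mapping original to new read ids.
#' @return invisibly, a list with `out1`, `out2`, `counts`, `report`,
#'   `decisions`.
#' @export
clean <- function(fastq1, fastq2 = NULL, index = NULL,
                  aligner = c("short", "long"), rename = FALSE,
                  threads = 1L, out_dir = ".", min_chain_score = 40L,
                  offline_sam = NULL, report_path = NULL,
                  rename_map_path = NULL) {
  aligner <- match.arg(aligner)
  if (!file.exists(fastq1)) hs_usage("fastq1 not found: %s", fastq1)
  if (!is.null(fastq2) && !file.exists(fastq2)) hs_usage("fastq2 not found: %s", fastq2)
  if (!is.null(fastq2) && aligner == "long") {
    hs_usage("paired input requires the short backend")
  }
  if (is.null(index) && is.null(offline_sam)) {
    hs_usage("either an index or --offline-sam must be provided")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paired <- !is.null(fastq2)

  spec <- aligner_spec(aligner, index_path = index %||% "<offline>",
                       threads = threads, min_chain_score = min_chain_score)
  sam <- if (!is.null(offline_sam)) {
    offline_sam
  } else {
    run_alignment(plan_alignment(spec, fastq1, fastq2))
  }
  decisions <- decide_reads(sam, spec, paired = paired)

  counts <- apply_decisions(
    in1 = fastq1, in2 = fastq2, decisions = decisions, rename = rename,
    out_dir = out_dir, rename_map_path = rename_map_path
  )

  index_name <- if (is.null(index)) "offline-sam" else
    sub("\\.(sr|map-ont)\\.mmi$", "", basename(index))
  report <- decontam_report(
    fastq1 = fastq1, fastq2 = fastq2,
    reads_in = counts$total_in, reads_out = counts$total_out,
    reads_removed = counts$total_removed,
    aligner = aligner, index_name = index_name, rename = rename,
    threads = threads, min_chain_score = min_chain_score
  )
  write_report(report, report_path)
  invisible(list(out1 = counts$out1, out2 = counts$out2, counts = counts,
                 report = report, decisions = decisions))
}
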