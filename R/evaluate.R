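# Truth-based accuracy metrics: retention/removal percentages by truth
# class, run-to-run comparison, and the viral (EBV-style) subtraction
# adjustment of host-retention figures.

as_truth_table <- function(truth) {
  if (is.character(truth) && length(truth) == 1L && file.exists(truth)) {
    truth <- as.data.frame(data.table::fread(truth, sep = "\t", header = TRUE))
  }
  if (!is.data.frame(truth) || !all(c("read_id", "truth") %in% names(truth))) {
    hs_usage("truth must be a TSV path or data.frame with columns read_id, truth")
  }
  truth
}

output_unit_ids <- function(fastq1, fastq2 = NULL, id_map = NULL) {
  ids <- base_read_id(read_fastq(fastq1)$id)
  if (!is.null(fastq2)) {
    ids2 <- base_read_id(read_fastq(fastq2)$id)
    if (length(ids) != length(ids2)) {
      hs_format("paired outputs have unequal record counts (%d vs %d)",
                length(ids), length(ids2))
    }
  }
  if (!is.null(id_map)) {
    if (is.character(id_map)) {
      id_map <- as.data.frame(data.table::fread(id_map, sep = "\t", header = TRUE))
    }
    m <- match(ids, as.character(id_map$new_id))
    if (anyNA(m)) hs_format("renamed output id missing from id map: %s",
                            ids[which(is.na(m))[[1L]]])
    ids <- id_map$original_id[m]
  }
  ids
}

#' Score read retention against a truth table
#'
#' Counts, per truth class, how many input read units (reads, or pairs for
#' paired data) survived decontamination, and reports class retention
#' percentages. Percentages carry full precision and are formatted to 6
#' significant figures only for display — benchmark-level differences live
#' in the 5th decimal.
#'
#' @param truth truth table: TSV path or data.frame with columns `read_id`
#'   (one row per read/pair) and `truth` (`host`/`microbe`/`viral`).
#' @param fastq1,fastq2 decontaminated output FASTQ(s).
#' @param id_map optional sidecar TSV (from [apply_decisions()]) mapping
#'   original to renamed ids, consulted when outputs were renamed.
#' @return object of class `retention_metrics`: per-class `n_in` /
#'   `n_retained` counts and `retention` percentages, plus convenience
#'   fields `n_host_in`, `n_host_retained`, `host_retention`,
#'   `n_microbe_in`, `n_microbe_retained`, `microbe_retention`.
#' @export
score_retention <- function(truth, fastq1, fastq2 = NULL, id_map = NULL) {
  truth <- as_truth_table(truth)
  ids <- output_unit_ids(fastq1, fastq2, id_map)
  unknown <- setdiff(ids, truth$read_id)
  if (length(unknown)) {
    hs_abort("hs_data_integrity_error",
             "%d output read(s) absent from truth table; first offenders: %s",
             length(unknown), paste(utils::head(unknown, 10L), collapse = ", "))
  }
  classes <- sort(unique(truth$truth))
  retained_tab <- table(factor(truth$truth[match(ids, truth$read_id)], levels = classes))
  in_tab <- table(factor(truth$truth, levels = classes))
  n_in <- as.integer(in_tab)
  n_ret <- as.integer(retained_tab)
  names(n_in) <- names(n_ret) <- classes
  retention <- ifelse(n_in > 0L, 100 * n_ret / n_in, NA_real_)
  out <- list(
    classes = classes, n_in = n_in, n_retained = n_ret, retention = retention,
    n_host_in = unname(n_in["host"]) %|NA|% 0L,
    n_host_retained = unname(n_ret["host"]) %|NA|% 0L,
    n_microbe_in = unname(n_in["microbe"]) %|NA|% 0L,
    n_microbe_retained = unname(n_ret["microbe"]) %|NA|% 0L
  )
  out$host_retention <- if (out$n_host_in > 0) 100 * out$n_host_retained / out$n_host_in else NA_real_
  out$microbe_retention <- if (out$n_microbe_in > 0) 100 * out$n_microbe_retained / out$n_microbe_in else NA_real_
  structure(out, class = "retention_metrics")
}

`%|NA|%` <- function(x, y) if (length(x) == 0L || is.na(x)) y else x

#' @export
print.retention_metrics <- function(x, ...) {
  cat("Retention metrics (read units)\n")
  for (i in seq_along(x$classes)) {
    cat(sprintf("  %-8s %d / %d retained (%s%%)\n", x$classes[[i]],
                x$n_retained[[i]], x$n_in[[i]], signif(x$retention[[i]], 6L)))
  }
  invisible(x)
}

#' Aggregate retention metrics across samples
#'
#' Sums numerators and denominators before dividing (never mean-of-means),
#' matching how multi-sample retention percentages are reported.
#'
#' @param metrics_list list of `retention_metrics`.
#' @return a single `retention_metrics` over the pooled counts.
#' @export
aggregate_retention <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1L,
            all(vapply(metrics_list, inherits, TRUE, "retention_metrics")))
  classes <- sort(unique(unlist(lapply(metrics_list, `[[`, "classes"))))
  get_tab <- function(m, field) {
    v <- stats::setNames(rep(0L, length(classes)), classes)
    v[m$classes] <- m[[field]]
    v
  }
  n_in <- Reduce(`+`, lapply(metrics_list, get_tab, "n_in"))
  n_ret <- Reduce(`+`, lapply(metrics_list, get_tab, "n_retained"))
  retention <- ifelse(n_in > 0L, 100 * n_ret / n_in, NA_real_)
  out <- list(
    classes = classes, n_in = n_in, n_retained = n_ret, retention = retention,
    n_host_in = unname(n_in["host"]) %|NA|% 0L,
    n_host_retained = unname(n_ret["host"]) %|NA|% 0L,
    n_microbe_in = unname(n_in["microbe"]) %|NA|% 0L,
    n_microbe_retained = unname(n_ret["microbe"]) %|NA|% 0L
  )
  out$host_retention <- if (out$n_host_in > 0) 100 * out$n_host_retained / out$n_host_in else NA_real_
  out$microbe_retention <- if (out$n_microbe_in > 0) 100 * out$n_microbe_retained / out$n_microbe_in else NA_real_
  structure(out, class = "retention_metrics")
}

#' Subtract viral contamination from retained host reads
#'
#' Lymphoblastoid-cell-line human data are commonly contaminated with
#' Epstein-Barr Virus; such reads survive host decontamination and inflate
#' apparent host retention. This runs the full decontamination pipeline a
#' second time with a custom index built from a small viral reference
#' (e.g. EBV accessions NC_007605.1 and NC_009334.1) and reports the
#' adjusted host-retention figure
#' `retained after viral subtraction / original input units`.
#'
#' @param fastq1,fastq2 the retained (decontaminated) host reads.
#' @param viral_ref FASTA of viral reference sequence(s).
#' @param n_input_units original number of input read units the unadjusted
#'   retention was computed against.
#' @param out_dir working directory for the viral index and outputs.
#' @param aligner backend to align against the viral index.
#' @param threads worker threads.
#' @return object of class `ebv_adjustment`: `viral_index_accessions`,
#'   `n_viral_removed`, `unadjusted_host_retention`,
#'   `adjusted_host_retention` (percentages), plus output paths.
#' @export
ebv_adjust <- function(fastq1, fastq2 = NULL, viral_ref, n_input_units,
                       out_dir = tempfile("ebv_adjust_"),
                       aligner = c("short", "long"), threads = 1L) {
  aligner <- match.arg(aligner)
  if (!file.exists(viral_ref)) hs_io("viral reference not found: %s", viral_ref)
  vset <- Biostrings::readDNAStringSet(viral_ref)
  if (length(vset) == 0L || sum(Biostrings::width(vset)) == 0L) {
    hs_validation("viral reference is empty: %s", viral_ref)
  }
  if (n_input_units < 1L) hs_validation("n_input_units must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- reference_db("viral-custom", viral_ref)
  idx <- build_index(db, backend = aligner, out_dir = out_dir)
  res <- clean(fastq1 = fastq1, fastq2 = fastq2, index = idx,
               aligner = aligner, threads = threads, out_dir = out_dir,
               report_path = file.path(out_dir, "viral_subtraction.json"))
  n_before <- res$counts$reads_in[[1L]]
  n_after <- res$counts$reads_out[[1L]]
  unadjusted <- 100 * n_before / n_input_units
  adjusted <- 100 * n_after / n_input_units
  structure(
    list(
      viral_index_accessions = sub("\\s.*$", "", names(vset)),
      n_viral_removed = n_before - n_after,
      unadjusted_host_retention = unadjusted,
      adjusted_host_retention = adjusted,
      out1 = res$out1, out2 = res$out2
    ),
    class = "ebv_adjustment"
  )
}

#' Bootstrap confidence interval for a removed-read fold-change
#'
#' For paired per-sample removed-read counts from two tools/runs, computes
#' the mean per-sample fold-change `removed_b / removed_a` and a seeded
#' bootstrap percentile CI over samples. Samples where both runs removed
#' nothing contribute fold 1; samples where only run a removed nothing are
#' infinite and excluded from the mean (reported separately).
#'
#' @param removed_a,removed_b integer vectors of removed-read counts, one
#'   element per sample, positionally matched.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the resampling.
#' @return list with `mean_fold`, `ci` (length 2), `n_samples`,
#'   `n_infinite`.
#' @export
fold_change_ci <- function(removed_a, removed_b, n_boot = 10000L,
                           conf = 0.95, seed = 1L) {
  if (length(removed_a) != length(removed_b) || length(removed_a) == 0L) {
    hs_usage("removed_a and removed_b must be non-empty and equal length")
  }
  fold <- ifelse(removed_a == 0L, ifelse(removed_b == 0L, 1, Inf),
                 removed_b / removed_a)
  finite <- fold[is.finite(fold)]
  if (length(finite) == 0L) hs_validation("no finite per-sample fold-changes")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(finite[sample.int(length(finite), replace = TRUE)])
  }, 1.0)
  alpha <- (1 - conf) / 2
  list(
    mean_fold = mean(finite),
    ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
    n_samples = length(fold),
    n_infinite = sum(is.infinite(fold))
  )
}

#' Compare two decontamination runs
#'
#' Percentage-point retention deltas per class and fold-changes in
#' removed-read counts (`removed_b / removed_a`), with `removed_a = 0`
#' reported as infinite rather than crashing (and 0/0 as fold-change 1).
#'
#' @param metrics_a,metrics_b `retention_metrics` over the same truth
#'   universe (identical per-class input counts).
#' @return data.frame with one row per class: input/removed counts,
#'   retention percentages, `delta_pp` (b - a) and `fold_change_removed`.
#' @export
compare_runs <- function(metrics_a, metrics_b) {
  stopifnot(inherits(metrics_a, "retention_metrics"),
            inherits(metrics_b, "retention_metrics"))
  if (!identical(metrics_a$classes, metrics_b$classes) ||
      !identical(unname(metrics_a$n_in), unname(metrics_b$n_in))) {
    hs_usage("runs were scored against different truth universes")
  }
  removed_a <- metrics_a$n_in - metrics_a$n_retained
  removed_b <- metrics_b$n_in - metrics_b$n_retained
  fold <- ifelse(removed_a == 0L,
                 ifelse(removed_b == 0L, 1, Inf),
                 removed_b / removed_a)
  data.frame(
    class = metrics_a$classes,
    n_in = unname(metrics_a$n_in),
    removed_a = unname(removed_a),
    removed_b = unname(removed_b),
    retention_a = unname(metrics_a$retention),
    retention_b = unname(metrics_b$retention),
    delta_pp = unname(metrics_b$retention - metrics_a$retention),
    fold_change_removed = unname(fold),
    stringsAsFactors = FALSE
  )
}
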