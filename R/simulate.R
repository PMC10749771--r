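# Deterministic synthetic-data generators: random genomes, Illumina-like
# paired reads, nanopore-like long reads, and contamination mixtures with
# truth labels encoded in read names.
#
# These stand in for the DWGSIM/PBSIM2 simulations used to benchmark
# decontamination accuracy at full scale; error models are deliberately
# simple (see the methods vignette) since the removal decision never looks
# at base qualities and only coarse error structure matters.

#' Simulation parameter set
#'
#' @param seed RNG seed; every generator is bit-reproducible given the seed.
#' @param read_len short-read length in bp (2x100 and 2x150 are the
#'   benchmark layouts; default 150).
#' @param frag_mean,frag_sd insert-size distribution (bp) for paired reads.
#' @param err_rate per-base error probability (substitutions for short
#'   reads; total substitution+indel rate for long reads).
#' @param long_len_mean,long_len_shape gamma length distribution of long
#'   reads (mean bp, shape); lengths are truncated to `[200, genome]`.
#' @param depth target fold-coverage when `n` is derived from depth.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, read_len = 150L, frag_mean = 300L,
                       frag_sd = 50L, err_rate = 0.01,
                       long_len_mean = 5000, long_len_shape = 2,
                       depth = 10) {
  if (err_rate < 0 || err_rate >= 1) hs_validation("err_rate must be in [0, 1)")
  if (read_len < 1L) hs_validation("read_len must be >= 1")
  if (depth <= 0) hs_validation("depth must be > 0")
  structure(
    list(seed = as.integer(seed), read_len = as.integer(read_len),
         frag_mean = frag_mean, frag_sd = frag_sd, err_rate = err_rate,
         long_len_mean = long_len_mean, long_len_shape = long_len_shape,
         depth = depth),
    class = "sim_params"
  )
}

#' Generate a random genome sequence
#'
#' i.i.d. bases with the requested GC content, written as FASTA when `path`
#' is given.
#'
#' @param length sequence length in bp (>= 1).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @param path optional output FASTA path.
#' @param name sequence name (default `"synth1"`).
#' @return the sequence as a character scalar (invisibly the path when
#'   `path` is given; the sequence is attached as attribute `"seq"`).
#' @export
synth_genome <- function(length, gc = 0.5, seed = 1L, path = NULL,
                         name = "synth1") {
  if (length < 1L) hs_validation("genome length must be >= 1")
  if (gc < 0 || gc > 1) hs_validation("gc must be in [0, 1]")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  seq <- paste(bases, collapse = "")
  if (is.null(path)) return(stats::setNames(seq, name))
  set <- Biostrings::DNAStringSet(seq)
  names(set) <- name
  Biostrings::writeXStringSet(set, path, width = 60L)
  out <- path
  attr(out, "seq") <- stats::setNames(seq, name)
  invisible(out)
}

# Accept a FASTA path, a DNAStringSet, or a named character vector.
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    set <- Biostrings::readDNAStringSet(genome)
    g <- as.character(set)
    names(g) <- sub("\\s.*$", "", names(set))
    return(g)
  }
  if (inherits(genome, "DNAStringSet")) {
    g <- as.character(genome)
    names(g) <- sub("\\s.*$", "", names(genome))
    return(g)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
    return(genome)
  }
  hs_usage("cannot interpret genome input of class %s", class(genome)[[1L]])
}

# --- provenance --------------------------------------------------------------

#' Encode / parse read provenance
#'
#' Generated read names are `source|start0|strand|truth|serial[/mate]`,
#' losslessly recording the origin of every simulated read so truth-based
#' retention metrics can be computed downstream.
#'
#' @param source_id source sequence name.
#' @param start 0-based start of the fragment/read on the source.
#' @param strand `"+"` or `"-"`.
#' @param truth `"host"`, `"microbe"` or `"viral"`.
#' @param serial integer serial number within the batch.
#' @return `encode_provenance`: character vector of ids.
#' @export
encode_provenance <- function(source_id, start, strand, truth, serial) {
  paste(source_id, start, strand, truth, serial, sep = "|")
}

#' @rdname encode_provenance
#' @param ids read ids (mate suffixes are stripped first).
#' @return `parse_provenance`: data.frame with columns `source_id`, `start`,
#'   `strand`, `truth`, `serial`.
#' @export
parse_provenance <- function(ids) {
  ids <- base_read_id(ids)
  parts <- data.table::tstrsplit(ids, "|", fixed = TRUE)
  if (length(parts) != 5L) hs_format("read ids do not carry provenance fields")
  data.frame(
    source_id = parts[[1L]], start = as.integer(parts[[2L]]),
    strand = parts[[3L]], truth = parts[[4L]], serial = as.integer(parts[[5L]]),
    stringsAsFactors = FALSE
  )
}

# Introduce i.i.d. substitutions at rate err into uppercase reads.
mutate_substitutions <- function(reads, err) {
  if (err <= 0) return(reads)
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, err)
  idx <- which(n_err > 0L)
  for (i in idx) {
    chars <- strsplit(reads[[i]], "", fixed = TRUE)[[1L]]
    at <- sample.int(lens[[i]], n_err[[i]])
    for (p in at) {
      chars[[p]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[p]]), 1L)
    }
    reads[[i]] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate Illumina-like paired-end reads
#'
#' Fragments are drawn uniformly from the genome with normally distributed
#' insert sizes; read 1 is the 5' end of the fragment on its strand, read 2
#' the reverse complement of the fragment's 3' end, so with `err_rate = 0`
#' every read is an exact substring of the genome or its reverse
#' complement. Errors are i.i.d. substitutions. Qualities are constant Q25.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param n_pairs number of read pairs.
#' @param params a [sim_params()]; `seed`, `read_len`, `frag_mean`,
#'   `frag_sd` and `err_rate` are used.
#' @param truth truth label stored in read names.
#' @param out1,out2 optional FASTQ(.gz) output paths.
#' @return list of two FASTQ data.frames (`r1`, `r2`), plus `out1`/`out2`
#'   when written.
#' @export
simulate_illumina_pairs <- function(genome, n_pairs, params = sim_params(),
                                    truth = "microbe",
                                    out1 = NULL, out2 = NULL) {
  g <- load_genome(genome)
  lens <- nchar(g)
  min_len <- params$frag_mean + 6 * params$frag_sd
  if (all(lens < min_len)) {
    hs_validation("genome too short for frag_mean=%s, frag_sd=%s (need >= %s bp)",
                  params$frag_mean, params$frag_sd, min_len)
  }
  g <- g[lens >= min_len]
  lens <- nchar(g)
  set.seed(params$seed)
  src <- sample.int(length(g), n_pairs, replace = TRUE, prob = lens / sum(lens))
  frag <- pmax(params$read_len,
               pmin(round(stats::rnorm(n_pairs, params$frag_mean, params$frag_sd)),
                    lens[src]))
  start <- vapply(seq_len(n_pairs), function(i) {
    sample.int(lens[src[[i]]] - frag[[i]] + 1L, 1L)
  }, 1L)
  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  frag_seq <- substring(g[src], start, start + frag - 1L)
  neg <- strand == "-"
  frag_seq[neg] <- revcomp_chr(frag_seq[neg])
  r1_seq <- substring(frag_seq, 1L, params$read_len)
  r2_seq <- revcomp_chr(substring(frag_seq, frag - params$read_len + 1L, frag))
  r1_seq <- mutate_substitutions(r1_seq, params$err_rate)
  r2_seq <- mutate_substitutions(r2_seq, params$err_rate)
  ids <- encode_provenance(names(g)[src], start - 1L, strand, truth, seq_len(n_pairs))
  qual <- strrep(rawToChar(as.raw(25L + 33L)), params$read_len)
  r1 <- data.frame(id = paste0(ids, "/1"), seq = r1_seq, qual = qual,
                   stringsAsFactors = FALSE)
  r2 <- data.frame(id = paste0(ids, "/2"), seq = r2_seq, qual = qual,
                   stringsAsFactors = FALSE)
  if (!is.null(out1)) write_fastq(r1, out1)
  if (!is.null(out2)) write_fastq(r2, out2)
  list(r1 = r1, r2 = r2, out1 = out1, out2 = out2)
}

# Apply the long-read error model to one read: total rate split 40%
# substitution / 30% insertion / 30% deletion.
mutate_long_read <- function(seq, err) {
  if (err <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ev <- sample.int(4L, length(chars), replace = TRUE,
                   prob = c(1 - err, 0.4 * err, 0.3 * err, 0.3 * err))
  out <- character(length(chars))
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(chars)) {
    out[[i]] <- switch(ev[[i]],
      chars[[i]],                                           # match
      sample(setdiff(bases, chars[[i]]), 1L),               # substitution
      paste0(chars[[i]], sample(bases, 1L)),                # insertion after
      ""                                                    # deletion
    )
  }
  paste(out, collapse = "")
}

#' Simulate nanopore-like long reads
#'
#' Read lengths follow a gamma distribution with mean `long_len_mean` and
#' shape `long_len_shape`, truncated to `[200, genome length]`. Errors at
#' total rate `err_rate` are split 40% substitution / 30% insertion / 30%
#' deletion. Qualities are constant Q12.
#'
#' @inheritParams simulate_illumina_pairs
#' @param n number of reads.
#' @param out optional FASTQ(.gz) output path.
#' @return FASTQ data.frame (and `out` path when written).
#' @export
simulate_long_reads <- function(genome, n, params = sim_params(err_rate = 0.05),
                                truth = "microbe", out = NULL) {
  g <- load_genome(genome)
  if (length(g) == 0L || all(nchar(g) == 0L)) hs_validation("genome is empty")
  lens <- nchar(g)
  set.seed(params$seed)
  reads <- data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE)
  if (n > 0L) {
    src <- sample.int(length(g), n, replace = TRUE, prob = lens / sum(lens))
    shape <- params$long_len_shape
    rl <- stats::rgamma(n, shape = shape, scale = params$long_len_mean / shape)
    rl <- pmin(pmax(round(rl), 200L), lens[src])
    rl <- pmax(rl, 1L)
    start <- vapply(seq_len(n), function(i) {
      sample.int(lens[src[[i]]] - rl[[i]] + 1L, 1L)
    }, 1L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(g[src], start, start + rl - 1L)
    neg <- strand == "-"
    seqs[neg] <- revcomp_chr(seqs[neg])
    if (params$err_rate > 0) {
      seqs <- vapply(seqs, mutate_long_read, "", err = params$err_rate,
                     USE.NAMES = FALSE)
    }
    ids <- encode_provenance(names(g)[src], start - 1L, strand, truth, seq_len(n))
    qual <- strrep(rawToChar(as.raw(12L + 33L)), nchar(seqs))
    reads <- data.frame(id = ids, seq = seqs, qual = qual, stringsAsFactors = FALSE)
  }
  if (!is.null(out)) write_fastq(reads, out)
  if (!is.null(out)) attr(reads, "out") <- out
  reads
}

#' Mix host and microbe reads into a contaminated sample
#'
#' Concatenates two read sets of identical layout, shuffles read (pair)
#' order deterministically, and emits a truth table mapping each read id to
#' its truth class (taken from the provenance-encoded names).
#'
#' @param host_reads,microbe_reads either FASTQ data.frames / single paths
#'   (single-end) or lists of two data.frames / two paths (paired).
#' @param seed shuffle seed.
#' @param out1,out2 optional mixed FASTQ output path(s).
#' @param truth_path optional truth-table TSV output path.
#' @return list with `r1` (+ `r2` if paired) FASTQ data.frames and `truth`
#'   (data.frame `read_id`, `truth`).
#' @export
mix_contamination <- function(host_reads, microbe_reads, seed = 1L,
                              out1 = NULL, out2 = NULL, truth_path = NULL) {
  norm <- function(x) {
    if (is.data.frame(x)) return(list(x))
    if (is.character(x)) return(lapply(x, read_fastq))
    if (is.list(x)) {
      x <- x[!vapply(x, is.null, TRUE)]
      x <- x[vapply(x, is.data.frame, TRUE) | vapply(x, is.character, TRUE)]
      return(lapply(x, function(e) if (is.data.frame(e)) e else read_fastq(e)))
    }
    hs_usage("cannot interpret read input")
  }
  h <- norm(host_reads); m <- norm(microbe_reads)
  if (length(h) != length(m)) {
    hs_usage("host and microbe read sets have different layouts (%d vs %d files)",
             length(h), length(m))
  }
  paired <- length(h) == 2L
  if (!paired && length(h) != 1L) hs_usage("expected 1 (single) or 2 (paired) files")
  combined <- lapply(seq_along(h), function(i) rbind(h[[i]], m[[i]]))
  n <- nrow(combined[[1L]])
  set.seed(seed)
  perm <- sample.int(n)
  combined <- lapply(combined, function(df) df[perm, , drop = FALSE])
  ids <- base_read_id(combined[[1L]]$id)
  truth <- data.frame(read_id = ids,
                      truth = parse_provenance(ids)$truth,
                      stringsAsFactors = FALSE)
  if (!is.null(out1)) write_fastq(combined[[1L]], out1)
  if (paired && !is.null(out2)) write_fastq(combined[[2L]], out2)
  if (!is.null(truth_path)) {
    data.table::fwrite(truth, truth_path, sep = "\t")
  }
  out <- list(r1 = combined[[1L]], truth = truth, out1 = out1)
  if (paired) { out$r2 <- combined[[2L]]; out$out2 <- out2 }
  out
}
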