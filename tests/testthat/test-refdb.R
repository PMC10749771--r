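# refdb module: interval merging, reference masking, index building.

test_that("merge_intervals matches a brute-force covered-base oracle", {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(seq_id = paste0("chr", m[, 1]), start = as.integer(m[, 2]),
               end = as.integer(m[, 3]))
  }
  covered <- function(d) {
    unlist(lapply(seq_len(nrow(d)), function(i) {
      paste0(d$seq_id[i], ":", seq(d$start[i], d$end[i] - 1L))
    }))
  }
  expect_equal(nrow(merge_intervals(NULL)), 0L)
  expect_equal(merge_intervals(iv("A", 0, 10, "A", 5, 20)),
               iv("A", 0, 20), ignore_attr = TRUE)
  # disjoint sequences never merge, output is sorted
  d <- merge_intervals(iv("B", 0, 10, "A", 0, 10))
  expect_equal(d$seq_id, c("chrA", "chrB"))
  # randomized: union of covered bases is preserved and output is disjoint
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:12, 1L)
    d <- data.frame(seq_id = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = sample(0:80, n, replace = TRUE))
    d$end <- d$start + sample(1:30, n, replace = TRUE)
    m <- merge_intervals(d)
    expect_setequal(covered(m), unique(covered(d)))
    expect_true(all(m$start < m$end))
    by_seq <- split(m, m$seq_id)
    for (s in by_seq) {
      if (nrow(s) > 1L) expect_true(all(s$start[-1L] > s$end[-nrow(s)]))
    }
  }
  expect_error(merge_intervals(iv("A", 5, 5)), class = "hs_validation_error")
})

make_planted_host <- function(dir, host_len = 100000L, seg = c(20001L, 20500L)) {
  microbe <- synth_genome(50000L, gc = 0.5, seed = 7L)
  host <- synth_genome(host_len, gc = 0.41, seed = 8L)
  planted <- paste0(substr(host, 1L, seg[1L] - 1L),
                    substr(microbe, 1001L, 1000L + diff(seg) + 1L),
                    substr(host, seg[2L] + 1L, host_len))
  host_fa <- file.path(dir, "host.fa"); microbe_fa <- file.path(dir, "microbe.fa")
  hs <- Biostrings::DNAStringSet(planted); names(hs) <- "hostchr"
  Biostrings::writeXStringSet(hs, host_fa, width = 60L)
  ms <- Biostrings::DNAStringSet(microbe); names(ms) <- "microbe1"
  Biostrings::writeXStringSet(ms, microbe_fa, width = 60L)
  list(host_fa = host_fa, microbe_fa = microbe_fa, planted = planted)
}

test_that("mask_reference with an empty panel changes nothing", {
  d <- withr::local_tempdir()
  fx <- make_planted_host(d)
  res <- mask_reference(fx$host_fa, character(),
                        out_fasta = file.path(d, "m.fa"),
                        out_bed = file.path(d, "m.bed"))
  expect_equal(nrow(res$intervals), 0L)
  expect_equal(res$masked_bases, 0L)
  out <- as.character(Biostrings::readDNAStringSet(res$fasta))
  expect_identical(unname(out), fx$planted)
})

test_that("mask_reference finds a planted microbe segment (both routes)", {
  d <- withr::local_tempdir()
  fx <- make_planted_host(d)  # 500 bp microbe segment at [20000, 20500)
  for (method in c("kmer", "minimap2")) {
    res <- mask_reference(fx$host_fa, fx$microbe_fa, method = method,
                          out_fasta = file.path(d, paste0(method, ".fa")),
                          out_bed = file.path(d, paste0(method, ".bed")))
    expect_equal(nrow(res$intervals), 1L)
    ov <- min(res$intervals$end, 20500L) - max(res$intervals$start, 20000L)
    expect_gte(ov, 0.9 * 500L)
    # conservation: length unchanged, added N count equals interval length
    out <- Biostrings::readDNAStringSet(res$fasta)
    expect_equal(Biostrings::width(out), nchar(fx$planted))
    n_count <- Biostrings::letterFrequency(out, "N")[1L]
    expect_equal(unname(n_count), res$masked_bases)
    # non-masked bases are byte-identical to input
    chars_in <- strsplit(fx$planted, "")[[1L]]
    chars_out <- strsplit(as.character(out)[[1L]], "")[[1L]]
    expect_identical(chars_out[chars_out != "N"], chars_in[chars_out != "N"])
  }
})

test_that("overlapping planted segments merge to one interval", {
  d <- withr::local_tempdir()
  microbe <- synth_genome(50000L, gc = 0.5, seed = 7L)
  host <- synth_genome(100000L, gc = 0.41, seed = 8L)
  # two 400 bp microbe windows overlapping by 100 bp on the microbe side,
  # planted as one contiguous 700 bp run in the host
  planted <- paste0(substr(host, 1L, 30000L), substr(microbe, 5001L, 5700L),
                    substr(host, 30701L, 100000L))
  host_fa <- file.path(d, "host.fa")
  hs <- Biostrings::DNAStringSet(planted); names(hs) <- "hostchr"
  Biostrings::writeXStringSet(hs, host_fa, width = 60L)
  m1 <- file.path(d, "m1.fa"); m2 <- file.path(d, "m2.fa")
  s1 <- Biostrings::DNAStringSet(substr(microbe, 5001L, 5400L)); names(s1) <- "m1"
  s2 <- Biostrings::DNAStringSet(substr(microbe, 5301L, 5700L)); names(s2) <- "m2"
  Biostrings::writeXStringSet(s1, m1, width = 60L)
  Biostrings::writeXStringSet(s2, m2, width = 60L)
  res <- mask_reference(host_fa, c(m1, m2), method = "kmer",
                        out_fasta = file.path(d, "out.fa"),
                        out_bed = file.path(d, "out.bed"))
  expect_equal(nrow(res$intervals), 1L)
  expect_equal(res$intervals$start, 30000L)
  expect_equal(res$intervals$end, 30700L)
})

test_that("masking is monotone in the microbe panel", {
  d <- withr::local_tempdir()
  fx <- make_planted_host(d)
  extra_fa <- file.path(d, "extra.fa")
  host_seq <- as.character(Biostrings::readDNAStringSet(fx$host_fa))[[1L]]
  es <- Biostrings::DNAStringSet(substr(host_seq, 60001L, 60400L))
  names(es) <- "extra_microbe"
  Biostrings::writeXStringSet(es, extra_fa, width = 60L)
  r1 <- mask_reference(fx$host_fa, fx$microbe_fa, method = "kmer",
                       out_fasta = file.path(d, "a.fa"), out_bed = file.path(d, "a.bed"))
  r2 <- mask_reference(fx$host_fa, c(fx$microbe_fa, extra_fa), method = "kmer",
                       out_fasta = file.path(d, "b.fa"), out_bed = file.path(d, "b.bed"))
  expect_gte(r2$masked_bases, r1$masked_bases)
})

test_that("build_index is idempotent and detects staleness", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "ref.fa")
  synth_genome(20000L, seed = 3L, path = fa, name = "ref1")
  db <- reference_db("tiny-ref", fa)
  idx <- build_index(db, "short", out_dir = d)
  expect_true(file.exists(idx))
  expect_match(basename(idx), "^tiny-ref\\.sr\\.mmi$")
  mtime1 <- file.mtime(idx)
  idx2 <- build_index(db, "short", out_dir = d)   # no-op rebuild
  expect_identical(idx, idx2)
  expect_identical(file.mtime(idx2), mtime1)
  expect_silent(validate_index(idx, fa))
  unlink(fa)
  expect_error(validate_index(idx, fa), class = "hs_stale_index_error")
})

test_that("reference_db validates its name", {
  expect_error(reference_db("has space", "x.fa"), class = "hs_validation_error")
  expect_error(reference_db("a/b", "x.fa"), class = "hs_validation_error")
  db <- reference_db("human-t2t-hla", "x.fa")
  expect_s3_class(db, "reference_db")
})
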