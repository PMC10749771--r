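# filter_engine module: classification, pair-aware decisions, application.

short_spec <- function() aligner_spec("short", "idx")
long_spec <- function() aligner_spec("long", "idx")

test_that("classify_alignment applies backend rules", {
  aln <- parse_sam_lines(c(
    sam_line("u", 4L),                           # unmapped
    sam_line("at", 0L, tags = "s1:i:40"),        # at threshold
    sam_line("below", 0L, tags = "s1:i:39"),     # strictly below
    sam_line("notag", 0L)                        # mapped, no score tag
  ))
  expect_equal(classify_alignment(aln, long_spec()), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(classify_alignment(aln, short_spec()), c(FALSE, TRUE, TRUE, TRUE))
  expect_length(classify_alignment(aln[0, ], short_spec()), 0L)
})

test_that("decide_reads removes pairs when either mate aligns", {
  sam <- c(sam_header,
           sam_line("a/1", 69L), sam_line("a/2", 133L),    # both unmapped
           sam_line("b/1", 73L), sam_line("b/2", 133L))    # mate 1 mapped
  dec <- decide_reads(sam, short_spec(), paired = TRUE)
  d <- dec$decisions
  expect_false(any(d$remove[d$read_id == "a"]))
  expect_true(all(d$remove[d$read_id == "b"]))
  expect_equal(d$reason[d$read_id == "b" & d$mate == 1L], "self_aligned")
  expect_equal(d$reason[d$read_id == "b" & d$mate == 2L], "mate_aligned")
  expect_equal(dec$removed_ids, "b")
  expect_equal(dec$n_distinct_units, 4L)
})

test_that("paired mode rejects records without a mate flag", {
  sam <- c(sam_line("a/1", 73L), sam_line("weird", 0L))
  expect_error(decide_reads(sam, short_spec(), paired = TRUE),
               "neither mate flag", class = "hs_format_error")
})

test_that("secondary/supplementary records OR into the read decision", {
  sam <- c(
    sam_line("x", 4L),                              # primary unmapped
    sam_line("x", 256L, tags = "s1:i:80"),          # secondary mapped
    sam_line("y", 4L),
    sam_line("y", 2048L, tags = "s1:i:10")          # supplementary below threshold
  )
  dec <- decide_reads(sam, long_spec(), paired = FALSE)
  expect_equal(dec$removed_ids, "x")
})

test_that("decide_reads equals the brute-force oracle on a mixed fixture", {
  set.seed(99)
  sam <- c(sam_header, unlist(lapply(1:6, function(i) {
    id <- paste0("p", i)
    m1 <- sample(c(73L, 69L), 1L)
    m2 <- sample(c(133L, 137L), 1L)
    extra <- if (i %% 2L == 0L) sam_line(paste0(id, "/1"), m1 %% 2048L + 256L) else NULL
    c(sam_line(paste0(id, "/1"), m1), sam_line(paste0(id, "/2"), m2), extra)
  })))
  dec <- decide_reads(sam, short_spec(), paired = TRUE)
  expect_setequal(dec$removed_ids, oracle_removed_ids(sam, "short"))
})

test_that("apply_decisions keeps everything when no decision removes", {
  d <- withr::local_tempdir()
  fx <- write_pair_fixture(d, paste0("r", 1:5))
  res <- apply_decisions(fx$p1, fx$p2, decisions = character(), out_dir = d)
  expect_equal(res$total_in, 10L)
  expect_equal(res$total_removed, 0L)
  out1 <- read_fastq(res$out1)
  expect_identical(out1, fx$r1)
})

test_that("apply_decisions removes pairs and renames with shared integers", {
  d <- withr::local_tempdir()
  fx <- write_pair_fixture(d, paste0("p", 1:4))
  map_path <- file.path(d, "map.tsv")
  res <- apply_decisions(fx$p1, fx$p2, decisions = c("p2", "p3"),
                         rename = TRUE, out_dir = d,
                         rename_map_path = map_path)
  o1 <- read_fastq(res$out1); o2 <- read_fastq(res$out2)
  expect_equal(o1$id, c("1", "2"))
  expect_equal(o2$id, c("1", "2"))
  expect_equal(o1$seq, fx$r1$seq[c(1L, 4L)])  # input order preserved
  expect_equal(res$total_removed, 4L)
  m <- read.delim(map_path)
  expect_equal(m$original_id, c("p1", "p4"))
  expect_equal(as.character(m$new_id), c("1", "2"))
})

test_that("apply_decisions handles empty input and degenerate duplicates", {
  d <- withr::local_tempdir()
  empty <- file.path(d, "empty.fq.gz")
  write_fastq(make_reads(character()), empty)
  res <- apply_decisions(empty, decisions = character(), out_dir = d)
  expect_equal(res$total_in, 0L)
  expect_equal(res$total_out, 0L)
  expect_equal(nrow(read_fastq(res$out1)), 0L)
  # duplicate ids in one single-end file must not crash
  dup <- file.path(d, "dup.fq.gz")
  write_fastq(make_reads(c("d", "d", "e")), dup)
  res2 <- apply_decisions(dup, decisions = "d", out_dir = d)
  expect_equal(res2$total_out, 1L)
  expect_equal(res2$total_in, res2$total_out + res2$total_removed)
})

test_that("paired input integrity errors name the offender", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a_1.fq.gz"); p2 <- file.path(d, "a_2.fq.gz")
  write_fastq(make_reads(c("x/1", "y/1")), p1)
  write_fastq(make_reads(c("x/2")), p2)
  expect_error(apply_decisions(p1, p2, out_dir = d),
               basename(p2), class = "hs_format_error")
  write_fastq(make_reads(c("x/2", "z/2")), p2)
  expect_error(apply_decisions(p1, p2, out_dir = d),
               "record 2", class = "hs_format_error")
})

test_that("rename_reads assigns shared incrementing integers", {
  expect_equal(rename_reads(make_reads(c("a", "b", "c")))$id, c("1", "2", "3"))
  expect_equal(nrow(rename_reads(make_reads(character()))), 0L)
  pair <- rename_reads(list(make_reads(c("x/1", "y/1")),
                            make_reads(c("x/2", "y/2"))), start = 5L)
  expect_equal(pair[[1L]]$id, c("5", "6"))
  expect_equal(pair[[2L]]$id, c("5", "6"))
})

test_that("reads absent from the SAM stream are kept (subtractive semantics)", {
  d <- withr::local_tempdir()
  fx <- write_pair_fixture(d, c("seen", "unseen"))
  sam <- c(sam_line("seen/1", 73L), sam_line("seen/2", 133L))
  dec <- decide_reads(sam, short_spec(), paired = TRUE)
  res <- apply_decisions(fx$p1, fx$p2, decisions = dec, out_dir = d)
  expect_equal(base_read_id(read_fastq(res$out1)$id), "unseen")
})
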