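# Interval containers, BED round-trips, merging and overlap counting.

test_that("read_bed parses BED4, skips headers, tolerates CRLF, synthesizes ids", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "track name=demo",
               "browser position chrX",
               "chrX\t100\t200\telemA",
               "",
               "chrX\t500\t650"), bed)
  tr <- read_bed(bed, "demo", element_class = "lncRNA")
  expect_length(tr, 2)
  expect_identical(names(tr), c("elemA", "chrX:500-650"))
  expect_identical(GenomicRanges::width(tr), c(100L, 150L))
  expect_identical(S4Vectors::metadata(tr)$track_name, "demo")
  expect_identical(S4Vectors::metadata(tr)$element_class, "lncRNA")

  # same content with CRLF endings parses identically
  crlf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrX\t100\t200\telemA\r", "chrX\t500\t650\r"), crlf, sep = "\n")
  tr2 <- read_bed(crlf, "demo", element_class = "lncRNA")
  expect_identical(names(tr2), names(tr))
  expect_identical(GenomicRanges::start(tr2), GenomicRanges::start(tr))
})

test_that("read_bed of a file with no data lines yields an empty track", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# only comments", "track name=x"), bed)
  expect_length(read_bed(bed, "empty"), 0)
})

test_that("read_bed rejects malformed lines naming the line number", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrX\t1\t2", "chrX\t10\tten"), bed)
  expect_error(read_bed(bed), "line 2")

  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# header", "chrX\t200\t100"), bed2)
  expect_error(read_bed(bed2), "line 2")

  bed3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrX\t100", bed3)
  expect_error(read_bed(bed3), "line 1")
})

test_that("write_bed emits sorted BED4 lines and empty files for empty sets", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr0("chrX", 100, 200, "r1"), path)
  expect_identical(readLines(path), "chrX\t100\t200\tr1")

  write_bed(GenomicRanges::GRanges(), path)
  expect_identical(readLines(path), character(0))
})

test_that("BED round-trip preserves the (chrom, start, end, id) multiset", {
  for (s in c(11L, 12L, 13L)) {
    set.seed(s)
    df <- rand_elements_df(50, 1e6, 10, 5000)
    tr <- df_to_granges(df)
    path <- withr::local_tempfile(fileext = ".bed")
    write_bed(tr, path)
    back <- read_bed(path)
    key <- function(g) sort(sprintf("%s:%d-%d:%s",
                                    as.character(GenomicRanges::seqnames(g)),
                                    GenomicRanges::start(g),
                                    GenomicRanges::end(g), names(g)))
    expect_identical(key(back), key(tr))
  }
})

test_that("merge_intervals unions overlapping and book-ended intervals", {
  m1 <- merge_intervals(gr0("chrX", c(100, 150), c(200, 250)))
  expect_length(m1, 1)
  expect_identical(GenomicRanges::start(m1), 101L)
  expect_identical(GenomicRanges::end(m1), 250L)

  # book-ended convention: [100,200) + [200,300) merge to [100,300)
  m2 <- merge_intervals(gr0("chrX", c(100, 200), c(200, 300)))
  expect_length(m2, 1)
  expect_identical(GenomicRanges::width(m2), 200L)

  # but different chromosomes never merge
  two <- GenomicRanges::GRanges(c("chrX", "chr1"),
                                IRanges::IRanges(c(101, 101), c(200, 200)))
  expect_length(merge_intervals(two), 2)
})

test_that("merge_intervals covered bases match the per-base bitmap oracle and merging is idempotent", {
  set.seed(21)
  L <- 20000L
  df <- rand_elements_df(200, L, 5, 400)
  gr <- df_to_granges(df)
  merged <- merge_intervals(gr)
  expect_identical(sum(GenomicRanges::width(merged)),
                   bf_covered_bases(df$start, df$end, L))
  expect_true(GenomicRanges::isDisjoint(merged))

  again <- merge_intervals(merged)
  expect_identical(GenomicRanges::start(again), GenomicRanges::start(merged))
  expect_identical(GenomicRanges::end(again), GenomicRanges::end(merged))
})

test_that("count_overlapping_elements deduplicates by element id", {
  expect_identical(count_overlapping_elements(GenomicRanges::GRanges(),
                                              gr0("chrX", 0, 100))$count, 0L)

  # one element touching two regions counts once
  oc <- count_overlapping_elements(gr0("chrX", 150, 160, "el1"),
                                   gr0("chrX", c(100, 155), c(200, 300)))
  expect_identical(oc$count, 1L)
  expect_identical(oc$element_ids, "el1")

  # coordinate-identical elements with distinct ids count twice
  oc2 <- count_overlapping_elements(gr0("chrX", c(150, 150), c(160, 160),
                                        c("a", "b")),
                                    gr0("chrX", 100, 200))
  expect_identical(oc2$count, 2L)

  # book-ended element/region pairs do not overlap
  expect_identical(count_overlapping_elements(gr0("chrX", 200, 300, "el"),
                                              gr0("chrX", 100, 200))$count, 0L)

  # disjoint chromosome namespaces yield zero
  expect_identical(count_overlapping_elements(gr0("chr7", 150, 160, "el"),
                                              gr0("chrX", 100, 200))$count, 0L)
})

test_that("interval-index counts equal the all-pairs brute force on random fixtures", {
  set.seed(31)
  el <- rand_elements_df(1000, 5e5, 5, 2000)
  rg <- rand_elements_df(30, 5e5, 100, 20000)
  got <- count_overlapping_elements(df_to_granges(el), df_to_granges(rg))$count
  expect_identical(got, bf_count_elements(el, rg))
})

test_that("counting is monotone in both the track and the region set", {
  set.seed(41)
  el <- rand_elements_df(200, 1e5, 5, 500)
  rg <- rand_elements_df(10, 1e5, 50, 5000)
  base <- count_overlapping_elements(df_to_granges(el), df_to_granges(rg))$count
  for (r in 1:20) {
    extra_el <- rand_elements_df(1, 1e5, 5, 500)
    extra_el$id <- sprintf("x%03d", r)
    more_el <- count_overlapping_elements(df_to_granges(rbind(el, extra_el)),
                                          df_to_granges(rg))$count
    expect_gte(more_el, base)

    extra_rg <- rand_elements_df(1, 1e5, 50, 5000)
    more_rg <- count_overlapping_elements(df_to_granges(el),
                                          df_to_granges(rbind(rg, extra_rg)))$count
    expect_gte(more_rg, base)
  }
})
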