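# Independent brute-force oracles and small fixture builders. These work
# on plain vectors/data.frames in 0-based half-open (BED) coordinates and
# deliberately avoid the package's interval machinery.

# Half-open overlap predicate: [s1,e1) and [s2,e2) share a base iff
# s1 < e2 and s2 < e1.
bf_overlap_halfopen <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# All-pairs O(N*M) overlapping-element count, deduplicated by element id.
bf_count_elements <- function(el, rg) {
  hit <- character(0)
  for (i in seq_len(nrow(el))) {
    for (j in seq_len(nrow(rg))) {
      if (el$chrom[i] == rg$chrom[j] &&
          el$start[i] < rg$end[j] && rg$start[j] < el$end[i]) {
        hit <- c(hit, el$id[i])
        break
      }
    }
  }
  length(unique(hit))
}

# Per-base bitmap oracle for covered bases (0-based half-open input).
bf_covered_bases <- function(start0, end1, L) {
  bits <- logical(L)
  for (i in seq_along(start0)) {
    bits[(start0[i] + 1):end1[i]] <- TRUE
  }
  sum(bits)
}

# Random element table in BED coordinates plus conversion to GRanges.
rand_elements_df <- function(n, L, wmin, wmax, chrom = "chrX") {
  s0 <- sample.int(L - wmax, n, replace = TRUE) - 1L
  w <- sample.int(wmax - wmin + 1L, n, replace = TRUE) + wmin - 1L
  data.frame(chrom = chrom, start = s0, end = s0 + w,
             id = sprintf("e%05d", seq_len(n)), stringsAsFactors = FALSE)
}

df_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  names(gr) <- df$id
  gr
}

# GRanges built from BED (0-based half-open) coordinates, for readable
# expected values in tests.
gr0 <- function(chrom, start0, end1, ids = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end1))
  if (!is.null(ids)) names(gr) <- ids
  gr
}
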