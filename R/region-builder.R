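# Query-region construction from SNP association results.
#
# The association study behind the query set reports SNPs with nominal
# p-values; SNPs passing a strict threshold (p < 0.0005 by default) are
# expanded to symmetric windows and merged into disjoint regions. The flank
# default (75 kb) makes a singleton SNP yield a ~150 kb region, the order of
# magnitude of the study's mean region length; it is a modeling choice, not
# a reconstruction of the original (undisclosed) region-building algorithm.

#' Read a SNP association table
#'
#' Expects a tab-separated file with header columns `snp_id`, `chrom`,
#' `pos` (1-based, association-output convention) and `p`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `snp_id`, `chrom`, `pos`, `p`.
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) .stopf("SNP table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("SNP table %s lacks column(s): %s", path,
                           paste(miss, collapse = ", "))
  df <- df[need]
  if (any(is.na(df$pos)) || any(df$pos < 1) || any(df$pos != floor(df$pos))) {
    .stopf("SNP positions must be integers >= 1 (1-based)")
  }
  if (any(is.na(df$p)) || any(df$p <= 0) || any(df$p > 1)) {
    .stopf("association p-values must lie in (0, 1]")
  }
  df
}

#' Build query regions from thresholded SNPs
#'
#' SNPs with `p < p_max` (strict, matching a nominal `p < 0.0005` inclusion
#' rule) are each expanded to a symmetric window of `flank` bases on either
#' side, clipped to the chromosome, and windows closer than `merge_gap` are
#' merged. The result is sorted and disjoint; it does not depend on the
#' input row order.
#'
#' @param snps Data.frame as returned by [read_snp_table()].
#' @param model A [chromosome_model()] naming the analysis chromosome.
#' @param p_max Strict inclusion threshold (default `5e-4`).
#' @param flank Symmetric padding per SNP in bases (default `75000`,
#'   so a singleton SNP yields a 150,001-base region).
#' @param merge_gap Maximum gap for merging padded windows (default `0`:
#'   merge only on overlap or book-end).
#' @return A sorted, disjoint, named `GRanges`. If no SNP passes the
#'   threshold an empty `GRanges` is returned with a warning.
#' @export
build_regions_from_snps <- function(snps, model, p_max = 5e-4,
                                    flank = 75000, merge_gap = 0) {
  stopifnot(is.data.frame(snps), inherits(model, "chromosome_model"),
            is.numeric(p_max), p_max > 0, p_max < 1,
            .is_count(flank), .is_count(merge_gap))
  off <- snps$chrom != model$name
  if (any(off)) {
    .warnf("dropping %d SNP(s) not on analysis chromosome %s",
           sum(off), model$name)
    snps <- snps[!off, , drop = FALSE]
  }
  pass <- snps$p < p_max
  if (!any(pass)) {
    .warnf("no SNP passes p < %g; returning an empty region set", p_max)
    return(GRanges())
  }
  pos <- snps$pos[pass]
  win <- GRanges(model$name,
                 IRanges(start = pmax(1, pos - flank),
                         end = pmin(model$length, pos + flank)))
  merge_intervals(win, merge_gap = merge_gap)
}

#' Summarize a region set in report form
#'
#' Returns the region count, mean width and width SD in kb, and total
#' covered width (DNA content) in Mb, each rounded to one decimal with ties
#' away from zero, matching the reporting precision of the enrichment table.
#'
#' @param regions A `GRanges`.
#' @return A one-row data.frame with columns `n_regions`, `mean_width_kb`,
#'   `width_sd_kb`, `total_width_mb`. For an empty set `n_regions` is 0 and
#'   the width statistics are `NA`.
#' @examples
#' gr <- GenomicRanges::GRanges("chrX", IRanges::IRanges(c(1, 500000),
#'                                                       width = c(100000, 200000)))
#' summarize_region_set(gr)  # mean 150.0 kb, total 0.3 Mb
#' @export
summarize_region_set <- function(regions) {
  if (!is(regions, "GRanges")) .stopf("summarize_region_set() expects a GRanges")
  n <- length(regions)
  if (n == 0L) {
    return(data.frame(n_regions = 0L, mean_width_kb = NA_real_,
                      width_sd_kb = NA_real_, total_width_mb = NA_real_))
  }
  w <- width(regions)
  data.frame(n_regions = n,
             mean_width_kb = .round_half_away(mean(w) / 1e3, 1),
             width_sd_kb = if (n > 1L) .round_half_away(sd(w) / 1e3, 1) else NA_real_,
             total_width_mb = .round_half_away(sum(w) / 1e6, 1))
}
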