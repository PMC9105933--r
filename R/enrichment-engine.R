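# Observed counts, null distributions, empirical p-values and the
# report-shaped enrichment table.
#
# The empirical p-value is the fraction of randomized iterations whose
# overlap count is the same as or larger than the observed count: with
# k = |{i : null_i >= observed}| over n iterations, p = k/n. The reported
# two-decimal p equals the percent row divided by 100 (e.g. 24.5% -> 0.25),
# which requires rounding the exact rational k/n with ties away from zero.

#' Empirical p-value from null counts
#'
#' @param observed Observed overlap count (non-negative integer).
#' @param null_counts Integer vector of per-iteration null counts
#'   (non-empty).
#' @param conservative Use the `(k+1)/(n+1)` estimator instead of `k/n`.
#'   Off by default: the reported p is the plain qualifying fraction.
#' @return A list with `k` (qualifying iterations), `n`, `pct_ge`
#'   (`100*k/n`) and `p_emp`.
#' @examples
#' empirical_p(5, c(1, 2, 3, 4))   # p_emp = 0
#' empirical_p(0, rep(0, 10))      # equality counts: p_emp = 1
#' @export
empirical_p <- function(observed, null_counts, conservative = FALSE) {
  if (length(null_counts) == 0L) .stopf("null_counts must be non-empty")
  stopifnot(.is_count(observed), is.numeric(null_counts))
  k <- sum(null_counts >= observed)
  n <- length(null_counts)
  list(k = k, n = n, pct_ge = 100 * k / n,
       p_emp = if (conservative) (k + 1) / (n + 1) else k / n)
}

#' Format an empirical p-value for reporting
#'
#' Rounds to `decimals` places with ties away from zero. When the number of
#' iterations `n` is supplied the rounding is performed on the exact
#' rational `k/n` in integer arithmetic (`245/1000 -> "0.25"`,
#' `465/1000 -> "0.47"`); binary-float round-half-even would misreport such
#' ties.
#'
#' @param p_emp Empirical p-value(s) in \eqn{[0, 1]}.
#' @param decimals Decimal places (default 2).
#' @param n Optional iteration count that `p_emp` is a multiple of `1/n`
#'   of; enables exact rational rounding.
#' @return Character vector of fixed-decimal strings.
#' @examples
#' format_p(245 / 1000, n = 1000)  # "0.25"
#' format_p(51 / 1000, n = 1000)   # "0.05"
#' @export
format_p <- function(p_emp, decimals = 2, n = NULL) {
  stopifnot(is.numeric(p_emp), all(p_emp >= 0 & p_emp <= 1),
            .is_count(decimals))
  m <- 10^decimals
  if (!is.null(n)) {
    stopifnot(.is_count(n), n >= 1)
    k <- round(p_emp * n)           # recover the integer numerator
    num <- k * m
    q <- num %/% n
    r <- num - q * n
    val <- (q + (2 * r >= n)) / m
  } else {
    val <- floor(p_emp * m + 0.5 + 1e-9) / m
  }
  formatC(val, format = "f", digits = decimals)
}

#' Permutation enrichment of annotation tracks in a region set
#'
#' Counts, for each annotation track, the elements overlapping the query
#' region set, then compares against a single shared null ensemble of
#' `n_iter` random region sets preserving the query's region count and
#' width multiset (see [make_null_ensemble()]): within one iteration every
#' track is evaluated against the same random set. Per track the result
#' reports the observed count, the null mean and sample SD (n-1
#' denominator), the percent of iterations with the same or a larger count,
#' and the empirical p-value.
#'
#' Rerunning with the same `seed` reproduces every null count bit-exactly.
#'
#' @param query Query region set (`GRanges`, non-empty) on the model
#'   chromosome.
#' @param tracks A named list of annotation tracks (`GRanges`), or a single
#'   track.
#' @param model A [chromosome_model()].
#' @param n_iter Number of null iterations (default 1000).
#' @param seed Root seed for the null ensemble (default 1000).
#' @param conservative Report `(k+1)/(n+1)` instead of `k/n`.
#' @inheritParams sample_region_set
#' @return A data.frame of class `track_enrichment`, one row per track,
#'   with columns `track`, `observed`, `null_mean`, `null_sd`, `pct_ge`,
#'   `p_emp`, `p_label`, `n_iter`, `seed`; the per-iteration null count
#'   matrix is attached as `attr(, "null_counts")`.
#' @export
run_track_enrichment <- function(query, tracks, model, n_iter = 1000,
                                 seed = 1000, max_attempts = 10000L,
                                 allow_overlap = FALSE, conservative = FALSE) {
  stopifnot(is(query, "GRanges"), inherits(model, "chromosome_model"),
            .is_count(n_iter), n_iter >= 1)
  if (length(query) == 0L) .stopf("query region set is empty")
  if (is(tracks, "GRanges")) tracks <- list(tracks)
  if (length(tracks) == 0L) .stopf("at least one annotation track is required")
  nm <- names(tracks)
  if (is.null(nm)) nm <- rep(NA_character_, length(tracks))
  for (t in seq_along(tracks)) {
    if (is.na(nm[t]) || nm[t] == "") {
      mt <- metadata(tracks[[t]])$track_name
      nm[t] <- if (is.null(mt)) sprintf("track%d", t) else mt
    }
  }

  observed <- vapply(tracks, function(tr) {
    count_overlapping_elements(tr, query)$count
  }, integer(1))

  widths <- width(sort(query))
  track_ir <- lapply(tracks, .track_as_iranges, chrom = model$name)
  ex_s <- start(model$exclusions)
  ex_e <- end(model$exclusions)

  null_counts <- matrix(0L, nrow = n_iter, ncol = length(tracks),
                        dimnames = list(NULL, nm))
  for (i in seq_len(n_iter)) {
    set.seed(.iter_seed(seed, i))
    pl <- .place_regions(model$length, widths, excl_start = ex_s,
                         excl_end = ex_e, max_attempts = max_attempts,
                         allow_overlap = allow_overlap)
    for (t in seq_along(track_ir)) {
      null_counts[i, t] <- .count_elements_ir(pl$start, pl$end, track_ir[[t]])
    }
  }

  stats <- lapply(seq_along(tracks), function(t) {
    ep <- empirical_p(observed[t], null_counts[, t], conservative = conservative)
    data.frame(track = nm[t], observed = observed[t],
               null_mean = mean(null_counts[, t]),
               null_sd = sd(null_counts[, t]),
               pct_ge = ep$pct_ge, p_emp = ep$p_emp,
               p_label = format_p(ep$p_emp, 2, n = if (conservative) NULL else ep$n),
               n_iter = as.integer(n_iter), seed = as.integer(seed),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, stats)
  rownames(res) <- NULL
  attr(res, "null_counts") <- null_counts
  class(res) <- c("track_enrichment", "data.frame")
  res
}

#' @export
print.track_enrichment <- function(x, digits = 3, ...) {
  cat(sprintf("Permutation enrichment: %d track(s), %d iteration(s), seed %d\n\n",
              nrow(x), x$n_iter[1], x$seed[1]))
  df <- data.frame(track = x$track, observed = x$observed,
                   null_mean = .round_half_away(x$null_mean, 1),
                   null_sd = .round_half_away(x$null_sd, 1),
                   `pct_ge` = .round_half_away(x$pct_ge, 1),
                   p = x$p_label, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Report-shaped enrichment table
#'
#' Lays out the query-set summary and the permutation results as the
#' familiar published table: one column block for the region-set geometry
#' (n, mean kb, DNA Mb) and one column per track; rows for the observed
#' set, the random-set means, their SDs, the percent of iterations with the
#' same or a larger count, and the empirical p-value.
#'
#' @param query Query region set (`GRanges`).
#' @param result A `track_enrichment` from [run_track_enrichment()].
#' @param set_label Row label for the query set.
#' @return A character data.frame.
#' @export
enrichment_table <- function(query, result, set_label = "query set") {
  stopifnot(inherits(result, "track_enrichment"))
  s <- summarize_region_set(query)
  nc <- attr(result, "null_counts")
  n_iter <- result$n_iter[1]
  fmt1 <- function(v) formatC(.round_half_away(v, 1), format = "f", digits = 1)
  base_cols <- data.frame(
    set = c(set_label, "SD", "random sets", "SD", "% >= observed", "p value"),
    regions_n = c(s$n_regions, "-", fmt1(s$n_regions), "-", "-", "-"),
    regions_kb = c(fmt1(s$mean_width_kb), fmt1(s$width_sd_kb),
                   fmt1(s$mean_width_kb), "-", "-", "-"),
    dna_mb = c(fmt1(s$total_width_mb), "-", fmt1(s$total_width_mb), "-", "-", "-"),
    stringsAsFactors = FALSE)
  for (t in seq_len(nrow(result))) {
    base_cols[[result$track[t]]] <- c(
      as.character(result$observed[t]), "-",
      fmt1(mean(nc[, t])), fmt1(sd(nc[, t])),
      fmt1(result$pct_ge[t]), result$p_label[t])
  }
  base_cols
}
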