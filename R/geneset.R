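# Bootstrap gene-set enrichment: are association candidates enriched in a
# curated list of differentially methylated genes?
#
# The null resamples candidate-set-sized gene draws from the universe; the
# empirical p is the fraction of draws whose overlap with the curated list
# is the same as or larger than the observed overlap. Without replacement
# (the default) this converges to the hypergeometric tail P(X >= observed).

#' Bootstrap gene-set enrichment test
#'
#' Gene symbols are case-normalized (upper case, trimmed) and deduplicated.
#' Candidate or curated genes absent from the universe are dropped with a
#' warning before testing.
#'
#' @param candidates Character vector of candidate gene symbols (e.g. genes
#'   pinpointed by suggestive association signals).
#' @param curated Character vector of curated gene symbols (e.g.
#'   differentially methylated genes; see [curated_dmg_genes()]).
#' @param universe Character vector of all eligible gene symbols.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Integer seed (default 1000).
#' @param replace Draw with replacement instead of without. Off by default:
#'   resampling set membership without replacement matches the
#'   hypergeometric null for a fixed-size gene set.
#' @return An object of class `geneset_enrichment`: list with
#'   `n_candidates`, `n_curated`, `n_universe`, `observed_overlap`,
#'   `pct_ge`, `p_emp`, `n_iter`, `seed` and the per-iteration
#'   `null_overlaps`.
#' @examples
#' res <- geneset_bootstrap(c("g1", "g2", "g3"), c("g1", "g9"),
#'                          paste0("g", 1:50), n_iter = 200, seed = 7)
#' res$p_emp
#' @export
geneset_bootstrap <- function(candidates, curated, universe, n_iter = 1000,
                              seed = 1000, replace = FALSE) {
  stopifnot(is.character(candidates), is.character(curated),
            is.character(universe), .is_count(n_iter), n_iter >= 1)
  norm <- function(x) unique(toupper(trimws(x)))
  candidates <- norm(candidates)
  curated <- norm(curated)
  universe <- norm(universe)
  if (length(universe) == 0L) .stopf("gene universe is empty")

  out_cand <- setdiff(candidates, universe)
  if (length(out_cand)) {
    .warnf("dropping %d candidate gene(s) not in the universe: %s",
           length(out_cand), paste(out_cand, collapse = ", "))
    candidates <- intersect(candidates, universe)
  }
  out_cur <- setdiff(curated, universe)
  if (length(out_cur)) {
    .warnf("dropping %d curated gene(s) not in the universe: %s",
           length(out_cur), paste(out_cur, collapse = ", "))
    curated <- intersect(curated, universe)
  }
  m <- length(candidates)
  if (m == 0L) .stopf("no candidate genes remain after universe filtering")
  if (!replace && m > length(universe)) {
    .stopf("cannot draw %d genes without replacement from a universe of %d",
           m, length(universe))
  }

  observed <- length(intersect(candidates, curated))
  in_curated <- universe %in% curated
  n_u <- length(universe)

  set.seed(as.integer(seed))
  null_overlaps <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    idx <- sample.int(n_u, m, replace = replace)
    null_overlaps[i] <- if (replace) {
      # a gene drawn twice still counts once toward the overlap
      sum(in_curated[unique(idx)])
    } else {
      sum(in_curated[idx])
    }
  }
  ep <- empirical_p(observed, null_overlaps)
  structure(list(n_candidates = m, n_curated = length(curated),
                 n_universe = n_u, observed_overlap = observed,
                 pct_ge = ep$pct_ge, p_emp = ep$p_emp,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 replace = replace, null_overlaps = null_overlaps),
            class = "geneset_enrichment")
}

#' @export
print.geneset_enrichment <- function(x, ...) {
  cat(sprintf(paste0("Bootstrap gene-set enrichment (%d iterations, seed %d)\n",
                     "  candidates: %d   curated: %d   universe: %d\n",
                     "  observed overlap: %d   null mean: %.2f\n",
                     "  p (same or larger overlap): %s\n"),
              x$n_iter, x$seed, x$n_candidates, x$n_curated, x$n_universe,
              x$observed_overlap, mean(x$null_overlaps),
              format_p(x$p_emp, 3, n = x$n_iter)))
  invisible(x)
}

#' Curated differentially methylated genes
#'
#' The nine-gene curated list of differentially methylated genes in primary
#' biliary cholangitis that ships with the package, for use as the
#' `curated` argument of [geneset_bootstrap()].
#'
#' @return Character vector of gene symbols.
#' @export
curated_dmg_genes <- function() {
  path <- system.file("extdata", "pbc_dmg_curated_genes.txt",
                      package = "xregenrich", mustWork = TRUE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines[lines != "" & !grepl("^#", lines)]
}
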