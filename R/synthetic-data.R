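# Synthetic chromosomes, annotation tracks, SNP tables and gene universes
# with exactly planted truths, so every pipeline stage can be tested
# end-to-end without any external download.
#
# All generators are pure functions of (scenario, seed): each draws from a
# deterministic substream keyed by the scenario seed and a per-generator
# counter, so generators can be called in any order and reproduce exactly.
# Planted truths are enforced, not merely expected: the query set has
# exactly n_query_regions regions summing exactly to query_total_width,
# tracks have exact element counts, and the candidate/curated gene overlap
# is exactly planted_overlap.

#' Annotation-track specification for the synthetic generator
#'
#' @param element_class Element class label.
#' @param n_elements Exact number of elements to generate.
#' @param width_min,width_max Uniform integer width range in bases
#'   (point-like for miRNAs, broad for superenhancers).
#' @param enrichment_fold Relative midpoint density inside query regions:
#'   `1` is the null (uniform), `0` plants depletion to absence, `>1`
#'   plants enrichment.
#' @param name Track name; defaults to the element class.
#' @return A list of class `track_spec`.
#' @export
track_spec <- function(element_class, n_elements, width_min, width_max,
                       enrichment_fold = 1, name = element_class) {
  stopifnot(is.character(element_class), .is_count(n_elements),
            .is_count(width_min), .is_count(width_max),
            width_min >= 1, width_min <= width_max,
            is.numeric(enrichment_fold), enrichment_fold >= 0)
  structure(list(element_class = element_class,
                 n_elements = as.integer(n_elements),
                 width_min = as.integer(width_min),
                 width_max = as.integer(width_max),
                 enrichment_fold = enrichment_fold,
                 name = name),
            class = "track_spec")
}

# Default tracks: element counts chosen so that, at the default 62-region /
# 9.3 Mb query on a 155 Mb chromosome, the expected null overlap count
# n_el * (W_query + n_regions * mean_width) / L lands at the scale typical
# of chrX non-coding annotation (tens of lncRNAs, hundreds of circRNAs and
# superenhancers, ~10 miRNAs overlapping a ~6% query).
.default_track_specs <- function() {
  list(lncRNA = track_spec("lncRNA", 280, 200, 60000),
       circRNA = track_spec("circRNA", 2900, 200, 5000),
       miRNA = track_spec("miRNA", 160, 22, 100),
       superenhancer = track_spec("superenhancer", 5100, 10000, 50000))
}

#' Synthetic analysis scenario
#'
#' Bundles every parameter of the synthetic data generators. Defaults
#' emulate the geometry of a chrX association query: a 155 Mb chromosome
#' carrying 62 disjoint query regions totaling exactly 9.3 Mb, four
#' annotation tracks at the null (`enrichment_fold = 1`), a 500-SNP
#' association table with 5 planted signal clusters, and an 800-gene
#' universe with a planted candidate/curated overlap of 2.
#'
#' @param seed Integer root seed; every generator derives its substream
#'   from it.
#' @param chrom_name,chrom_length Chromosome name and length in bases.
#' @param exclusion_fraction Fraction of the chromosome covered by
#'   exclusion zones (must be `< 1`; default 0).
#' @param n_exclusions Number of exclusion intervals when
#'   `exclusion_fraction > 0`.
#' @param n_query_regions,query_total_width Exact region count and exact
#'   total width (bases) of the generated query set.
#' @param width_shape Gamma shape for query-region width draws (shape 1.65
#'   reproduces a width coefficient of variation around 0.78, i.e. an SD
#'   near 117 kb at a 150 kb mean).
#' @param track_specs Named list of [track_spec()] objects.
#' @param snp_spec List with `n_snps` (total), `n_signal_clusters`,
#'   `snps_per_cluster` and `signal_p_scale` (signal p-values are uniform
#'   on `(0, 5e-4 * signal_p_scale)`).
#' @param gene_spec List with `n_universe`, `n_curated`, `n_candidates`,
#'   `planted_overlap`.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1000,
                               chrom_name = "chrX",
                               chrom_length = 155e6,
                               exclusion_fraction = 0,
                               n_exclusions = 10,
                               n_query_regions = 62,
                               query_total_width = 9.3e6,
                               width_shape = 1.65,
                               track_specs = .default_track_specs(),
                               snp_spec = list(n_snps = 500,
                                               n_signal_clusters = 5,
                                               snps_per_cluster = 10,
                                               signal_p_scale = 1),
                               gene_spec = list(n_universe = 800,
                                                n_curated = 9,
                                                n_candidates = 20,
                                                planted_overlap = 2)) {
  stopifnot(.is_count(chrom_length), chrom_length >= 1,
            is.numeric(exclusion_fraction), exclusion_fraction >= 0,
            .is_count(n_query_regions),
            .is_count(query_total_width),
            query_total_width < chrom_length,
            width_shape > 0)
  if (exclusion_fraction >= 1) .stopf("exclusion_fraction must be < 1")
  structure(list(seed = as.integer(seed), chrom_name = chrom_name,
                 chrom_length = as.integer(chrom_length),
                 exclusion_fraction = exclusion_fraction,
                 n_exclusions = as.integer(n_exclusions),
                 n_query_regions = as.integer(n_query_regions),
                 query_total_width = as.integer(query_total_width),
                 width_shape = width_shape,
                 track_specs = track_specs,
                 snp_spec = snp_spec, gene_spec = gene_spec),
            class = "synthetic_scenario")
}

# Generator substream counters; >= 1e6 so they never coincide with null-
# ensemble iteration substreams at equal root seeds.
.GEN_CHROM <- 1000001
.GEN_QUERY <- 1000002
.GEN_SNP <- 1000003
.GEN_GENE <- 1000004
.GEN_TRACK_BASE <- 2000000

#' Generate the chromosome model of a scenario
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [chromosome_model()]; when `exclusion_fraction > 0`, disjoint
#'   exclusion intervals covering exactly
#'   `round(exclusion_fraction * chrom_length)` bases.
#' @export
make_chromosome <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  L <- scenario$chrom_length
  if (scenario$exclusion_fraction == 0) {
    return(chromosome_model(scenario$chrom_name, L))
  }
  set.seed(.iter_seed(scenario$seed, .GEN_CHROM))
  total <- round(scenario$exclusion_fraction * L)
  k <- max(1L, min(scenario$n_exclusions, total))
  prop <- rgamma(k, shape = 2)
  w <- pmax(1L, as.integer(floor(prop / sum(prop) * total)))
  w[k] <- w[k] + (total - sum(w))
  if (w[k] < 1L) {
    j <- which.max(w[-k])
    w[j] <- w[j] + (w[k] - 1L)
    w[k] <- 1L
  }
  pl <- .place_regions(L, w)
  excl <- sort(GRanges(scenario$chrom_name, IRanges(pl$start, pl$end)))
  chromosome_model(scenario$chrom_name, L, exclusions = excl)
}

#' Generate the query region set of a scenario
#'
#' Widths are drawn from a gamma distribution and rescaled to sum exactly
#' to `query_total_width` (only the final width absorbs the rounding
#' residue, keeping the others distribution-faithful); regions are then
#' placed disjointly and uniformly, avoiding exclusions, with the same
#' placement routine the null sampler uses.
#'
#' @param scenario A [synthetic_scenario()].
#' @param model The matching [chromosome_model()] (defaults to
#'   `make_chromosome(scenario)`).
#' @return A sorted, disjoint, named `GRanges` with exactly
#'   `n_query_regions` regions totaling exactly `query_total_width` bases.
#' @export
make_query_regions <- function(scenario, model = make_chromosome(scenario)) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(model, "chromosome_model"))
  n <- scenario$n_query_regions
  total <- scenario$query_total_width
  if (n < 1L) .stopf("n_query_regions must be >= 1")
  set.seed(.iter_seed(scenario$seed, .GEN_QUERY))
  if (n == 1L) {
    w <- total
  } else {
    g <- rgamma(n, shape = scenario$width_shape)
    w <- pmax(1L, as.integer(floor(g / sum(g) * total)))
    w[n] <- w[n] + (total - sum(w))
    if (w[n] < 1L) {
      j <- which.max(w[-n])
      w[j] <- w[j] + (w[n] - 1L)
      w[n] <- 1L
    }
  }
  if (sum(w) != total || any(w < 1L)) {
    .stopf("infeasible query geometry: %d regions cannot total %d bases", n, total)
  }
  pl <- .place_regions(model$length, w,
                       excl_start = start(model$exclusions),
                       excl_end = end(model$exclusions))
  gr <- sort(GRanges(model$name, IRanges(pl$start, pl$end)))
  names(gr) <- sprintf("query_%03d", seq_along(gr))
  gr
}

# Is each (sorted) position inside the sorted disjoint region set?
.inside_regions <- function(pos, r_start, r_end) {
  if (length(r_start) == 0L) return(rep(FALSE, length(pos)))
  j <- findInterval(pos, r_start)
  j > 0L & pos <= r_end[pmax(j, 1L)]
}

#' Generate a synthetic annotation track
#'
#' Element midpoints are drawn from a two-component density: uniform over
#' the chromosome with relative weight 1 outside the query regions and
#' weight `enrichment_fold` inside, so the expected in-query midpoint
#' fraction is `f*Wq / (f*Wq + (L - Wq))` -- exactly `Wq/L` at the null.
#' Widths are uniform integers in the track specification's range;
#' elements are clipped to
#' the chromosome, and under `enrichment_fold = 0` additionally clipped to
#' the inter-region gap holding their midpoint so that planted depletion is
#' exact (zero overlapping elements).
#'
#' @param scenario A [synthetic_scenario()].
#' @param model The matching [chromosome_model()].
#' @param query The query region set the enrichment is planted against.
#' @param spec A [track_spec()]; one of `scenario$track_specs` or custom.
#' @return A sorted, named `GRanges` with `metadata()` fields `track_name`
#'   and `element_class`, and a `midpoint` metadata column holding the
#'   drawn (pre-clipping) midpoints.
#' @export
make_annotation_track <- function(scenario, model, query, spec) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(model, "chromosome_model"),
            is(query, "GRanges"), inherits(spec, "track_spec"))
  n <- spec$n_elements
  prefix <- c(lncRNA = "lnc", circRNA = "circ", miRNA = "mir",
              superenhancer = "se")[spec$element_class]
  if (is.na(prefix)) prefix <- "elem"
  mk_meta <- function(gr) {
    metadata(gr) <- list(track_name = spec$name,
                         element_class = spec$element_class)
    gr
  }
  if (n == 0L) return(mk_meta(GRanges()))

  set.seed(.iter_seed(scenario$seed,
                      .GEN_TRACK_BASE + sum(utf8ToInt(spec$name))))
  L <- model$length
  query <- sort(query)
  r_start <- start(query)
  r_end <- end(query)
  Wq <- sum(width(query))
  f <- spec$enrichment_fold
  q_in <- if (Wq == 0L) 0 else f * Wq / (f * Wq + (L - Wq))

  inside <- runif(n) < q_in
  mid <- integer(n)
  n_in <- sum(inside)
  if (n_in > 0L) {
    # uniform over query bases: offset into the concatenated regions
    cw <- cumsum(width(query))
    o <- sample.int(Wq, n_in, replace = TRUE)
    ridx <- findInterval(o - 0.5, c(0, cw))
    mid[inside] <- r_start[ridx] + (o - c(0L, cw)[ridx] - 1L)
  }
  n_out <- n - n_in
  if (n_out > 0L) {
    pos <- integer(0)
    while (length(pos) < n_out) {
      cand <- sample.int(L, n_out - length(pos), replace = TRUE)
      pos <- c(pos, cand[!.inside_regions(cand, r_start, r_end)])
    }
    mid[!inside] <- pos
  }

  w <- sample.int(spec$width_max - spec$width_min + 1L, n, replace = TRUE) +
    spec$width_min - 1L
  s <- pmax(1L, mid - w %/% 2L)
  e <- pmin(L, s + w - 1L)
  if (f == 0 && length(r_start) > 0L) {
    # clip boundary-straddling elements to the gap holding their midpoint
    g_start <- c(1L, r_end + 1L)
    g_end <- c(r_start - 1L, L)
    gi <- findInterval(mid, g_start)
    s <- pmax(s, g_start[gi])
    e <- pmin(e, g_end[gi])
  }

  gr <- GRanges(model$name, IRanges(s, e))
  names(gr) <- sprintf("%s_%05d", prefix, seq_len(n))
  mcols(gr)$midpoint <- mid
  mk_meta(sort(gr))
}

#' Generate a synthetic SNP association table
#'
#' Background SNPs get uniform positions and `Uniform(0,1)` p-values;
#' signal clusters are positionally tight (within a 50 kb window around
#' centers at least 1 Mb apart) with p-values uniform on
#' `(0, 5e-4 * signal_p_scale)`, i.e. below the nominal inclusion threshold
#' at the default scale.
#'
#' @param scenario A [synthetic_scenario()].
#' @param model The matching [chromosome_model()].
#' @return A data.frame with columns `snp_id`, `chrom`, `pos`, `p`, ordered
#'   by position.
#' @export
make_snp_table <- function(scenario, model = make_chromosome(scenario)) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(model, "chromosome_model"))
  sp <- scenario$snp_spec
  n_sig <- sp$n_signal_clusters * sp$snps_per_cluster
  if (n_sig > sp$n_snps) {
    .stopf("signal SNPs (%d) exceed n_snps (%d)", n_sig, sp$n_snps)
  }
  set.seed(.iter_seed(scenario$seed, .GEN_SNP))
  L <- model$length
  n_bg <- sp$n_snps - n_sig

  pos <- sample.int(L, n_bg, replace = TRUE)
  p <- runif(n_bg)

  if (sp$n_signal_clusters > 0L) {
    margin <- 100000L
    att <- 0L
    repeat {
      att <- att + 1L
      centers <- sample.int(L - 2L * margin, sp$n_signal_clusters) + margin
      if (sp$n_signal_clusters == 1L || min(diff(sort(centers))) >= 1e6) break
      if (att > 1000L) .stopf("could not place %d signal clusters 1 Mb apart",
                              sp$n_signal_clusters)
    }
    for (ctr in centers) {
      cpos <- ctr + sample.int(50001L, sp$snps_per_cluster, replace = TRUE) - 25001L
      pos <- c(pos, cpos)
      p <- c(p, runif(sp$snps_per_cluster) * 5e-4 * sp$signal_p_scale)
    }
  }

  ord <- order(pos)
  data.frame(snp_id = sprintf("rs%06d", seq_along(pos)),
             chrom = model$name, pos = pos[ord], p = p[ord],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic gene universe with a planted overlap
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `universe`, `curated` and `candidates` such that
#'   `length(intersect(candidates, curated))` equals `planted_overlap`
#'   exactly.
#' @export
make_gene_universe <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  gs <- scenario$gene_spec
  if (gs$n_curated > gs$n_universe || gs$n_candidates > gs$n_universe) {
    .stopf("curated/candidate list sizes exceed the universe")
  }
  if (gs$planted_overlap > min(gs$n_curated, gs$n_candidates)) {
    .stopf("planted_overlap %d exceeds min(n_curated, n_candidates)",
           gs$planted_overlap)
  }
  if (gs$n_candidates - gs$planted_overlap > gs$n_universe - gs$n_curated) {
    .stopf("not enough non-curated genes for %d overlap-free candidates",
           gs$n_candidates - gs$planted_overlap)
  }
  set.seed(.iter_seed(scenario$seed, .GEN_GENE))
  universe <- sprintf("GENE%04d", seq_len(gs$n_universe))
  curated <- sample(universe, gs$n_curated)
  candidates <- c(sample(curated, gs$planted_overlap),
                  sample(setdiff(universe, curated),
                         gs$n_candidates - gs$planted_overlap))
  list(universe = universe, curated = curated,
       candidates = sample(candidates))
}
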