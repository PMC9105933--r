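# Interval containers and the overlap-counting statistic.
#
# Region sets and annotation tracks are plain GRanges objects: a region set
# is a sorted, named GRanges; an annotation track is a GRanges whose names()
# are the element ids (unique within the track), with the track label and
# element class kept in metadata(). Coordinates are Bioconductor-native
# 1-based closed internally; BED files are 0-based half-open and conversion
# happens only in read_bed()/write_bed(), so BED round-trips are bit-exact.
# Under either convention two intervals overlap iff they share >= 1 base;
# book-ended intervals do not overlap (but do merge in merge_intervals()).

#' Read a BED3/BED4 file as an annotation track
#'
#' Parses a tab-separated BED file (0-based half-open coordinates) into a
#' sorted, named `GRanges`. Lines starting with `#`, `track` or `browser`,
#' and blank lines, are skipped; both LF and CRLF line endings are accepted.
#' Elements without a name column get a synthesized id `"chrom:start-end"`
#' (BED coordinates); coordinate-identical unnamed duplicates are
#' disambiguated with [make.unique()] suffixes. Explicitly duplicated names
#' are an error, since element ids must be unique within a track.
#'
#' @param path Path to a BED file.
#' @param track_name Label for the track; defaults to the file name.
#' @param element_class One of `"lncRNA"`, `"circRNA"`, `"miRNA"`,
#'   `"superenhancer"`, `"other"`.
#' @return A `GRanges`, sorted, with element ids as `names()` and
#'   `metadata()` fields `track_name` and `element_class`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chrX\t100\t200\telemA", bed)
#' read_bed(bed, "demo")
#' @export
read_bed <- function(path, track_name = NULL,
                     element_class = c("other", "lncRNA", "circRNA",
                                       "miRNA", "superenhancer")) {
  element_class <- match.arg(element_class)
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  if (is.null(track_name)) track_name <- basename(path)

  raw <- sub("\r$", "", readLines(path, warn = FALSE))
  is_data <- !(raw == "" | grepl("^#", raw) | grepl("^(track|browser)([ \t]|$)", raw))
  idx <- which(is_data)

  if (length(idx) == 0L) {
    gr <- GRanges()
    metadata(gr) <- list(track_name = track_name, element_class = element_class)
    return(gr)
  }

  fields <- strsplit(raw[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    .stopf("malformed BED line %d in %s: fewer than 3 tab-separated fields",
           idx[which(nf < 3L)[1L]], path)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s_raw <- vapply(fields, `[[`, character(1), 2L)
  e_raw <- vapply(fields, `[[`, character(1), 3L)
  s <- suppressWarnings(as.numeric(s_raw))
  e <- suppressWarnings(as.numeric(e_raw))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e) | s < 0 | s >= e
  if (any(bad)) {
    j <- which(bad)[1L]
    .stopf("malformed BED line %d in %s: '%s\t%s' is not a valid 0-based half-open interval",
           idx[j], path, s_raw[j], e_raw[j])
  }

  ids <- character(length(idx))
  named <- nf >= 4L
  ids[named] <- vapply(fields[named], `[[`, character(1), 4L)
  ids[!named] <- sprintf("%s:%d-%d", chrom[!named], as.integer(s[!named]),
                         as.integer(e[!named]))
  if (anyDuplicated(ids[named])) {
    .stopf("duplicated element id '%s' in %s: ids must be unique within a track",
           ids[named][duplicated(ids[named])][1L], path)
  }
  ids <- make.unique(ids, sep = ".")

  gr <- GRanges(chrom, IRanges(start = s + 1, end = e))
  names(gr) <- ids
  gr <- sort(gr)
  metadata(gr) <- list(track_name = track_name, element_class = element_class)
  gr
}

#' Write a region set or annotation track as BED
#'
#' Emits sorted, tab-separated, newline-terminated BED lines with 0-based
#' half-open coordinates: BED4 when the object has `names()`, BED3
#' otherwise. An empty object yields an empty file.
#'
#' @param x A `GRanges` (region set or annotation track).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (!is(x, "GRanges")) .stopf("write_bed() expects a GRanges")
  x <- sort(x)
  if (length(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  chrom <- as.character(seqnames(x))
  s <- format(start(x) - 1, scientific = FALSE, trim = TRUE)
  e <- format(end(x), scientific = FALSE, trim = TRUE)
  lines <- if (is.null(names(x))) {
    paste(chrom, s, e, sep = "\t")
  } else {
    paste(chrom, s, e, names(x), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge overlapping or book-ended intervals
#'
#' Unions intervals on the same chromosome that overlap or are book-ended
#' (the end of one equals the start of the next in half-open coordinates),
#' optionally bridging gaps up to `merge_gap` bases. Idempotent; the covered
#' base count of already-disjoint input is invariant.
#'
#' @param regions A `GRanges`.
#' @param merge_gap Maximum gap (bases) bridged when merging; `0` merges
#'   only overlapping or book-ended intervals.
#' @return A sorted, disjoint `GRanges` named `region_001`, `region_002`, ...
#' @export
merge_intervals <- function(regions, merge_gap = 0) {
  if (!is(regions, "GRanges")) .stopf("merge_intervals() expects a GRanges")
  stopifnot(.is_count(merge_gap))
  out <- reduce(sort(regions), min.gapwidth = merge_gap + 1)
  if (length(out) > 0L) {
    names(out) <- sprintf("region_%03d", seq_along(out))
  }
  out
}

#' Count annotation elements overlapping a region set
#'
#' An element is counted when it shares at least one base with at least one
#' query region ("partially or totally overlapping"); an element touching
#' several regions is counted once, deduplicated by element id. Book-ended
#' element/region pairs do not overlap. Elements on chromosomes absent from
#' the region set contribute zero.
#'
#' @param track Annotation track (`GRanges` with element ids as `names()`).
#' @param regions Query region set (`GRanges`).
#' @param track_name Optional label; defaults to the track's
#'   `metadata()$track_name`.
#' @return An object of class `overlap_count`: a list with `track_name`,
#'   `count` and `element_ids` (`count == length(element_ids)`).
#' @export
count_overlapping_elements <- function(track, regions, track_name = NULL) {
  if (!is(track, "GRanges") || !is(regions, "GRanges")) {
    .stopf("count_overlapping_elements() expects GRanges inputs")
  }
  if (is.null(track_name)) {
    track_name <- metadata(track)$track_name
    if (is.null(track_name)) track_name <- "track"
  }
  # disjoint chromosome namespaces are a supported zero-count case, not a
  # condition worth Bioconductor's no-common-seqlevels warning
  hit <- suppressWarnings(countOverlaps(track, regions)) > 0L
  ids <- names(track)
  if (is.null(ids)) {
    ids <- sprintf("%s:%d-%d", as.character(seqnames(track)),
                   start(track) - 1L, end(track))
  }
  element_ids <- unique(ids[hit])
  structure(list(track_name = track_name,
                 count = length(element_ids),
                 element_ids = element_ids),
            class = "overlap_count")
}

#' @export
print.overlap_count <- function(x, ...) {
  cat(sprintf("<overlap_count> track '%s': %d element(s) overlapping\n",
              x$track_name, x$count))
  invisible(x)
}

# Fast single-chromosome counting used inside the permutation loop: regions
# as bare start/end vectors, track pre-converted to an IRanges.
.count_elements_ir <- function(r_start, r_end, track_ir) {
  if (length(track_ir) == 0L || length(r_start) == 0L) return(0L)
  sum(countOverlaps(track_ir, IRanges(r_start, r_end)) > 0L)
}

# Restrict a track to one chromosome and strip to an IRanges.
.track_as_iranges <- function(track, chrom) {
  keep <- as.character(seqnames(track)) == chrom
  IRanges(start(track)[keep], end(track)[keep])
}
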