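#' Aligned region (HSP) of a homology-search hit
#'
#' Coordinates are 0-based half-open throughout the package; BED output is
#' native in this convention.
#'
#' @param query_start,query_end Query span (0-based half-open).
#' @param subject_start,subject_end Subject span (0-based half-open,
#'   always on the forward subject coordinate system).
#' @param identity_fraction Fraction of identical aligned columns,
#'   computed over non-gap, non-ambiguous columns.
#' @param length_nt Subject-side span length in nucleotides.
#' @param strand \code{"+"} or \code{"-"}: subject strand of the match.
#' @param score Raw alignment score (used for tie-breaking).
#' @param evalue Optional per-region expectation value.
#' @return An object of class \code{aligned_region}.
#' @export
aligned_region <- function(query_start, query_end, subject_start, subject_end,
                           identity_fraction, length_nt, strand = "+",
                           score = NA_real_, evalue = NA_real_) {
  stopifnot(query_end > query_start, subject_end > subject_start,
            identity_fraction >= 0, identity_fraction <= 1,
            length_nt > 0, strand %in% c("+", "-"))
  structure(list(
    query_span = c(query_start, query_end),
    subject_span = c(subject_start, subject_end),
    identity_fraction = identity_fraction,
    length_nt = as.integer(length_nt),
    strand = strand,
    score = score,
    evalue = evalue
  ), class = "aligned_region")
}

#' Homology-search hit: one query/subject pair with its aligned regions
#'
#' @param query_id,subject_id Sequence identifiers.
#' @param evalue Expectation value of the best region; must be > 0.
#' @param regions List of \code{\link{aligned_region}} objects; stored
#'   sorted by subject start.
#' @return An object of class \code{search_hit}.
#' @export
search_hit <- function(query_id, subject_id, evalue, regions) {
  stopifnot(is.numeric(evalue), length(evalue) == 1L, evalue > 0,
            length(regions) >= 1L)
  ok <- vapply(regions, inherits, logical(1), "aligned_region")
  if (!all(ok)) stop("regions must be aligned_region objects")
  starts <- vapply(regions, function(r) r$subject_span[1], numeric(1))
  structure(list(
    query_id = query_id,
    subject_id = subject_id,
    evalue = evalue,
    regions = regions[order(starts)]
  ), class = "search_hit")
}

#' Sort hits deterministically
#'
#' Hits ordered by (evalue, subject id, first subject start) so that
#' outputs are reproducible across runs and platforms.
#'
#' @param hits List of \code{search_hit} objects.
#' @return The same list, sorted.
#' @export
sort_hits <- function(hits) {
  if (length(hits) == 0L) return(hits)
  ev <- vapply(hits, `[[`, numeric(1), "evalue")
  sid <- vapply(hits, `[[`, character(1), "subject_id")
  st <- vapply(hits, function(h) h$regions[[1]]$subject_span[1], numeric(1))
  hits[order(ev, sid, st)]
}

#' Number of distinct aligned regions in a hit
#' @param hit A \code{search_hit}.
#' @return Integer count of regions.
#' @export
n_regions <- function(hit) length(hit$regions)

#' Flatten a list of hits to a data frame
#'
#' One row per aligned region, in the field order of BLAST-style tabular
#' output where applicable.
#'
#' @param hits List of \code{search_hit} objects.
#' @return A data frame.
#' @export
hits_to_df <- function(hits) {
  if (length(hits) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), region = integer(),
                      query_start = numeric(), query_end = numeric(),
                      subject_start = numeric(), subject_end = numeric(),
                      identity_fraction = numeric(), length_nt = integer(),
                      strand = character(), score = numeric()))
  }
  do.call(rbind, lapply(hits, function(h) {
    do.call(rbind, lapply(seq_along(h$regions), function(i) {
      r <- h$regions[[i]]
      data.frame(query_id = h$query_id, subject_id = h$subject_id,
                 evalue = h$evalue, region = i,
                 query_start = r$query_span[1], query_end = r$query_span[2],
                 subject_start = r$subject_span[1], subject_end = r$subject_span[2],
                 identity_fraction = r$identity_fraction, length_nt = r$length_nt,
                 strand = r$strand, score = r$score)
    }))
  }))
}

#' Split grouped hits into one hit per aligned region
#'
#' The engines group all regions of a query/subject pair into one hit,
#' which is what presence/absence classification wants ("multiple
#' regions of alignment"). The duplication screen instead treats every
#' aligned region as a separate candidate locus; this helper performs
#' that split, using per-region E-values where recorded (falling back
#' to the parent hit's E-value).
#'
#' @param hits List of \code{search_hit}s.
#' @return List of single-region \code{search_hit}s, sorted.
#' @export
split_hits <- function(hits) {
  out <- list()
  for (h in hits) {
    for (r in h$regions) {
      ev <- if (is.na(r$evalue)) h$evalue else r$evalue
      out[[length(out) + 1L]] <- search_hit(h$query_id, h$subject_id,
                                            evalue = ev, regions = list(r))
    }
  }
  sort_hits(out)
}

#' Read hits from a BLAST-style 12+ column tabular file
#'
#' Accepts the conventional outfmt-6 column order (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore). One-based inclusive input coordinates are converted to the
#' package's 0-based half-open convention; sstart > send encodes a
#' minus-strand match. Rows sharing (qseqid, sseqid) are merged into one
#' hit whose E-value is the best row E-value.
#'
#' @param path Path to the tabular file.
#' @return A list of \code{search_hit} objects, deterministically sorted.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("tabular hit file does not exist: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected >= 12 tab-separated columns, got ", ncol(tab))
  names(tab)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")
  key <- paste(tab$qseqid, tab$sseqid, sep = "\r")
  hits <- lapply(split(tab, key), function(d) {
    regions <- lapply(seq_len(nrow(d)), function(i) {
      minus <- d$sstart[i] > d$send[i]
      s0 <- if (minus) d$send[i] else d$sstart[i]
      s1 <- if (minus) d$sstart[i] else d$send[i]
      aligned_region(query_start = d$qstart[i] - 1L, query_end = d$qend[i],
                     subject_start = s0 - 1L, subject_end = s1,
                     identity_fraction = d$pident[i] / 100,
                     length_nt = s1 - s0 + 1L,
                     strand = if (minus) "-" else "+",
                     score = d$bitscore[i],
                     evalue = max(d$evalue[i], .Machine$double.xmin))
    })
    search_hit(d$qseqid[1], d$sseqid[1], evalue = max(min(d$evalue), .Machine$double.xmin),
               regions = regions)
  })
  sort_hits(unname(hits))
}
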