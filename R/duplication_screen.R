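#' Threshold self-genome hits for the duplication screen
#'
#' Keeps hits with E-value strictly below the screen cutoff and removes
#' the query's own locus. Self-locus removal is by coordinate overlap
#' between any aligned region and the query gene's annotated span on its
#' own contig: without it every self-genome search would trivially call
#' a "duplication".
#'
#' @param hits List of \code{\link{search_hit}}s from searching a gene
#'   against its own genome.
#' @param evalue_cutoff Retain only hits with \code{evalue} strictly
#'   below this (default 0.001).
#' @param self_contig,self_span Contig id and 0-based half-open span of
#'   the query's own locus; hits whose regions all fall within (overlap)
#'   this span on this contig are dropped. \code{NULL} disables removal.
#' @return Filtered, deterministically sorted hit list.
#' @export
threshold_hits <- function(hits, evalue_cutoff = 0.001,
                           self_contig = NULL, self_span = NULL) {
  keep <- vapply(hits, function(h) {
    if (h$evalue >= evalue_cutoff) return(FALSE)
    if (!is.null(self_contig) && identical(h$subject_id, self_contig) &&
        !is.null(self_span)) {
      overlaps <- vapply(h$regions, function(r) {
        r$subject_span[1] < self_span[2] && self_span[1] < r$subject_span[2]
      }, logical(1))
      if (all(overlaps)) return(FALSE)   # the query's own locus
    }
    TRUE
  }, logical(1))
  sort_hits(hits[keep])
}

#' Remove likely sequencing-artifact hits
#'
#' A hit is eliminated when any of its aligned regions shows a large
#' stretch (> 200 nt) of near-perfect (> 98\%) identity: such hits more
#' likely reflect assembly/sequencing artifacts than real duplications.
#' Both inequalities are strict; identity is computed over aligned
#' columns excluding gaps and ambiguous positions.
#'
#' @param hits List of \code{\link{search_hit}}s.
#' @param min_length_nt,min_identity Artifact rule boundaries.
#' @return Hit list with artifact hits removed. Idempotent.
#' @export
filter_artifact_hits <- function(hits, min_length_nt = 200, min_identity = 0.98) {
  keep <- vapply(hits, function(h) {
    art <- vapply(h$regions, function(r) {
      r$length_nt > min_length_nt && r$identity_fraction > min_identity
    }, logical(1))
    !any(art)
  }, logical(1))
  hits[keep]
}

#' Validate one retained duplication candidate
#'
#' A candidate already annotated as a paralog of the expected gene
#' family passes without a search; otherwise it is searched against an
#' annotated close-relative reference and passes only when the expected
#' gene is the reciprocal best match.
#'
#' @param hit_sequence Length-1 named \code{DNAStringSet}: the candidate
#'   duplicate sequence.
#' @param close_relative_reference Named list of annotated reference
#'   sequences (see \code{\link{reciprocal_validate}}).
#' @param expected_gene Gene id expected as best match.
#' @param annotated_as_paralog If TRUE the candidate passes immediately.
#' @param engine,params Search engine.
#' @return Logical: is the candidate a validated duplication?
#' @export
validate_duplication <- function(hit_sequence, close_relative_reference,
                                 expected_gene, annotated_as_paralog = FALSE,
                                 engine = NULL, params = NULL) {
  if (isTRUE(annotated_as_paralog)) return(TRUE)
  chk <- reciprocal_validate(hit_sequence, close_relative_reference,
                             expected_gene, engine = engine, params = params)
  isTRUE(chk$confirmed)
}

#' Full duplication screen for one gene in one genome
#'
#' Pipeline (order fixed): self-genome nucleotide search, E-value
#' threshold with self-locus removal, artifact filter, reciprocal
#' validation of each surviving candidate.
#'
#' @param gene_seq Length-1 named \code{DNAStringSet}: the gene's own
#'   nucleotide sequence.
#' @param genome Named \code{DNAStringSet}: the species' own genome.
#' @param self_contig,self_span Annotated location of \code{gene_seq} in
#'   \code{genome} (0-based half-open), for self-locus removal.
#' @param reference Named list of annotated close-relative sequences for
#'   validation; \code{NULL} skips validation (candidates pass).
#' @param gene,taxon Labels.
#' @param annotated_paralogs Character vector of subject contig ids known
#'   to carry annotated paralogs of this gene family (pass unchecked).
#' @param evalue_cutoff Screen E-value cutoff (default 0.001).
#' @param engine,params Search engine (nucleotide by default).
#' @return A list of class \code{duplication_call}: fields \code{gene},
#'   \code{taxon}, \code{candidate_hits}, \code{retained},
#'   \code{duplicated}.
#' @export
duplication_screen <- function(gene_seq, genome, self_contig = NULL,
                               self_span = NULL, reference = NULL,
                               gene = names(gene_seq), taxon = "taxon",
                               annotated_paralogs = character(),
                               evalue_cutoff = 0.001,
                               engine = NULL, params = NULL) {
  if (is.null(params)) params <- engine_params("dna", evalue_max = evalue_cutoff)
  # every aligned region is a separate candidate locus, so the self-locus
  # and putative duplicate copies on the same contig stay distinct
  candidates <- split_hits(search_genome(gene_seq, genome, engine = engine,
                                         params = params))
  kept <- threshold_hits(candidates, evalue_cutoff = evalue_cutoff,
                         self_contig = self_contig, self_span = self_span)
  kept <- filter_artifact_hits(kept)
  retained <- list()
  for (h in kept) {
    ok <- if (is.null(reference)) {
      TRUE
    } else {
      validate_duplication(extract_hit_sequence(h, genome), reference,
                           expected_gene = gene,
                           annotated_as_paralog = h$subject_id %in% annotated_paralogs,
                           engine = engine)
    }
    if (ok) retained[[length(retained) + 1L]] <- h
  }
  structure(list(gene = gene, taxon = taxon,
                 candidate_hits = candidates, retained = retained,
                 duplicated = length(retained) > 0L),
            class = "duplication_call")
}

#' Summarize duplication calls as a table
#'
#' @param calls List of \code{duplication_call} objects.
#' @return Data frame: gene, taxon, n_candidates, n_retained, duplicated.
#' @export
duplication_table <- function(calls) {
  do.call(rbind, lapply(calls, function(d) {
    data.frame(gene = d$gene, taxon = d$taxon,
               n_candidates = length(d$candidate_hits),
               n_retained = length(d$retained),
               duplicated = d$duplicated)
  }))
}
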