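#' Classify the hits of one bait search as strong, weak or none
#'
#' The classification mirrors the tiered presence/absence protocol:
#' a *strong* hit (best E-value at or below 1e-10 with at least two
#' distinct aligned regions on the same subject) establishes presence
#' without further validation; a *weak* hit (best E-value in
#' (1e-10, 0.05], or a low E-value supported by only a single aligned
#' region) requires reciprocal validation; anything with no hit at
#' E-value <= 0.05 is *none*.
#'
#' @param hits List of \code{\link{search_hit}}s (may be empty).
#' @param strong_evalue,weak_evalue Classification cutoffs.
#' @return One of \code{"strong"}, \code{"weak"}, \code{"none"}.
#' @export
classify_hit <- function(hits, strong_evalue = 1e-10, weak_evalue = 0.05) {
  if (length(hits) == 0L) return("none")
  hits <- sort_hits(hits)
  best <- hits[[1]]
  if (best$evalue > weak_evalue) return("none")
  if (best$evalue <= strong_evalue && n_regions(best) >= 2L) return("strong")
  "weak"
}

#' Reciprocally validate a candidate sequence against an annotated reference
#'
#' A weak hit is confirmed by searching the putative subunit sequence
#' against an annotated reference gene set of a related species and
#' checking that the expected subunit is the best match.
#'
#' @param candidate Length-1 named \code{DNAStringSet}: the putative
#'   subunit sequence extracted from the target genome.
#' @param annotated_reference Named list of length-1 \code{AAStringSet}
#'   (annotated protein per gene) or \code{DNAStringSet} (gene sequence);
#'   names are gene ids.
#' @param expected_gene Gene id that must come out on top for the
#'   candidate to be confirmed.
#' @param engine,params Search engine used for the reciprocal search;
#'   defaults to the built-in engine appropriate for the reference type.
#' @param reference_taxon Label recorded in the returned check.
#' @param max_evalue References matching worse than this are ignored; if
#'   no reference clears it, the check fails with best match \code{NA}.
#' @param db_size Effective database size (residues) at which reciprocal
#'   E-values are judged when \code{params} is not supplied. The default
#'   of 2e6 is the scale of a typical annotated insect gene set, the
#'   database this validation stands in for; it makes marginal chance
#'   similarities (which would replicate against any small extracted
#'   candidate) insignificant, while genuine subunit matches remain many
#'   orders of magnitude below the cutoff.
#' @return A list of class \code{reciprocal_check} with fields
#'   \code{reference_taxon}, \code{best_match_gene}, \code{confirmed}.
#' @export
reciprocal_validate <- function(candidate, annotated_reference, expected_gene,
                                engine = NULL, params = NULL,
                                reference_taxon = "reference", max_evalue = 0.05,
                                db_size = 2e6) {
  stopifnot(length(annotated_reference) >= 1L, !is.null(names(annotated_reference)))
  if (is.null(params)) {
    type <- if (inherits(annotated_reference[[1]], "AAStringSet")) "protein" else "dna"
    params <- engine_params(type, db_size = db_size)
  }
  best_gene <- NA_character_
  best_ev <- Inf
  best_score <- -Inf
  for (g in names(annotated_reference)) {
    ref <- annotated_reference[[g]]
    # search the annotated reference gene against the candidate sequence:
    # protein references use the translated engine, DNA references the
    # nucleotide engine
    hits <- search_genome(ref, candidate, engine = engine, params = params)
    if (length(hits) == 0L) next
    h <- hits[[1]]
    if (h$evalue > max_evalue) next
    tot <- sum(vapply(h$regions, `[[`, numeric(1), "score"))
    if (h$evalue < best_ev || (h$evalue == best_ev && tot > best_score)) {
      best_ev <- h$evalue
      best_score <- tot
      best_gene <- g
    }
  }
  structure(list(reference_taxon = reference_taxon,
                 best_match_gene = best_gene,
                 confirmed = identical(best_gene, expected_gene)),
            class = "reciprocal_check")
}

#' Bundle bait sequences for one escalation tier
#'
#' @param tier Tier number (1, 2 or 3); tiers are applied in ascending
#'   order. Tier 1 holds distant canonical baits, tier 2 within-order
#'   annotated baits, tier 3 the closest-relative sequence.
#' @param baits Named \code{AAStringSet} of protein baits (may be empty
#'   for tiers 2-3).
#' @return An object of class \code{bait_tier}.
#' @export
bait_tier <- function(tier, baits) {
  stopifnot(tier %in% 1:3)
  if (tier == 1L && length(baits) == 0L) stop("tier 1 bait set must be non-empty")
  structure(list(tier = as.integer(tier), baits = baits), class = "bait_tier")
}

#' Presence/absence call for one (taxon, gene) under the tiered protocol
#'
#' Bait tiers are tried in ascending order. A tier decides the call when
#' it produces a strong hit, or a weak hit that passes reciprocal
#' validation; a weak hit that fails validation does not stop the
#' cascade, later tiers are still tried. The gene is called absent only
#' when every provided tier fails.
#'
#' @param genome Named \code{DNAStringSet} of target-genome contigs.
#' @param tiers List of \code{\link{bait_tier}} objects, ascending tier.
#' @param reference Named list of annotated reference sequences for
#'   reciprocal validation (see \code{\link{reciprocal_validate}});
#'   required only if weak hits are to be validated.
#' @param gene,taxon Labels recorded in the call.
#' @param engine,params Search engine (see \code{\link{search_genome}}).
#' @param strong_evalue,weak_evalue Classification cutoffs, as in
#'   \code{\link{classify_hit}}.
#' @return A list of class \code{presence_call} with fields \code{taxon},
#'   \code{gene}, \code{verdict} (present/absent), \code{evidence_tier}
#'   (1, 2, 3 or NA), \code{hit_class} (strong, weak_validated, none),
#'   \code{validation} (a \code{reciprocal_check} or NULL), \code{hits}
#'   (the deciding hit list) and \code{warning} (e.g. empty genome).
#' @export
tiered_search <- function(genome, tiers, reference = NULL,
                          gene = "gene", taxon = "taxon",
                          engine = NULL, params = NULL,
                          strong_evalue = 1e-10, weak_evalue = 0.05) {
  stopifnot(length(tiers) >= 1L)
  tier_no <- vapply(tiers, `[[`, integer(1), "tier")
  stopifnot(!is.unsorted(tier_no))
  if (length(tiers[[1]]$baits) == 0L) stop("tier 1 bait set must be non-empty")
  if (length(genome) == 0L) {
    return(structure(list(taxon = taxon, gene = gene, verdict = "absent",
                          evidence_tier = NA_integer_, hit_class = "none",
                          validation = NULL, hits = list(),
                          warning = "empty genome"),
                     class = "presence_call"))
  }
  for (ti in seq_along(tiers)) {
    tier <- tiers[[ti]]
    if (length(tier$baits) == 0L) next
    for (bi in seq_along(tier$baits)) {
      bait <- tier$baits[bi]
      hits <- search_genome(bait, genome, engine = engine, params = params)
      cls <- classify_hit(hits, strong_evalue, weak_evalue)
      if (cls == "strong") {
        return(structure(list(taxon = taxon, gene = gene, verdict = "present",
                              evidence_tier = tier$tier, hit_class = "strong",
                              validation = NULL, hits = hits, warning = NULL),
                         class = "presence_call"))
      }
      if (cls == "weak") {
        if (is.null(reference)) next
        cand <- extract_hit_sequence(hits[[1]], genome)
        # validation runs at reference-database significance scale, not
        # with the genome-search parameters
        chk <- reciprocal_validate(cand, reference, expected_gene = gene,
                                   engine = engine)
        if (isTRUE(chk$confirmed)) {
          return(structure(list(taxon = taxon, gene = gene, verdict = "present",
                                evidence_tier = tier$tier,
                                hit_class = "weak_validated",
                                validation = chk, hits = hits, warning = NULL),
                           class = "presence_call"))
        }
      }
    }
  }
  structure(list(taxon = taxon, gene = gene, verdict = "absent",
                 evidence_tier = NA_integer_, hit_class = "none",
                 validation = NULL, hits = list(), warning = NULL),
            class = "presence_call")
}

#' Extract the subject sequence spanned by a hit's aligned regions
#'
#' Returns the forward-strand subsequence of the hit's subject contig
#' from the first to the last aligned region, for use as the candidate
#' in reciprocal validation.
#'
#' @param hit A \code{\link{search_hit}}.
#' @param genome Named \code{DNAStringSet} containing the subject contig.
#' @return Length-1 named \code{DNAStringSet}.
#' @export
extract_hit_sequence <- function(hit, genome) {
  ctg <- genome[[hit$subject_id]]
  lo <- min(vapply(hit$regions, function(r) r$subject_span[1], numeric(1)))
  hi <- max(vapply(hit$regions, function(r) r$subject_span[2], numeric(1)))
  out <- Biostrings::DNAStringSet(Biostrings::subseq(ctg, start = lo + 1L, end = hi))
  names(out) <- sprintf("%s:%d-%d", hit$subject_id, lo, hi)
  out
}

#' Run the tiered screen over many taxa and genes
#'
#' @param genomes Named list of \code{DNAStringSet} genomes, one per taxon.
#' @param tier_sets Named list (by gene) of lists of
#'   \code{\link{bait_tier}}s. Per-taxon tier-3 baits may be supplied via
#'   \code{tier3_by_taxon[[gene]][[taxon]]}.
#' @param reference Named list (by gene) of annotated reference sets, or
#'   a single reference set shared by all genes.
#' @param tier3_by_taxon Optional per-taxon tier-3 baits.
#' @param ... Passed to \code{\link{tiered_search}}.
#' @return A data frame with one row per (taxon, gene): taxon, gene,
#'   verdict, evidence_tier, hit_class.
#' @export
screen_genomes <- function(genomes, tier_sets, reference = NULL,
                           tier3_by_taxon = NULL, ...) {
  out <- list()
  for (taxon in names(genomes)) {
    for (gene in names(tier_sets)) {
      tiers <- tier_sets[[gene]]
      if (!is.null(tier3_by_taxon) && !is.null(tier3_by_taxon[[gene]][[taxon]])) {
        tiers <- c(tiers, list(bait_tier(3L, tier3_by_taxon[[gene]][[taxon]])))
      }
      ref <- if (!is.null(reference) && !is.null(reference[[gene]]) &&
                 is.list(reference[[gene]])) reference[[gene]] else reference
      call <- tiered_search(genomes[[taxon]], tiers, reference = ref,
                            gene = gene, taxon = taxon, ...)
      out[[length(out) + 1L]] <-
        data.frame(taxon = taxon, gene = gene, verdict = call$verdict,
                   evidence_tier = if (is.na(call$evidence_tier)) NA_integer_
                                   else call$evidence_tier,
                   hit_class = call$hit_class)
    }
  }
  do.call(rbind, out)
}

#' Convert screen results to a tip-state matrix
#'
#' @param calls Data frame from \code{\link{screen_genomes}}.
#' @return Character matrix (taxa x genes) with entries present/absent,
#'   suitable for \code{\link{dollo_loss_map}}.
#' @export
calls_to_state_matrix <- function(calls) {
  taxa <- unique(calls$taxon)
  genes <- unique(calls$gene)
  m <- matrix("unknown", nrow = length(taxa), ncol = length(genes),
              dimnames = list(taxa, genes))
  for (i in seq_len(nrow(calls))) {
    m[calls$taxon[i], calls$gene[i]] <- calls$verdict[i]
  }
  m[m == "present"] <- "present"
  m[m == "absent"] <- "absent"
  m
}
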