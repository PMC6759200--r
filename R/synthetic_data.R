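#' Derive a deterministic substream seed
#'
#' A single root seed fans out to named per-component substreams, so
#' adding a generator does not perturb the draws of existing ones. The
#' derived seed stays below 2^31.
#'
#' @param seed Integer root seed.
#' @param stream Stream name.
#' @return An integer seed.
#' @export
sim_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' @noRd
aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Random protein sequence
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return Character string of residues.
#' @export
random_protein <- function(length, seed) {
  set.seed(seed)
  paste(sample(aa_alphabet(), length, replace = TRUE), collapse = "")
}

#' Random DNA sequence
#' @param length Number of bases.
#' @param seed Integer seed.
#' @return Character string of bases.
#' @export
random_dna <- function(length, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Substitute a fixed proportion of residues in a protein
#'
#' Each selected position is replaced with a uniformly chosen different
#' residue; used to build divergence ladders between bait and target.
#'
#' @param protein Residue string.
#' @param proportion Fraction of positions to substitute, in [0, 1].
#' @param seed Integer seed.
#' @return Mutated residue string.
#' @export
mutate_protein <- function(protein, proportion, seed) {
  set.seed(seed)
  aa <- strsplit(protein, "")[[1]]
  n_mut <- round(length(aa) * proportion)
  if (n_mut == 0L) return(protein)
  pos <- sample(length(aa), n_mut)
  for (p in pos) aa[p] <- sample(setdiff(aa_alphabet(), aa[p]), 1L)
  paste(aa, collapse = "")
}

# fixed back-translation table: lexicographically first codon per amino
# acid (codon-usage realism is out of scope)
#' @noRd
backtranslate_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc))
  vapply(unique(gc), function(a) codons[gc[codons] == a][1L], character(1)) |>
    stats::setNames(unique(gc))
}

#' Back-translate a protein with a fixed codon table
#' @param protein Residue string.
#' @return DNA string (coding sequence, no stop).
#' @export
backtranslate <- function(protein) {
  tab <- backtranslate_table()
  paste(tab[strsplit(protein, "")[[1]]], collapse = "")
}

#' Simulate a Dollo loss history on a rooted tree
#'
#' The gene is present at the root; each edge loses it independently
#' with probability \code{loss_prob} given the parent still carries it,
#' and once lost it stays lost. Both tip states and the true loss edges
#' are returned, so inference can be compared against truth.
#'
#' @param tree Rooted \code{phylo}.
#' @param loss_prob Per-edge loss probability in [0, 1].
#' @param seed Integer seed.
#' @return List: \code{tip_states} (named vector, present/absent),
#'   \code{loss_edges} (data frame parent/child), \code{n_losses}
#'   (count of true loss events).
#' @export
simulate_presence_history <- function(tree, loss_prob, seed) {
  check_rooted(tree)
  stopifnot(loss_prob >= 0, loss_prob <= 1)
  set.seed(sim_seed(seed, "presence_history"))
  ntip <- length(tree$tip.label)
  nno <- ntip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "cladewise")$edge   # parents before children
  state <- rep(TRUE, nno)
  lost_on <- logical(nrow(edge))
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    if (!state[p]) {
      state[ch] <- FALSE
    } else {
      lose <- stats::runif(1) < loss_prob
      state[ch] <- !lose
      lost_on[i] <- lose
    }
  }
  tips <- stats::setNames(ifelse(state[seq_len(ntip)], "present", "absent"),
                          tree$tip.label)
  list(tip_states = tips,
       loss_edges = data.frame(parent = edge[lost_on, 1], child = edge[lost_on, 2]),
       n_losses = sum(lost_on))
}

#' Simulate target genomes with implanted, diverged or deleted orthologs
#'
#' Each taxon receives one random-background contig in which the coding
#' sequence of every gene it carries (per \code{tip_states}) is
#' embedded, back-translated from the ancestral protein after
#' substituting \code{divergence[taxon]} of its residues. Optional decoy
#' paralogs (implanted everywhere) and exact-repeat artifacts (a
#' duplicated identical fragment of a gene, emulating an assembly
#' artifact) can be injected.
#'
#' @param tip_states Character matrix (taxa x genes), entries
#'   present/absent (unknown treated as absent).
#' @param family_proteins Named character vector: ancestral protein per
#'   gene.
#' @param divergence Single proportion or named per-taxon vector of
#'   residue-substitution proportions applied to implanted orthologs.
#' @param seed Integer seed.
#' @param bg_length Background length inserted before/between/after
#'   implants.
#' @param decoy_proteins Optional named character vector of decoy
#'   paralog proteins implanted in every taxon.
#' @param artifact_genes Genes for which an exact duplicate fragment of
#'   the implanted CDS is additionally inserted (in taxa carrying the
#'   gene).
#' @param artifact_len Length (nt) of the duplicated fragment.
#' @param n_exons Number of exons each implanted gene is split into
#'   (default 2, separated by random intronic sequence, so that a
#'   genuine ortholog produces the multi-region hits real annotated
#'   genes give a translated search).
#' @param intron_length Length (nt) of each intron; the default is not
#'   a multiple of 3, so successive exons fall in different reading
#'   frames as they typically do in real genes.
#' @return List: \code{genomes} (named list of one-contig
#'   \code{DNAStringSet}s), \code{implants} (data frame taxon, gene,
#'   contig, start, end: 0-based half-open spans of implanted CDS),
#'   \code{tip_proteins} (list by taxon of implanted mutated proteins).
#' @export
simulate_genomes <- function(tip_states, family_proteins, divergence = 0.1,
                             seed = 1L, bg_length = 600L,
                             decoy_proteins = NULL,
                             artifact_genes = character(),
                             artifact_len = 300L,
                             n_exons = 2L, intron_length = 151L) {
  taxa <- rownames(tip_states)
  genes <- colnames(tip_states)
  if (length(divergence) == 1L && is.null(names(divergence))) {
    divergence <- stats::setNames(rep(divergence, length(taxa)), taxa)
  }
  genomes <- list()
  implants <- list()
  tip_proteins <- list()
  for (tx in taxa) {
    parts <- character()
    pos <- 0L
    tip_proteins[[tx]] <- list()
    push <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
    push(random_dna(bg_length, sim_seed(seed, paste0("bg1_", tx))))
    for (g in genes) {
      if (tip_states[tx, g] != "present") next
      prot <- mutate_protein(family_proteins[[g]], divergence[[tx]],
                             sim_seed(seed, paste0("div_", tx, "_", g)))
      tip_proteins[[tx]][[g]] <- prot
      cds <- backtranslate(prot)
      # split into exons at codon boundaries, separated by random introns
      n_cod <- nchar(cds) %/% 3L
      k <- max(1L, min(n_exons, n_cod))
      bounds <- round(seq(0, n_cod, length.out = k + 1L)) * 3L
      gene_start <- pos
      for (e in seq_len(k)) {
        if (e > 1L) {
          push(random_dna(intron_length, sim_seed(seed, paste0("int_", tx, "_", g, "_", e))))
        }
        push(substr(cds, bounds[e] + 1L, bounds[e + 1L]))
      }
      implants[[length(implants) + 1L]] <-
        data.frame(taxon = tx, gene = g, contig = paste0(tx, "_ctg1"),
                   start = gene_start, end = pos)
      if (g %in% artifact_genes) {
        frag <- substr(cds, 1L, min(artifact_len, nchar(cds)))
        push(random_dna(bg_length, sim_seed(seed, paste0("bga_", tx, "_", g))))
        push(frag)
      }
      push(random_dna(bg_length, sim_seed(seed, paste0("bg_", tx, "_", g))))
    }
    if (!is.null(decoy_proteins)) {
      for (d in names(decoy_proteins)) {
        push(backtranslate(decoy_proteins[[d]]))
        push(random_dna(bg_length, sim_seed(seed, paste0("bgd_", tx, "_", d))))
      }
    }
    ctg <- Biostrings::DNAStringSet(paste(parts, collapse = ""))
    names(ctg) <- paste0(tx, "_ctg1")
    genomes[[tx]] <- ctg
  }
  list(genomes = genomes,
       implants = if (length(implants)) do.call(rbind, implants) else
         data.frame(taxon = character(), gene = character(), contig = character(),
                    start = integer(), end = integer()),
       tip_proteins = tip_proteins)
}

#' Simulate a codon alignment with known MK structure
#'
#' Sites are independent; each receives at most one event: a synonymous
#' or nonsynonymous segregating polymorphism in the ingroup (probability
#' theta/2 each), a synonymous or neutral nonsynonymous fixed difference
#' to the outgroup (divergence/2 each), or an adaptive nonsynonymous
#' fixed difference, whose rate divergence/2 * a/(1-a) makes the
#' expected proportion of adaptive amino-acid fixations equal \code{a}.
#' Events are realized on a glycine background codon whose single-step
#' neighbors are cleanly synonymous (third position) or nonsynonymous
#' (first position), so true counts are exact.
#'
#' @param n_ingroup Number of ingroup haplotypes (>= 2; default 20).
#' @param n_codons Alignment length in codons (default 2000).
#' @param theta Per-site polymorphism probability (default 0.28).
#' @param divergence Per-site neutral fixed-difference probability
#'   (default 0.10).
#' @param adaptive_fraction Target adaptive proportion \code{a} in
#'   [0, 1) (default 0).
#' @param seed Integer seed.
#' @return List: \code{ingroup}, \code{outgroup} (DNAStringSets),
#'   \code{truth} (\code{mk_counts} of the realized true counts),
#'   \code{adaptive_fraction}.
#' @export
simulate_mk_alignment <- function(n_ingroup = 20L, n_codons = 2000L,
                                  theta = 0.28, divergence = 0.10,
                                  adaptive_fraction = 0, seed = 1L) {
  stopifnot(n_ingroup >= 2L, n_codons >= 1L,
            adaptive_fraction >= 0, adaptive_fraction < 1)
  set.seed(sim_seed(seed, "mk_alignment"))
  base <- "GGC"     # Gly; GGx all Gly
  syn_alt <- "GGT"  # third-position, synonymous
  non_alt <- "AGC"  # first-position G->A, Gly->Ser, nonsynonymous
  p_adapt <- divergence / 2 * adaptive_fraction / (1 - adaptive_fraction)
  probs <- c(pS = theta / 2, pN = theta / 2,
             dS = divergence / 2, dN = divergence / 2, dA = p_adapt)
  if (sum(probs) > 1) stop("theta/divergence/adaptive_fraction imply event probability > 1")
  cats <- sample(c(names(probs), "none"), n_codons, replace = TRUE,
                 prob = c(probs, 1 - sum(probs)))
  ing <- matrix(base, nrow = n_ingroup, ncol = n_codons)
  og <- rep(base, n_codons)
  max_minor <- max(1L, ceiling(n_ingroup / 2) - 1L)
  for (s in which(cats %in% c("pS", "pN"))) {
    k <- if (max_minor == 1L) 1L else sample(max_minor, 1L)
    carriers <- sample(n_ingroup, k)
    ing[carriers, s] <- if (cats[s] == "pS") syn_alt else non_alt
  }
  og[cats == "dS"] <- syn_alt
  og[cats %in% c("dN", "dA")] <- non_alt
  truth <- mk_counts(pS = sum(cats == "pS"), pN = sum(cats == "pN"),
                     dS = sum(cats == "dS"), dN = sum(cats %in% c("dN", "dA")))
  ing_seqs <- Biostrings::DNAStringSet(apply(ing, 1L, paste, collapse = ""))
  names(ing_seqs) <- paste0("ing", seq_len(n_ingroup))
  og_seqs <- Biostrings::DNAStringSet(paste(og, collapse = ""))
  names(og_seqs) <- "outgroup1"
  list(ingroup = ing_seqs, outgroup = og_seqs, truth = truth,
       adaptive_fraction = adaptive_fraction)
}

#' Simulate a nucleus-pairing count
#'
#' @param p_pair Per-nucleus pairing probability in [0, 1].
#' @param n_nuclei Number of nuclei scored.
#' @param seed Integer seed.
#' @return List: \code{paired}, \code{total}.
#' @export
simulate_pairing <- function(p_pair, n_nuclei, seed = 1L) {
  stopifnot(p_pair >= 0, p_pair <= 1, n_nuclei >= 1)
  set.seed(sim_seed(seed, "pairing"))
  list(paired = stats::rbinom(1L, n_nuclei, p_pair), total = n_nuclei)
}
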