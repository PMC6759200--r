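test_that("single-step codon changes classify by the standard code", {
  syn <- classify_codon_pair("AAA", "AAG")     # Lys -> Lys
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$weight, 1)
  non <- classify_codon_pair("AAA", "GAA")     # Lys -> Glu
  expect_equal(non$effect, "nonsynonymous")
  expect_equal(non$weight, 1)
  expect_equal(nrow(classify_codon_pair("AAA", "AAA")), 0)
})

test_that("two-step codons average over both mutational pathways", {
  # TTT -> GTA: TTT(F)->GTT(V)->GTA(V) is non+syn; TTT(F)->TTA(L)->GTA(V)
  # is non+non; averaging gives 0.5 synonymous, 1.5 nonsynonymous
  cls <- classify_codon_pair("TTT", "GTA")
  w <- stats::setNames(cls$weight, cls$effect)
  expect_equal(w[["synonymous"]], 0.5)
  expect_equal(w[["nonsynonymous"]], 1.5)
  expect_equal(sum(cls$weight), 2)
})

test_that("pathways through stop codons are excluded", {
  # TCA -> TGG: the path via TGA (stop) is discarded, leaving only
  # TCA(S)->TCG(S)->TGG(W): one synonymous plus one nonsynonymous step
  cls <- classify_codon_pair("TCA", "TGG")
  w <- stats::setNames(cls$weight, cls$effect)
  expect_equal(w[["synonymous"]], 1)
  expect_equal(w[["nonsynonymous"]], 1)
})

test_that("invalid codons are rejected", {
  expect_error(classify_codon_pair("TAA", "AAA"), "stop")
  expect_error(classify_codon_pair("AN-", "AAA"))
  expect_error(classify_codon_pair("AAAA", "AAA"))
})

test_that("tabulation separates polymorphism from divergence", {
  ing <- Biostrings::DNAStringSet(rep("ATGAAA", 4))
  names(ing) <- paste0("h", 1:4)
  og <- Biostrings::DNAStringSet(c(out = "ATGAAG"))
  tab <- tabulate_mk(ing, og)
  expect_equal(c(tab$pS, tab$pN, tab$dS, tab$dN), c(0, 0, 1, 0))  # AAA/AAG both Lys

  ing2 <- Biostrings::DNAStringSet(c(h1 = "ATGAAA", h2 = "ATGGAA"))
  og2 <- Biostrings::DNAStringSet(c(out = "ATGAAA"))
  tab2 <- tabulate_mk(ing2, og2)
  expect_equal(c(tab2$pS, tab2$pN, tab2$dS, tab2$dN), c(0, 1, 0, 0))  # Lys/Glu segregates

  same <- tabulate_mk(Biostrings::DNAStringSet(c(a = "ATGAAA", b = "ATGAAA")),
                      Biostrings::DNAStringSet(c(out = "ATGAAA")))
  expect_equal(c(same$pS, same$pN, same$dS, same$dN), c(0, 0, 0, 0))
})

test_that("a site both polymorphic and divergent contributes both components", {
  # ingroup segregates AAA/AAG (syn); outgroup GAA not among ingroup
  # alleles -> fixed nonsynonymous component on top of the polymorphism
  ing <- Biostrings::DNAStringSet(c(h1 = "AAA", h2 = "AAA", h3 = "AAG"))
  og <- Biostrings::DNAStringSet(c(out = "GAA"))
  tab <- tabulate_mk(ing, og)
  expect_equal(tab$pS, 1)
  expect_equal(tab$dN, 1)
  # but when the outgroup allele is segregating in the ingroup, there is
  # no fixed difference
  og2 <- Biostrings::DNAStringSet(c(out = "AAG"))
  tab2 <- tabulate_mk(ing, og2)
  expect_equal(tab2$pS, 1)
  expect_equal(tab2$dS + tab2$dN, 0)
})

test_that("gapped, ambiguous and stop-containing codon columns are skipped and reported", {
  ing <- Biostrings::DNAStringSet(c(h1 = "ATG---AAANNNTAAAAC",
                                    h2 = "ATGAAAAAGAAAAAAAAC"))
  og <- Biostrings::DNAStringSet(c(out = "ATGAAAAAAAAAAAAAAT"))
  tab <- tabulate_mk(ing, og)
  expect_equal(sum(tab$skipped), 3)   # gap, N, stop (TAA), and nothing else
  expect_gte(tab$skipped[["gap_or_ambiguous"]], 2)
  expect_gte(tab$skipped[["stop_codon"]], 1)
  # the clean segregating site (AAG vs AAA, syn) and final divergent site still count
  expect_equal(tab$pS, 1)
  expect_equal(tab$dS, 1)   # AAC vs AAT both Asn
})

test_that("tabulation is invariant to haplotype order and relabeling", {
  sim <- simulate_mk_alignment(n_ingroup = 8, n_codons = 150,
                               adaptive_fraction = 0.3, seed = 99)
  tab1 <- tabulate_mk(sim$ingroup, sim$outgroup)
  perm <- sim$ingroup[sample(length(sim$ingroup))]
  names(perm) <- paste0("relabeled", seq_along(perm))
  tab2 <- tabulate_mk(perm, sim$outgroup)
  expect_equal(tab1$raw, tab2$raw)
})

test_that("alpha reproduces hand-computed and published values", {
  expect_equal(round(alpha_from_counts(mk_counts(544, 231, 25, 53)), 4), 0.7997)
  expect_equal(round(alpha_from_counts(mk_counts(278, 119, 36, 30)), 4), 0.4863)
  expect_equal(round(alpha_from_counts(mk_counts(150, 44, 24, 6)), 4), -0.1733)
  expect_equal(alpha_from_counts(mk_counts(100, 100, 10, 10)), 0)
  expect_true(is.na(alpha_from_counts(mk_counts(100, 100, 10, 0))))   # dN = 0
  expect_true(is.na(alpha_from_counts(mk_counts(0, 100, 10, 10))))    # pS = 0
})

test_that("Fisher p-values equal the hypergeometric enumeration oracle", {
  # every 2x2 table with total count <= 14, all three tails
  for (n in 2:14) {
    parts <- expand.grid(dN = 0:n, dS = 0:n, pN = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    for (i in seq_len(nrow(parts))) {
      dN <- parts$dN[i]; dS <- parts$dS[i]; pN <- parts$pN[i]
      pS <- n - dN - dS - pN
      cnt <- mk_counts(pS, pN, dS, dN)
      for (tail in c("two.sided", "greater", "less")) {
        expect_equal(mk_fisher(cnt, tail),
                     fisher_brute_force(dN, dS, pN, pS, tail),
                     tolerance = 1e-10,
                     info = sprintf("table %d/%d/%d/%d %s", dN, dS, pN, pS, tail))
      }
    }
  }
  # plus a spread of larger random tables up to total 60
  set.seed(31)
  for (i in 1:200) {
    v <- as.vector(stats::rmultinom(1, sample(20:60, 1), rep(0.25, 4)))
    cnt <- mk_counts(v[1], v[2], v[3], v[4])
    expect_equal(mk_fisher(cnt, "two.sided"),
                 fisher_brute_force(v[4], v[3], v[2], v[1], "two.sided"),
                 tolerance = 1e-10)
  }
})

test_that("hand-enumerated small Fisher cases come out exactly", {
  # [[2,0],[0,2]]: one-sided p = 1/6 over the hypergeometric support
  expect_equal(mk_fisher(mk_counts(2, 0, 0, 2), "greater"), 1 / 6,
               tolerance = 1e-12)
  # identical row proportions with large margins: no divergence excess
  expect_gt(mk_fisher(mk_counts(500, 500, 50, 50), "greater"), 0.4)
  expect_equal(mk_fisher(mk_counts(0, 0, 0, 0)), 1)
})

test_that("batch MK analysis reproduces the published condensin/cohesin table", {
  counts_path <- system.file("extdata", "mk_counts_dmel_dsim.tsv", package = "condevo")
  res <- mk_from_counts_table(counts_path)
  expect_equal(nrow(res), 10)
  pub <- utils::read.table(system.file("extdata", "mk_published_dmel_dsim.tsv",
                                       package = "condevo"),
                           sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  merged <- merge(res, pub, by = "gene", suffixes = c("", "_pub"))
  reproducible <- c("Barren (Cap-H)", "Cap-D2", "Cap-D3", "Cap-H2",
                    "Glu (SMC4)", "SA", "SMC1", "SMC2")
  for (g in reproducible) {
    row <- merged[merged$gene == g, ]
    expect_lt(abs(row$alpha - row$alpha_pub), 1e-4)
    expect_lt(abs(row$p_value - row$p_value_pub) / max(row$p_value_pub, 1e-12),
              0.02)
  }
  # two rows of the published table are known transcription anomalies:
  # their printed alphas do NOT follow from their printed counts
  capg <- merged[merged$gene == "Cap-G", ]
  expect_gt(abs(capg$alpha - capg$alpha_pub), 0.1)
  smc3 <- merged[merged$gene == "SMC3", ]
  expect_gt(abs(smc3$alpha - smc3$alpha_pub), 1e-3)
})

test_that("batch MK handles empty tables and undefined alpha rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tpS\tpN\tdS\tdN", f)
  expect_equal(nrow(mk_from_counts_table(f)), 0)

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tpS\tpN\tdS\tdN", "x\t10\t5\t3\t0"), g)
  res <- mk_from_counts_table(g)
  expect_true(is.na(res$alpha))
  expect_false(is.na(res$p_value))

  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tpS\tpN\tdS\tdN", "x\t10\t5\t-3\t0"), h)
  expect_error(mk_from_counts_table(h), "negative")
})
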