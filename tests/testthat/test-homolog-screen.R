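test_that("hit classification follows the strong/weak/none boundaries", {
  expect_equal(classify_hit(list(make_hit(evalue = 1e-12, n_regions = 3))), "strong")
  expect_equal(classify_hit(list(make_hit(evalue = 1e-3, n_regions = 1))), "weak")
  expect_equal(classify_hit(list(make_hit(evalue = 0.2, n_regions = 2))), "none")
  # a low E-value with a single aligned region still needs validation
  expect_equal(classify_hit(list(make_hit(evalue = 1e-12, n_regions = 1))), "weak")
  expect_equal(classify_hit(list()), "none")
  # boundary values: thresholds are inclusive
  expect_equal(classify_hit(list(make_hit(evalue = 1e-10, n_regions = 2))), "strong")
  expect_equal(classify_hit(list(make_hit(evalue = 0.05, n_regions = 1))), "weak")
})

test_that("adding a better hit never turns a present verdict into absent", {
  base <- list(make_hit(evalue = 1e-12, n_regions = 2))
  expect_equal(classify_hit(base), "strong")
  better <- c(base, list(make_hit(subject = "s2", evalue = 1e-15, n_regions = 2)))
  expect_equal(classify_hit(better), "strong")
  # generalized: appending any lower-evalue multi-region hit keeps/raises class
  set.seed(99)
  for (i in 1:20) {
    e0 <- 10^(-stats::runif(1, 1, 12))
    h0 <- list(make_hit(evalue = e0, n_regions = sample(1:3, 1)))
    c0 <- classify_hit(h0)
    h1 <- c(h0, list(make_hit(subject = "x", evalue = e0 / 10, n_regions = 2)))
    c1 <- classify_hit(h1)
    rank <- c(none = 0, weak = 1, strong = 2)
    expect_gte(rank[[c1]], rank[[c0]])
  }
})

test_that("reciprocal validation confirms self and rejects decoys", {
  capH2 <- random_protein(120, 201)
  capH <- random_protein(120, 202)
  reference <- list(
    `Cap-H2` = sequence_record("ref_capH2", capH2, "protein"),
    `Cap-H` = sequence_record("ref_capH", capH, "protein"))

  cand_true <- sequence_record("cand", backtranslate(capH2))
  chk <- reciprocal_validate(cand_true, reference, "Cap-H2")
  expect_true(chk$confirmed)
  expect_equal(chk$best_match_gene, "Cap-H2")

  cand_decoy <- sequence_record("cand", backtranslate(capH))
  chk2 <- reciprocal_validate(cand_decoy, reference, "Cap-H2")
  expect_false(chk2$confirmed)
  expect_equal(chk2$best_match_gene, "Cap-H")

  cand_random <- sequence_record("cand", random_dna(360, 203))
  chk3 <- reciprocal_validate(cand_random, reference, "Cap-H2")
  expect_false(chk3$confirmed)
  expect_true(is.na(chk3$best_match_gene))
})

test_that("tiered search finds exact tier-1 copies and calls deletions absent", {
  anc <- random_protein(140, 301)
  states <- matrix(c("present", "absent"), nrow = 2,
                   dimnames = list(c("has_it", "lost_it"), "g1"))
  sim <- simulate_genomes(states, c(g1 = anc), divergence = 0, seed = 17)
  tiers <- list(bait_tier(1L, sequence_record("bait1", anc, "protein")))

  call1 <- tiered_search(sim$genomes$has_it, tiers, gene = "g1", taxon = "has_it")
  expect_equal(call1$verdict, "present")
  expect_equal(call1$evidence_tier, 1L)
  expect_equal(call1$hit_class, "strong")

  call2 <- tiered_search(sim$genomes$lost_it, tiers, gene = "g1", taxon = "lost_it")
  expect_equal(call2$verdict, "absent")
  expect_true(is.na(call2$evidence_tier))

  empty <- tiered_search(Biostrings::DNAStringSet(), tiers, gene = "g1")
  expect_equal(empty$verdict, "absent")
  expect_equal(empty$warning, "empty genome")
})

test_that("a diverged ortholog escalates to the tier-3 close-relative bait", {
  anc <- random_protein(150, 311)
  states <- matrix("present", 1, 1, dimnames = list("far_taxon", "g1"))
  sim <- simulate_genomes(states, c(g1 = anc), divergence = 0.8, seed = 19)
  tip_prot <- sim$tip_proteins$far_taxon$g1
  tier1 <- bait_tier(1L, sequence_record("distant_bait", anc, "protein"))
  tier3 <- bait_tier(3L, sequence_record("close_bait",
                                         mutate_protein(tip_prot, 0.05, 20),
                                         "protein"))

  # confirm by direct engine calls that tier 1 fails outright here
  t1_hits <- search_genome(tier1$baits, sim$genomes$far_taxon)
  expect_equal(classify_hit(t1_hits), "none")
  t3_hits <- search_genome(tier3$baits, sim$genomes$far_taxon)
  expect_equal(classify_hit(t3_hits), "strong")

  call <- tiered_search(sim$genomes$far_taxon, list(tier1, tier3),
                        gene = "g1", taxon = "far_taxon")
  expect_equal(call$verdict, "present")
  expect_equal(call$evidence_tier, 3L)
})

test_that("single-region hits are validated reciprocally before presence is called", {
  anc <- random_protein(140, 321)
  decoy <- random_protein(140, 322)
  states <- matrix("present", 1, 1, dimnames = list("tx", "g1"))
  # single-exon implant: one aligned region, so classification is weak
  sim <- simulate_genomes(states, c(g1 = anc), divergence = 0.1, seed = 23,
                          n_exons = 1L)
  tiers <- list(bait_tier(1L, sequence_record("bait1", anc, "protein")))
  reference <- list(g1 = sequence_record("ref_g1", anc, "protein"),
                    g2 = sequence_record("ref_g2", decoy, "protein"))
  call <- tiered_search(sim$genomes$tx, tiers, reference = reference,
                        gene = "g1", taxon = "tx")
  expect_equal(call$verdict, "present")
  expect_equal(call$hit_class, "weak_validated")
  expect_true(call$validation$confirmed)

  # without a reference the weak hit cannot be validated -> absent
  call2 <- tiered_search(sim$genomes$tx, tiers, gene = "g1", taxon = "tx")
  expect_equal(call2$verdict, "absent")
})

test_that("tier precedence: a strong tier-1 hit stops the cascade", {
  counter <- new.env(); counter$calls <- 0L
  script <- list(`b1|ctg` = list(make_hit("b1", "ctg", evalue = 1e-20, n_regions = 2)))
  eng <- stub_engine(script, counter)
  genome <- sequence_record("ctg", random_dna(300, 71))
  tiers <- list(bait_tier(1L, sequence_record("b1", "MKLV", "protein")),
                bait_tier(2L, sequence_record("b2", "MKLV", "protein")),
                bait_tier(3L, sequence_record("b3", "MKLV", "protein")))
  call <- tiered_search(genome, tiers, engine = eng, gene = "g", taxon = "t")
  expect_equal(call$evidence_tier, 1L)
  expect_equal(counter$calls, 1L)   # tiers 2-3 never consulted
})

test_that("the protocol layer is engine-agnostic: identical hits, identical calls", {
  hit <- make_hit("b1", "ctg", evalue = 1e-20, n_regions = 2)
  eng_a <- stub_engine(list(`b1|ctg` = list(hit)))
  eng_b <- function(query, subject, params = NULL) {
    if (names(query) == "b1" && names(subject) == "ctg") list(hit) else list()
  }
  genome <- sequence_record("ctg", random_dna(300, 72))
  tiers <- list(bait_tier(1L, sequence_record("b1", "MKLV", "protein")))
  call_a <- tiered_search(genome, tiers, engine = eng_a, gene = "g", taxon = "t")
  call_b <- tiered_search(genome, tiers, engine = eng_b, gene = "g", taxon = "t")
  expect_equal(call_a[c("verdict", "evidence_tier", "hit_class")],
               call_b[c("verdict", "evidence_tier", "hit_class")])
})

test_that("screen results convert to a tip-state matrix", {
  calls <- data.frame(taxon = c("a", "a", "b", "b"),
                      gene = c("g1", "g2", "g1", "g2"),
                      verdict = c("present", "absent", "absent", "present"),
                      evidence_tier = c(1L, NA, NA, 1L),
                      hit_class = c("strong", "none", "none", "strong"))
  m <- calls_to_state_matrix(calls)
  expect_equal(m["a", "g1"], "present")
  expect_equal(m["b", "g1"], "absent")
})
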