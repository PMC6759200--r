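balanced4 <- function() ape::read.tree(text = "((A,B),(C,D));")

test_that("hand-checked topologies give the expected minimal loss counts", {
  tr <- balanced4()
  one <- dollo_loss_map(tr, c(A = "present", B = "present",
                              C = "absent", D = "absent"))
  expect_equal(one$n_independent_losses, 1)
  # the loss sits on the edge above the (C,D) clade
  cd_mrca <- ape::getMRCA(tr, c("C", "D"))
  expect_equal(one$loss_edges$child, cd_mrca)

  two <- dollo_loss_map(tr, c(A = "present", B = "absent",
                              C = "present", D = "absent"))
  expect_equal(two$n_independent_losses, 2)

  none <- dollo_loss_map(tr, c(A = "present", B = "present",
                               C = "present", D = "present"))
  expect_equal(none$n_independent_losses, 0)

  all_absent <- c(A = "absent", B = "absent", C = "absent", D = "absent")
  expect_equal(dollo_loss_map(tr, all_absent)$n_independent_losses, 1)
  root_loss <- dollo_loss_map(tr, all_absent)
  expect_equal(root_loss$loss_edges$child_label, "root")
  no_assume <- dollo_loss_map(tr, all_absent, assume_ancestral_present = FALSE)
  expect_equal(no_assume$n_independent_losses, 0)
  expect_true(all(no_assume$ancestral_state == "absent"))
})

test_that("a single-leaf tree with a present tip has zero losses", {
  tr <- ape::read.tree(text = "(A);")
  expect_equal(dollo_loss_map(tr, c(A = "present"))$n_independent_losses, 0)
  expect_equal(dollo_loss_map(tr, c(A = "absent"))$n_independent_losses, 1)
})

test_that("a missing tip state is an error", {
  expect_error(dollo_loss_map(balanced4(), c(A = "present", B = "present",
                                             C = "absent")),
               "missing")
})

test_that("inferred counts equal exhaustive enumeration on random trees", {
  set.seed(1234)
  for (i in 1:60) {
    n <- sample(4:9, 1)
    tr <- random_rooted_tree(n)
    st <- stats::setNames(sample(c("present", "absent"), n, replace = TRUE),
                          tr$tip.label)
    for (assume in c(TRUE, FALSE)) {
      expect_equal(dollo_loss_map(tr, st, assume_ancestral_present = assume)$n_independent_losses,
                   dollo_brute_force(tr, st, assume),
                   info = paste("tree", i, "assume", assume))
    }
  }
})

test_that("unknown tips are free and never add losses", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    tr <- random_rooted_tree(n)
    st <- stats::setNames(sample(c("present", "absent", "unknown"), n,
                                 replace = TRUE, prob = c(0.4, 0.4, 0.2)),
                          tr$tip.label)
    got <- dollo_loss_map(tr, st)
    expect_equal(got$n_independent_losses, dollo_brute_force(tr, st, TRUE),
                 info = paste("tree", i))
    expect_setequal(got$unknown_tips, names(st)[st == "unknown"])
  }
})

test_that("flipping one absent tip to present never drops the count by more than 1", {
  # Note: such a flip CAN raise the count -- making one tip of a large
  # absent clade present splits that clade's single ancestral loss into
  # several deeper ones (confirmed against exhaustive enumeration), so
  # only the downward direction is bounded.
  set.seed(555)
  for (i in 1:40) {
    n <- sample(5:10, 1)
    tr <- random_rooted_tree(n)
    st <- stats::setNames(sample(c("present", "absent"), n, replace = TRUE),
                          tr$tip.label)
    absents <- names(st)[st == "absent"]
    if (length(absents) == 0) next
    base <- dollo_loss_map(tr, st)$n_independent_losses
    flip <- sample(absents, 1)
    st2 <- st; st2[flip] <- "present"
    after <- dollo_loss_map(tr, st2)$n_independent_losses
    expect_gte(after, base - 1)
    # both before and after agree with the brute-force oracle
    expect_equal(after, dollo_brute_force(tr, st2, TRUE))
  }
})

test_that("the minimal labeling is deterministic across repeated runs", {
  tr <- random_rooted_tree(10)
  set.seed(9)
  st <- stats::setNames(sample(c("present", "absent"), 10, replace = TRUE),
                        tr$tip.label)
  a <- dollo_loss_map(tr, st)
  b <- dollo_loss_map(tr, st)
  expect_identical(a, b)
})

test_that("loss_summary maps every gene and detects two sister-clade losses", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
  # gene lost in (A,B) and in (E,F), retained between them
  states <- matrix("present", nrow = 8, ncol = 2,
                   dimnames = list(LETTERS[1:8], c("CapG2", "CapH2")))
  states[c("A", "B", "E", "F"), "CapG2"] <- "absent"
  tab <- loss_summary(tr, states)
  expect_equal(tab$n_independent_losses[tab$gene == "CapG2"], 2)
  expect_equal(tab$n_independent_losses[tab$gene == "CapH2"], 0)
})

test_that("an order-level loss pattern maps to a single shared ancestral loss", {
  # Diptera, Lepidoptera, Coleoptera form a clade lacking the gene;
  # Hymenoptera (sister) and outgroups retain it
  tr <- ape::read.tree(
    text = "(((((Diptera,Lepidoptera),Coleoptera),Hymenoptera),Hemiptera),Outgroup);")
  st <- c(Diptera = "absent", Lepidoptera = "absent", Coleoptera = "absent",
          Hymenoptera = "present", Hemiptera = "present", Outgroup = "present")
  lm <- dollo_loss_map(tr, st)
  expect_equal(lm$n_independent_losses, 1)
  expect_equal(lm$loss_edges$child,
               ape::getMRCA(tr, c("Diptera", "Lepidoptera", "Coleoptera")))
})

test_that("polytomy edges count a loss once", {
  tr <- ape::read.tree(text = "((A,B,C),D);")
  lm <- dollo_loss_map(tr, c(A = "absent", B = "absent", C = "absent",
                             D = "present"))
  expect_equal(lm$n_independent_losses, 1)
})

test_that("annotated Newick export tags loss edges", {
  tr <- balanced4()
  lm <- dollo_loss_map(tr, c(A = "present", B = "present",
                             C = "absent", D = "absent"), gene = "CapG2")
  nwk <- loss_map_newick(tr, lm)
  expect_match(nwk, "loss=CapG2", fixed = TRUE)
})
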