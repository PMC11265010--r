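test_that("pairwise identity behaves on identical, mutated and unrelated pairs", {
  s <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"
  expect_equal(align_identity(s, s)$identity, 1)
  h <- align_identity(s, sub("^ACGT", "ACTT", s))
  expect_equal(h$identity, 39 / 40)
  expect_equal(h$coverage_short, 1)
  set.seed(1)
  u <- align_identity(random_seq(60), random_seq(60))
  expect_lt(u$identity * u$coverage_short, 0.5)
})

test_that("greedy clustering merges replicates and separates chains past the threshold", {
  s <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"
  expect_error(greedy_cluster(character(0)), "no sequences")
  gc <- greedy_cluster(c(x = s, y = s))
  expect_length(gc$clusters, 1)
  expect_identical(names(gc$clusters), "x") # lexicographic tie-break
  set.seed(2)
  two <- greedy_cluster(c(a = random_seq(60), b = random_seq(60)))
  expect_length(two$clusters, 2)

  # chain: A~B (2/60 subs), B~C (2 more), A!~C; no transitive merging
  set.seed(3)
  A <- random_seq(60)
  B <- mutate_seq(A, 2)    # 96.7% to A
  C <- mutate_seq(B, 4)    # ~93% to A, 93.3% to B < 95%? to B: 56/60 = 93.3%
  gc <- greedy_cluster(c(A = A, B = B, C = C))
  oracle <- oracle_greedy_cluster(c(A = A, B = B, C = C))
  got <- setNames(gc$membership$representative, gc$membership$id)
  expect_identical(got[names(oracle)], oracle)
  expect_identical(unname(got[c("A", "B")]), c("A", "A"))
  expect_identical(unname(got["C"]), "C")
})

test_that("clustering agrees with the exhaustive greedy oracle on random families", {
  set.seed(11)
  for (rep in 1:8) {
    reps <- replicate(3, random_seq(50))
    seqs <- c(reps,
              vapply(sample(1:3, 4, replace = TRUE),
                     function(i) mutate_seq(reps[i], 1), ""))
    names(seqs) <- sprintf("s%02d", seq_along(seqs))
    got <- greedy_cluster(seqs)
    oracle <- oracle_greedy_cluster(seqs)
    gmap <- setNames(got$membership$representative, got$membership$id)
    expect_identical(gmap[names(oracle)], oracle)
  }
})

test_that("clustering is stable under permutations of equal-length input", {
  set.seed(4)
  base <- replicate(2, random_seq(50))
  seqs <- c(base, vapply(c(1, 1, 2), function(i) mutate_seq(base[i], 1), ""))
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  ref <- greedy_cluster(seqs)
  for (i in 1:3) {
    p <- sample(seqs)
    got <- greedy_cluster(p)
    expect_equal(length(got$clusters), length(ref$clusters))
    expect_setequal(names(got$clusters), names(ref$clusters))
  }
})

ref_fixture <- make_reference_tree()

edge_for_node <- function(ref, node) {
  ref$edge_map$edge_num[match(node, ref$edge_map$node)]
}

place_one <- function(ref, edge, w = 0.9, name = "q1") {
  placement_set(ref$tree, ref$edge_map,
                data.frame(name = name, edge_num = edge, like_weight_ratio = w))
}

test_that("placement inside a family clade yields that family", {
  ref <- ref_fixture
  tip <- match("Mimiviridae_1", ref$tree$tip.label)
  call <- classify_placements(place_one(ref, edge_for_node(ref, tip)),
                              ref$clade_map)
  expect_identical(call$decision, "NCLDV")
  expect_identical(call$order, "Imitervirales")
  expect_identical(call$family, "Mimiviridae")
  expect_false(call$excluded)
})

test_that("placement basal to the family clades of an order is order-level unassigned", {
  ref <- ref_fixture
  mrca <- ape::getMRCA(ref$tree, c("Pithoviridae_1", "Iridoviridae_1"))
  call <- classify_placements(place_one(ref, edge_for_node(ref, mrca)),
                              ref$clade_map)
  expect_identical(call$decision, "NCLDV")
  expect_identical(call$order, "Pimascovirales")
  expect_identical(call$family, "unassigned")
})

test_that("families without cultivated representatives give unassigned calls", {
  ref <- ref_fixture
  tip <- match("Imitervirales_nr1_1", ref$tree$tip.label)
  call <- classify_placements(place_one(ref, edge_for_node(ref, tip)),
                              ref$clade_map)
  expect_identical(call$family, "unassigned")
  expect_identical(call$order, "Imitervirales")
})

test_that("outgroup and supra-split placements are non-NCLDV", {
  ref <- ref_fixture
  tip <- match("phage_1", ref$tree$tip.label)
  call <- classify_placements(place_one(ref, edge_for_node(ref, tip)),
                              ref$clade_map)
  expect_identical(call$decision, "non-NCLDV")
  expect_identical(call$family, "not-applicable")
})

test_that("Pandoravirales placements are excluded with a reason", {
  ref <- ref_fixture
  tip <- match("Pandoraviridae_1", ref$tree$tip.label)
  call <- classify_placements(place_one(ref, edge_for_node(ref, tip)),
                              ref$clade_map)
  expect_true(call$excluded)
  expect_identical(call$reason, "pandoravirales-removed")
})

test_that("weak placements are excluded as low-support", {
  ref <- ref_fixture
  tip <- match("Mimiviridae_1", ref$tree$tip.label)
  call <- classify_placements(place_one(ref, edge_for_node(ref, tip), w = 0.3),
                              ref$clade_map)
  expect_true(call$excluded)
  expect_identical(call$reason, "low-support")
})

test_that("classification depends only on the best placement, not candidate order", {
  ref <- ref_fixture
  sp <- simulate_placements(ref, n_true = 25, n_decoy = 25,
                            basal_fraction = 0.2, seed = 21)
  calls <- classify_placements(sp$placements, ref$clade_map)
  shuffled <- sp$placements$placements[sample(nrow(sp$placements$placements)), ]
  ps2 <- placement_set(ref$tree, ref$edge_map, shuffled)
  calls2 <- classify_placements(ps2, ref$clade_map)
  o1 <- order(calls$query); o2 <- order(calls2$query)
  expect_identical(calls[o1, c("query", "decision", "order", "family")],
                   calls2[o2, c("query", "decision", "order", "family")],
                   ignore_attr = TRUE)
})

test_that("decoys confined to outgroup clades give an exact zero FPR", {
  ref <- ref_fixture
  sp <- simulate_placements(ref, n_true = 10, n_decoy = 50, seed = 31)
  calls <- classify_placements(sp$placements, ref$clade_map)
  truth <- setNames(sp$truth$class, sp$truth$name)
  bm <- benchmark_decoys(calls, truth)
  expect_identical(bm$fpr, 0)
  expect_identical(bm$fp, 0L)
  expect_identical(bm$tp, 10L)
  expect_error(benchmark_decoys(calls, truth[-1]), "without truth label")
})

test_that("the confusion summary matches a hand-evaluated small fixture", {
  ref <- ref_fixture
  mimi <- edge_for_node(ref, match("Mimiviridae_2", ref$tree$tip.label))
  phage <- edge_for_node(ref, match("phage_2", ref$tree$tip.label))
  euk <- edge_for_node(ref, match("eukaryote_1", ref$tree$tip.label))
  pl <- data.frame(name = c("t1", "t2", "d1", "d2", "t3"),
                   edge_num = c(mimi, mimi, phage, euk, phage),
                   like_weight_ratio = c(0.9, 0.4, 0.95, 0.8, 0.9))
  calls <- classify_placements(placement_set(ref$tree, ref$edge_map, pl),
                               ref$clade_map)
  truth <- c(t1 = "ncldv", t2 = "ncldv", d1 = "phage", d2 = "eukaryote",
             t3 = "ncldv")
  bm <- benchmark_decoys(calls, truth)
  # by hand: t1 TP; t2 low-support -> FN; t3 placed in phage -> FN;
  # d1, d2 -> TN
  expect_identical(unlist(bm[c("tp", "fp", "tn", "fn")]),
                   c(tp = 1L, fp = 0L, tn = 2L, fn = 2L))
  expect_identical(bm$fpr, 0)
})
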