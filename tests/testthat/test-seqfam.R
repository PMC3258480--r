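test_that("global identity matches hand-checked alignments", {
  expect_equal(global_identity("ACDEFGHIKL", "ACDEFGHIKL")$identity, 100)
  expect_equal(global_identity("ACDEF", "ACDEG")$identity, 80)
  expect_equal(global_identity("AAAA", "CCCC")$identity, 0)
  # symmetric
  set.seed(11)
  a <- rand_seq(60); b <- rand_seq(60)
  expect_equal(global_identity(a, b)$identity,
               global_identity(b, a)$identity)
  expect_error(global_identity("", "ACD"), "empty")
})

test_that("identity graph links exactly the above-threshold pairs", {
  seqs <- setNames(rep(strrep("ACDEFGHIKL", 5), 4), paste0("s", 1:4))
  g <- identity_graph(seqs, 30, 0.8)
  expect_equal(igraph::ecount(g), 6)  # complete graph on 4
  set.seed(5)
  dis <- setNames(replicate(5, rand_seq(80)), paste0("d", 1:5))
  g2 <- identity_graph(dis, 30, 0.8)
  expect_equal(igraph::ecount(g2), 0)
  # planted two-family node: every edge stays within a family
  corpus <- generate_dataset(generator_config(n_ec_nodes = 1,
                                              families_per_node = 2,
                                              members_per_family = 4,
                                              rng_seed = 19))
  seqs3 <- setNames(corpus$dataset$sequences$sequence,
                    corpus$dataset$sequences$record_id)
  g3 <- identity_graph(seqs3, 30, 0.8)
  fam <- corpus$truth$family_of
  ends <- igraph::as_edgelist(g3)
  expect_true(all(fam[ends[, 1]] == fam[ends[, 2]]))
  expect_gt(igraph::ecount(g3), 0)
})

test_that("single linkage takes connected components", {
  # A-B and B-C above threshold, A-C below: one chained cluster
  set.seed(23)
  half1 <- rand_seq(60); half2 <- rand_seq(60); half3 <- rand_seq(60)
  seqs <- c(A = paste0(half1, half2), B = paste0(half2, half3),
            C = paste0(half3, rand_seq(60)))
  expect_gte(global_identity(seqs[["A"]], seqs[["B"]])$identity, 30)
  expect_gte(global_identity(seqs[["B"]], seqs[["C"]])$identity, 30)
  expect_lt(global_identity(seqs[["A"]], seqs[["C"]])$identity, 30)
  g <- identity_graph(seqs, 30, 0)
  cs <- single_linkage_partition(g, node = "1.1.1.1")
  expect_equal(n_clusters(cs), 1L)
  expect_setequal(cs$clusters[["C001"]], c("A", "B", "C"))
  # edgeless graph -> all singletons; empty input -> empty partition
  set.seed(6)
  dis <- setNames(replicate(5, rand_seq(80)), paste0("d", 1:5))
  cs2 <- single_linkage_partition(identity_graph(dis, 30, 0.8))
  expect_equal(n_clusters(cs2), 5L)
  cs3 <- single_linkage_partition(identity_graph(setNames(character(0),
                                                          character(0))))
  expect_equal(n_clusters(cs3), 0L)
})

test_that("single linkage equals the brute-force transitive closure", {
  for (seed in 1:3) {
    cfg <- generator_config(n_ec_nodes = 1, families_per_node = 3,
                            members_per_family = c(2, 4), seq_length = 100,
                            rng_seed = 100 + seed)
    corpus <- generate_dataset(cfg)
    seqs <- setNames(corpus$dataset$sequences$sequence,
                     corpus$dataset$sequences$record_id)
    expect_lte(length(seqs), 12L)
    got <- single_linkage_partition(identity_graph(seqs, 30, 0.8))
    oracle <- brute_force_families(seqs, 30, 0.8)
    expect_equal(unname(got$clusters), oracle)
  }
})

test_that("partitions are invariant under input order", {
  corpus <- generate_dataset(generator_config(n_ec_nodes = 1,
                                              families_per_node = 3,
                                              rng_seed = 37))
  seqs <- setNames(corpus$dataset$sequences$sequence,
                   corpus$dataset$sequences$record_id)
  cs1 <- single_linkage_partition(identity_graph(seqs, 30, 0.8))
  set.seed(1)
  shuffled <- seqs[sample(length(seqs))]
  cs2 <- single_linkage_partition(identity_graph(shuffled, 30, 0.8))
  expect_identical(cs1$clusters, cs2$clusters)
})

test_that("cluster count is monotone in the identity threshold", {
  corpus <- generate_dataset(generator_config(n_ec_nodes = 1,
                                              families_per_node = 4,
                                              rng_seed = 41))
  seqs <- setNames(corpus$dataset$sequences$sequence,
                   corpus$dataset$sequences$record_id)
  counts <- vapply(c(5, 30, 60, 85, 99), function(thr) {
    n_clusters(single_linkage_partition(identity_graph(seqs, thr, 0.8)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("profiles follow the center-star pseudocount scheme", {
  seqs <- c(m1 = "ACDEFGHIKL", m2 = "ACDEFGHIKL")
  pr <- build_profile(seqs)
  # modal frequency (2 + 0.1) / (2 + 2.0); columns renormalized to 1
  expect_equal(max(pr$freqs[, 1]), 2.1 / 4)
  expect_equal(unname(colSums(pr$freqs)), rep(1, 10))
  expect_equal(ncol(pr$freqs), nchar(seqs[["m1"]]))
  expect_equal(pr$consensus, "ACDEFGHIKL")
  # center is the longest member, ties to the smallest id
  seqs2 <- c(b = "ACDEFGHIKL", a = "ACDEFGHIKL", c = "ACDEFGHIKLMN")
  expect_equal(build_profile(seqs2)$center_id, "c")
  expect_equal(build_profile(seqs2[1:2])$center_id, "a")
  expect_error(build_profile(seqs["m1"]), ">= 2 members")
})

test_that("singleton merging absorbs kin and respects tie-breaks", {
  base <- strrep("ACDEFGHIKLMNPQRSTVWY", 5)
  seqs <- c(a1 = base, a2 = base, s = base)
  cs <- cluster_set(list(c("a1", "a2"), "s"), node = "1.1.1.1")
  merged <- merge_singletons(cs, seqs, tau = -1)
  expect_equal(n_clusters(merged), 1L)
  expect_equal(merged$stage, "merged")
  expect_setequal(merged$clusters[["C001"]], c("a1", "a2", "s"))
  # no singletons -> unchanged blocks
  cs2 <- cluster_set(list(c("a1", "a2"), c("s", "s2")))
  merged2 <- merge_singletons(cs2, c(seqs, s2 = base), tau = -1)
  expect_equal(unname(lapply(merged2$clusters, sort)),
               unname(lapply(cs2$clusters, sort)))
  # symmetric two-cluster tie: both profiles score the singleton equally,
  # merge goes to the lexicographically smallest label
  seqs3 <- c(a1 = base, a2 = base, b1 = base, b2 = base, s = base)
  cs3 <- cluster_set(list(c("a1", "a2"), c("b1", "b2"), "s"))
  p_a <- build_profile(seqs3[c("a1", "a2")])
  p_b <- build_profile(seqs3[c("b1", "b2")])
  expect_equal(catkit:::profile_score(p_a, base),
               catkit:::profile_score(p_b, base))
  merged3 <- merge_singletons(cs3, seqs3, tau = -1)
  expect_equal(n_clusters(merged3), 2L)
  expect_setequal(merged3$clusters[["C001"]], c("a1", "a2", "s"))
  # a merge below tau is refused
  merged4 <- merge_singletons(cs, seqs, tau = 0)
  expect_equal(n_clusters(merged4), 2L)
})

test_that("families per node recovers the planted structure", {
  d1 <- mini_dataset("ACDEFGHIKLMNP", catalytic_positions = 1)
  fc1 <- families_per_node(d1)
  expect_equal(fc1$per_node$raw, 1L)
  expect_equal(fc1$per_node$merged, 1L)

  cfg <- generator_config(n_ec_nodes = 20, rng_seed = 55)
  corpus <- generate_dataset(cfg)
  fc <- families_per_node(corpus$dataset)
  expect_true(all(fc$per_node$merged <= fc$per_node$raw))
  est <- setNames(fc$per_node$merged, fc$per_node$node)
  truth <- corpus$truth$node_family_counts
  expect_equal(est[names(truth)], truth, ignore_attr = TRUE)
  # records with several complete nodes are clustered under each node
  d <- corpus$dataset
  d$units$ec_nodes[1] <- paste0(d$units$ec_nodes[1], ";6.1.1.999")
  fc2 <- families_per_node(d)
  expect_equal(nrow(fc2$per_node), 21L)
  expect_equal(fc2$per_node$raw[fc2$per_node$node == "6.1.1.999"], 1L)
})
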