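# helper: one single-chain record with given CATH codes, catalytic site in
# the first domain
struct_record <- function(id, sequence, codes, ec = "1.1.1.1",
                          has_structure = TRUE) {
  L <- nchar(sequence)
  bounds <- round(seq(0, L, length.out = length(codes) + 1))
  enzyme_dataset(
    sequences = data.frame(record_id = id, chain_id = "A",
                           sequence = sequence, stringsAsFactors = FALSE),
    residues = data.frame(record_id = id, chain_id = "A", position = 1L,
                          residue_type = substr(sequence, 1, 1),
                          function_context = "catalytic",
                          involvement = "spectator",
                          roles = "stabilization",
                          acting_part = "side_chain",
                          stringsAsFactors = FALSE),
    domains = data.frame(record_id = id, chain_id = "A", cath_code = codes,
                         segments = paste0(bounds[-length(bounds)] + 1, "-",
                                           bounds[-1]),
                         stringsAsFactors = FALSE),
    units = data.frame(record_id = id, biological_unit_chains = "A",
                       catalytic_unit_chains = "A", ec_nodes = ec,
                       has_structure = has_structure,
                       stringsAsFactors = FALSE),
    strict = FALSE)
}

test_that("domain combination keys are canonical multisets", {
  set.seed(2)
  d <- struct_record("R1", rand_seq(120),
                     c("3.40.50.720", "1.10.600.10"))
  expect_equal(domain_combination(get_record(d, "R1")),
               "1.10.600.10+3.40.50.720")
  d2 <- struct_record("R2", rand_seq(60), "2.40.10.10")
  expect_equal(domain_combination(get_record(d2, "R2")), "2.40.10.10")
  # sorting is numeric per dotted field, not lexicographic
  d3 <- struct_record("R3", rand_seq(120),
                      c("3.40.50.720", "3.40.50.9"))
  expect_equal(domain_combination(get_record(d3, "R3")),
               "3.40.50.9+3.40.50.720")
  # domain listing order never matters
  d4 <- struct_record("R4", rand_seq(120),
                      c("1.10.600.10", "3.40.50.720"))
  expect_equal(domain_combination(get_record(d4, "R4")),
               domain_combination(get_record(d, "R1")))
})

test_that("multiplicity is preserved across chains", {
  # pyruvate-dehydrogenase-like: same catalytic domain on two chains
  d <- enzyme_dataset(
    sequences = data.frame(record_id = "R1", chain_id = c("A", "B"),
                           sequence = c("ACDEFGHIKL", "ACDEFGHIKW"),
                           stringsAsFactors = FALSE),
    residues = data.frame(record_id = "R1", chain_id = c("A", "B"),
                          position = c(1L, 2L), residue_type = c("A", "C"),
                          function_context = "catalytic",
                          involvement = "reactant", roles = "activation",
                          acting_part = "side_chain",
                          stringsAsFactors = FALSE),
    domains = data.frame(record_id = "R1", chain_id = c("A", "B"),
                         cath_code = "3.40.50.970", segments = "1-10",
                         stringsAsFactors = FALSE),
    units = data.frame(record_id = "R1", biological_unit_chains = "A,B",
                       catalytic_unit_chains = "A,B", ec_nodes = "1.2.4.1",
                       has_structure = TRUE, stringsAsFactors = FALSE),
    strict = FALSE)
  expect_equal(domain_combination(get_record(d, "R1")),
               "3.40.50.970+3.40.50.970")
})

test_that("records without domains are flagged and excluded", {
  d <- mini_dataset("ACDEFGHIKL", catalytic_positions = 1)
  expect_warning(key <- domain_combination(get_record(d, "R1")),
                 "no domain")
  expect_true(is.na(key))
})

test_that("structural partition groups by key then splits by identity", {
  set.seed(14)
  s <- rand_seq(100)
  same <- bind_datasets(struct_record("R1", s, "3.40.50.720"),
                        struct_record("R2", s, "3.40.50.720"))
  cs <- structural_partition(same, c("R1", "R2"))
  expect_equal(n_clusters(cs), 1L)

  diff_key <- bind_datasets(struct_record("R1", s, "3.40.50.720"),
                            struct_record("R2", s, "2.40.10.10"))
  expect_equal(n_clusters(structural_partition(diff_key, c("R1", "R2"))),
               2L)

  # same key, unrelated sequences (identity below the floor): kept apart
  u <- rand_seq(100)
  expect_lt(global_identity(s, u)$identity, 20)
  low <- bind_datasets(struct_record("R1", s, "3.40.50.720"),
                       struct_record("R2", u, "3.40.50.720"))
  expect_equal(n_clusters(structural_partition(low, c("R1", "R2"))), 2L)
  # ... but pure combination counting collapses them
  expect_equal(n_clusters(structural_partition(low, c("R1", "R2"),
                                               seq_refine = FALSE)), 1L)
})

test_that("refinement is monotone in the identity floor", {
  corpus <- generate_dataset(generator_config(n_ec_nodes = 1,
                                              families_per_node = 3,
                                              structure_prob = 1,
                                              rng_seed = 61))
  ids <- record_ids(corpus$dataset)
  counts <- vapply(c(0, 5, 20, 50, 80, 99), function(fl) {
    n_clusters(structural_partition(corpus$dataset, ids,
                                    identity_floor = fl))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("restrict_to_structures keeps exactly the flagged records", {
  corpus <- generate_dataset(generator_config(n_ec_nodes = 6, rng_seed = 3))
  d <- corpus$dataset
  sub <- restrict_to_structures(d)
  expect_equal(n_records(sub), sum(d$units$has_structure))
  d$units$has_structure <- FALSE
  expect_equal(n_records(restrict_to_structures(d)), 0L)
  d$units$has_structure <- TRUE
  expect_equal(record_ids(restrict_to_structures(d)), record_ids(d))
})

test_that("structural families recover the planted counts", {
  cfg <- generator_config(n_ec_nodes = 12, rng_seed = 77)
  corpus <- generate_dataset(cfg)
  sf <- structural_families_per_node(corpus$dataset)
  # planted truth restricted to structure-bearing records
  d <- corpus$dataset
  fam <- corpus$truth$family_of
  withstr <- d$units$record_id[d$units$has_structure]
  for (k in seq_len(nrow(sf$per_node))) {
    nd <- sf$per_node$node[k]
    in_node <- d$units$record_id[vapply(
      strsplit(d$units$ec_nodes, ";"), function(v) nd %in% v, logical(1))]
    planted <- length(unique(fam[intersect(in_node, withstr)]))
    expect_equal(sf$per_node$families[k], planted, label = nd)
  }
})

test_that("structural counts never exceed raw sequence counts", {
  corpus <- generate_dataset(generator_config(n_ec_nodes = 10,
                                              rng_seed = 99))
  sub <- restrict_to_structures(corpus$dataset)
  fc <- families_per_node(sub, merge = FALSE)
  sf <- structural_families_per_node(corpus$dataset)
  common <- intersect(fc$per_node$node, sf$per_node$node)
  expect_gt(length(common), 0L)
  raw <- setNames(fc$per_node$raw, fc$per_node$node)[common]
  str_counts <- setNames(sf$per_node$families, sf$per_node$node)[common]
  expect_true(all(str_counts <= raw))
})
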