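# hand-built record: one chain, explicit domains and residue annotations
arch_record <- function(id = "R1", n_domains = 2, dom_len = 20,
                        cath_codes = NULL, catalytic_at = integer(0),
                        binding_at = integer(0), ec = "1.1.1.1",
                        catalytic_unit_chains = "A") {
  L <- n_domains * dom_len
  seq <- strrep("A", L)
  if (is.null(cath_codes)) {
    cath_codes <- sprintf("3.40.50.%d", 100 + seq_len(n_domains))
  }
  segs <- paste0((seq_len(n_domains) - 1) * dom_len + 1, "-",
                 seq_len(n_domains) * dom_len)
  res <- NULL
  if (length(catalytic_at) || length(binding_at)) {
    res <- rbind(
      if (length(catalytic_at)) data.frame(
        record_id = id, chain_id = "A", position = catalytic_at,
        residue_type = "A", function_context = "catalytic",
        involvement = "spectator", roles = "stabilization",
        acting_part = "main_chain_NH", stringsAsFactors = FALSE),
      if (length(binding_at)) data.frame(
        record_id = id, chain_id = "A", position = binding_at,
        residue_type = "A", function_context = "binding",
        involvement = "", roles = "", acting_part = "main_chain_NH",
        stringsAsFactors = FALSE))
  }
  enzyme_dataset(
    sequences = data.frame(record_id = id, chain_id = "A", sequence = seq,
                           stringsAsFactors = FALSE),
    residues = res,
    domains = data.frame(record_id = id, chain_id = "A",
                         cath_code = cath_codes, segments = segs,
                         stringsAsFactors = FALSE),
    units = data.frame(record_id = id, biological_unit_chains = "A",
                       catalytic_unit_chains = catalytic_unit_chains,
                       ec_nodes = ec, has_structure = TRUE,
                       stringsAsFactors = FALSE),
    strict = FALSE)
}

test_that("domain labels follow the one-catalytic / three-binding rule", {
  # domain 1 hosts 1 catalytic residue, domain 2 hosts 3 binding residues
  d <- arch_record(n_domains = 3, catalytic_at = 5,
                   binding_at = c(21, 25, 30))
  roles <- classify_domain_roles(get_record(d, "R1"))
  expect_equal(roles$label, c("catalytic", "binding", "other"))
  expect_equal(roles$n_catalytic_residues, c(1L, 0L, 0L))
  expect_equal(roles$n_binding_residues, c(0L, 3L, 0L))
  # two binding residues are strictly below the threshold
  d2 <- arch_record(n_domains = 2, catalytic_at = 5, binding_at = c(21, 25))
  roles2 <- classify_domain_roles(get_record(d2, "R1"))
  expect_equal(roles2$label, c("catalytic", "other"))
  # a catalytic domain hosting binding residues stays catalytic
  d3 <- arch_record(n_domains = 1, catalytic_at = 5, binding_at = c(1:3))
  expect_equal(classify_domain_roles(get_record(d3, "R1"))$label,
               "catalytic")
})

test_that("linker catalytic residues are reported, never invent a domain", {
  d <- arch_record(n_domains = 1, dom_len = 20, catalytic_at = 5)
  # shrink the domain so position 5 falls outside every segment
  d$domains$segments <- "10-20"
  expect_message(roles <- classify_domain_roles(get_record(d, "R1")),
                 "outside every domain segment")
  expect_equal(attr(roles, "unassigned_catalytic"), 1L)
  expect_equal(roles$label, "other")
})

test_that("every domain gets exactly one label", {
  corpus <- generate_dataset(generator_config(n_ec_nodes = 5, rng_seed = 6))
  d <- corpus$dataset
  n_lab <- 0L
  for (id in record_ids(d)) {
    roles <- classify_domain_roles(get_record(d, id))
    expect_true(all(roles$label %in% c("catalytic", "binding", "other")))
    n_lab <- n_lab + nrow(roles)
  }
  expect_equal(n_lab, nrow(d$domains))
})

test_that("catalytic unit honours annotation, else derives from domains", {
  d <- arch_record(n_domains = 1, catalytic_at = 5)
  cu <- catalytic_unit(get_record(d, "R1"))
  expect_equal(cu$chains, "A")
  expect_equal(cu$source, "annotated")
  # interface case: catalytic residues split across two chains
  toy <- read_dataset(toy_dir())
  r2 <- get_record(toy, "R2")
  expect_setequal(catalytic_unit(r2)$chains, c("A", "B"))
  r2b <- r2
  r2b$catalytic_unit_chains <- character(0)   # force derivation
  cu2 <- catalytic_unit(r2b)
  expect_setequal(cu2$chains, c("A", "B"))
  expect_equal(cu2$source, "derived")
  # annotated unit overrides the derivation
  r2c <- r2
  r2c$catalytic_unit_chains <- "A"
  expect_equal(catalytic_unit(r2c)$chains, "A")
  # derived unit is always inside the biological unit
  expect_true(all(cu2$chains %in% r2$biological_unit_chains))
})

test_that("architecture signatures canonicalize letters and stars", {
  d1 <- arch_record(n_domains = 1, catalytic_at = 5)
  s1 <- architecture_signature(get_record(d1, "R1"))
  expect_equal(s1$catalytic_unit_pattern, "A*")
  expect_equal(s1$n_bio_domains, 1L)

  d2 <- arch_record(n_domains = 2, catalytic_at = 5)
  s2 <- architecture_signature(get_record(d2, "R1"))
  expect_equal(s2$catalytic_unit_pattern, "A*B")
  expect_equal(s2$n_bio_domains, 2L)

  d3 <- arch_record(n_domains = 2, catalytic_at = c(5, 25),
                    cath_codes = rep("3.40.50.970", 2))
  expect_equal(architecture_signature(get_record(d3, "R1"))$
                 catalytic_unit_pattern, "A*A*")
  # letter assignment ignores domain listing order
  d4 <- arch_record(n_domains = 2, catalytic_at = 25,
                    cath_codes = c("9.10.10.10", "1.10.600.10"))
  expect_equal(architecture_signature(get_record(d4, "R1"))$
                 catalytic_unit_pattern, "A*B")
})

test_that("the census partitions the corpus", {
  empty <- enzyme_dataset(
    sequences = data.frame(record_id = character(0),
                           chain_id = character(0),
                           sequence = character(0)))
  expect_equal(nrow(configuration_census(empty)$census), 0L)

  ds <- bind_datasets(
    arch_record("R1", n_domains = 1, catalytic_at = 5),
    arch_record("R2", n_domains = 1, catalytic_at = 5),
    arch_record("R3", n_domains = 2, catalytic_at = 5),
    arch_record("R4", n_domains = 2, catalytic_at = c(5, 25),
                cath_codes = rep("3.40.50.970", 2)))
  cc <- configuration_census(ds)
  expect_equal(sum(cc$census$count), 4L)
  expect_equal(cc$census$count[cc$census$pattern == "A*" &
                                 cc$census$n_bio_domains == 1], 2L)
  expect_equal(cc$census$count[cc$census$pattern == "A*B"], 1L)
  expect_equal(cc$census$count[cc$census$pattern == "A*A*"], 1L)
  # permutation invariance
  ids <- rev(record_ids(ds))
  cc2 <- configuration_census(subset_dataset(ds, ids))
  expect_equal(cc2$census, cc$census)
})

test_that("single-domain fraction needs both assemblies single", {
  all_single <- bind_datasets(arch_record("R1", 1, catalytic_at = 5),
                              arch_record("R2", 1, catalytic_at = 5))
  expect_equal(single_domain_fraction(all_single), 1)
  none <- arch_record("R1", 3, catalytic_at = 5)
  expect_equal(single_domain_fraction(none), 0)
  mixed <- bind_datasets(arch_record("R1", 1, catalytic_at = 5),
                         arch_record("R2", 2, catalytic_at = 5),
                         arch_record("R3", 2, catalytic_at = 5),
                         arch_record("R4", 1, catalytic_at = 5))
  expect_equal(single_domain_fraction(mixed), 0.5)
})

test_that("domain promiscuity counts distinct nodes and classes", {
  one <- arch_record("R1", 1, catalytic_at = 5, cath_codes = "3.40.50.720")
  p1 <- domain_ec_promiscuity(one)
  expect_equal(p1$table$ec_node_count, 1L)
  expect_equal(p1$table$ec_class_count, 1L)

  two_nodes <- bind_datasets(
    arch_record("R1", 1, catalytic_at = 5, cath_codes = "3.40.50.720",
                ec = "1.1.1.1"),
    arch_record("R2", 1, catalytic_at = 5, cath_codes = "3.40.50.720",
                ec = "1.1.1.2"))
  p2 <- domain_ec_promiscuity(two_nodes)
  expect_equal(p2$table$ec_node_count, 2L)
  expect_equal(p2$table$ec_class_count, 1L)

  two_classes <- bind_datasets(
    arch_record("R1", 1, catalytic_at = 5, cath_codes = "2.40.10.10",
                ec = "2.7.11.1"),
    arch_record("R2", 1, catalytic_at = 5, cath_codes = "2.40.10.10",
                ec = "3.4.21.4"))
  p3 <- domain_ec_promiscuity(two_classes)
  expect_equal(p3$table$ec_node_count, 2L)
  expect_equal(p3$table$ec_class_count, 2L)

  # non-catalytic codes appear only with all_domains = TRUE
  d <- arch_record("R1", 2, catalytic_at = 5)  # second domain never catalytic
  expect_equal(nrow(domain_ec_promiscuity(d)$table), 1L)
  expect_equal(nrow(domain_ec_promiscuity(d, all_domains = TRUE)$table), 2L)

  # class count never exceeds node count (synthetic corpus)
  corpus <- generate_dataset(generator_config(n_ec_nodes = 12,
                                              rng_seed = 23))
  pt <- domain_ec_promiscuity(corpus$dataset)$table
  expect_true(all(pt$ec_class_count <= pmin(6L, pt$ec_node_count)))
  expect_true(all(pt$ec_class_count >= 1L))
})
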