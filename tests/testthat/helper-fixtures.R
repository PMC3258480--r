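# Shared fixtures and independent oracles, built in code.

toy_dir <- function() {
  system.file("extdata", "toy", package = "catkit")
}

# minimal single-record dataset around one chain; annotations optional
mini_dataset <- function(sequence, catalytic_positions = integer(0),
                         binding_positions = integer(0),
                         ec = "1.1.1.1", record_id = "R1",
                         roles = "stabilization", cofactor = FALSE,
                         strict = FALSE) {
  letters_at <- function(p) substr(sequence, p, p)
  res <- NULL
  if (length(catalytic_positions) || length(binding_positions)) {
    res <- rbind(
      if (length(catalytic_positions)) data.frame(
        record_id = record_id, chain_id = "A",
        position = catalytic_positions,
        residue_type = vapply(catalytic_positions, letters_at, ""),
        function_context = "catalytic", involvement = "spectator",
        roles = roles, acting_part = "side_chain",
        stringsAsFactors = FALSE),
      if (length(binding_positions)) data.frame(
        record_id = record_id, chain_id = "A",
        position = binding_positions,
        residue_type = vapply(binding_positions, letters_at, ""),
        function_context = "binding", involvement = "", roles = "",
        acting_part = "side_chain", stringsAsFactors = FALSE))
  }
  cof <- if (cofactor) data.frame(
    record_id = record_id, cofactor_id = "ZN", entity_kind = "metal_ion",
    roles = "stabilization", stringsAsFactors = FALSE) else NULL
  enzyme_dataset(
    sequences = data.frame(record_id = record_id, chain_id = "A",
                           sequence = sequence, stringsAsFactors = FALSE),
    residues = res,
    cofactors = cof,
    units = data.frame(record_id = record_id, biological_unit_chains = "A",
                       catalytic_unit_chains = "A", ec_nodes = ec,
                       has_structure = TRUE, stringsAsFactors = FALSE),
    strict = strict)
}

# stack several single-record datasets into one corpus
bind_datasets <- function(...) {
  parts <- list(...)
  enzyme_dataset(
    sequences = do.call(rbind, lapply(parts, `[[`, "sequences")),
    residues = do.call(rbind, lapply(parts, `[[`, "residues")),
    domains = do.call(rbind, lapply(parts, `[[`, "domains")),
    cofactors = do.call(rbind, lapply(parts, `[[`, "cofactors")),
    units = do.call(rbind, lapply(parts, `[[`, "units")),
    strict = FALSE)
}

# independent single-linkage oracle: transitive closure of the pairwise
# above-threshold relation, by iterated boolean composition
brute_force_families <- function(sequences, identity_threshold = 30,
                                 coverage_threshold = 0.8) {
  n <- length(sequences)
  ids <- sort(names(sequences))
  sequences <- sequences[ids]
  rel <- diag(n) == 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        g <- global_identity(sequences[[i]], sequences[[j]])
        hit <- g$identity >= identity_threshold &&
          g$coverage >= coverage_threshold
        rel[i, j] <- rel[j, i] <- hit
      }
    }
  }
  repeat {
    closed <- (rel %*% rel) > 0 | rel
    if (identical(closed, rel)) break
    rel <- closed
  }
  blocks <- unique(lapply(seq_len(n), function(i) sort(ids[rel[i, ]])))
  blocks[order(vapply(blocks, `[`, "", 1L))]
}

# random amino-acid string
rand_seq <- function(n) paste(sample(aa_alphabet, n, TRUE), collapse = "")
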