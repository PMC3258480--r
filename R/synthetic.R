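# Synthetic mechanism-level enzyme corpora with planted ground truth:
# per-EC-node family structure with controlled within/between-family percent
# identity, catalytic sites drawn under per-class propensity multipliers,
# seven-category role assignments across the three catalytic entity kinds,
# and planted domain architectures.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

default_role_weights <- function() {
  res <- setNames(c(rep(1, 7), 0), all_roles)   # hydride shuttle forced 0
  org <- setNames(rep(1, 8), all_roles)         # only organic cofactors may
  list(residue = res, metal_ion = res, organic_cofactor = org)
}

default_architecture_patterns <- function() {
  # letters = domain identity; '*' marks a catalytic domain, '+' a designated
  # binding domain (receives three planted binding residues). Weights follow
  # the census shape of mechanism-level corpora: single-domain enzymes
  # dominate, multi-domain biological units around a single catalytic domain
  # are common, duplicated catalytic domains and binding partners rarer.
  data.frame(
    pattern = c("A*", "A*B", "A*BC", "A*BCD", "A*A*", "A*B+"),
    weight = c(86, 24, 5, 2, 10, 10),
    stringsAsFactors = FALSE
  )
}

default_cath_pool <- function(n = 40) {
  i <- seq_len(n)
  sprintf("%d.%d.%d.%d", 1L + (i - 1L) %% 3L, 10L * (1L + (i - 1L) %% 4L),
          10L + i, 10L * i)
}

#' Configuration for the synthetic corpus generator
#'
#' Describes the statistical world the generator emulates: how many EC nodes,
#' how many evolutionary families per node and members per family, sequence
#' lengths, the within-family percent identity and the cap on between-family
#' identity (the separability condition \code{within > clustering threshold >
#' cap} is what makes family recovery well-posed), catalytic-residue
#' propensity multipliers per EC class, role-assignment weights per catalytic
#' entity kind (with \code{hydride_shuttle} weight forced to zero for
#' residues and metal ions by default), and the pool of domain architecture
#' patterns.
#'
#' @param n_ec_nodes number of EC nodes to generate.
#' @param families_per_node integer vector: if of length \code{n_ec_nodes}
#'   it is used as-is, if length 1 it is constant, otherwise each node
#'   samples uniformly from it. Default \code{1:4}.
#' @param members_per_family scalar or length-2 range (inclusive).
#' @param seq_length chain length, scalar or length-2 range.
#' @param within_family_identity target pairwise percent identity between
#'   members of one family (default 90).
#' @param between_family_identity_cap maximum percent identity allowed
#'   between family founders within a node (default 15; enforced by
#'   rejection sampling, max 100 retries).
#' @param propensity_multipliers named numeric vector (names in
#'   \code{\link{aa_alphabet}}) of positive multipliers applied to the
#'   background frequency when drawing catalytic residue types, or a
#'   20 x 6 matrix (rows = residue types, columns = EC classes). Unnamed
#'   types default to 1.
#' @param background_freqs named frequency vector over the 20 types used to
#'   draw sequences (default uniform 1/20, which makes planted propensities
#'   exactly interpretable).
#' @param n_catalytic_per_record scalar or range.
#' @param n_binding_per_binding_domain binding residues planted in each
#'   designated binding domain (default 3, the classification threshold).
#' @param reactant_prob probability a catalytic residue is annotated
#'   \code{reactant} rather than \code{spectator}.
#' @param roles_per_annotation scalar or range of role-category counts drawn
#'   per annotation.
#' @param role_weights list with elements \code{residue}, \code{metal_ion},
#'   \code{organic_cofactor}: named non-negative weights over
#'   \code{\link{all_roles}}.
#' @param cofactor_prob probability a record carries a cofactor.
#' @param organic_cofactor_prob given a cofactor, probability it is organic
#'   rather than a metal ion.
#' @param architecture_patterns data.frame with columns \code{pattern}
#'   (letters with \code{*} = catalytic and \code{+} = binding markers) and
#'   \code{weight}; one pattern is drawn per family.
#' @param cath_pool character vector of CATH H-level codes assigned to
#'   pattern letters.
#' @param structure_prob probability a record is flagged as having a solved
#'   structure.
#' @param indel_rate per-member probability of a single 1-3 residue indel;
#'   default 0 (substitution-only model keeps identity targeting exact).
#' @param rng_seed integer seed; fixed seed gives byte-identical corpora.
#' @return A validated list of class \code{generator_config}.
#' @seealso \code{\link{generate_dataset}}
#' @export
generator_config <- function(n_ec_nodes = 20,
                             families_per_node = 1:4,
                             members_per_family = 3,
                             seq_length = 150,
                             within_family_identity = 90,
                             between_family_identity_cap = 15,
                             propensity_multipliers = NULL,
                             background_freqs = NULL,
                             n_catalytic_per_record = 3,
                             n_binding_per_binding_domain = 3,
                             reactant_prob = 0.5,
                             roles_per_annotation = c(1, 2),
                             role_weights = default_role_weights(),
                             cofactor_prob = 0.3,
                             organic_cofactor_prob = 0.5,
                             architecture_patterns =
                               default_architecture_patterns(),
                             cath_pool = default_cath_pool(),
                             structure_prob = 0.5,
                             indel_rate = 0,
                             rng_seed = 1L) {
  if (is.null(background_freqs)) {
    background_freqs <- setNames(rep(1 / 20, 20), aa_alphabet)
  }
  background_freqs <- background_freqs[aa_alphabet] /
    sum(background_freqs[aa_alphabet])
  mult <- matrix(1, nrow = 20, ncol = 6,
                 dimnames = list(aa_alphabet, as.character(1:6)))
  if (!is.null(propensity_multipliers)) {
    if (is.matrix(propensity_multipliers)) {
      mult[rownames(propensity_multipliers),
           colnames(propensity_multipliers)] <- propensity_multipliers
    } else {
      for (r in names(propensity_multipliers)) {
        mult[r, ] <- propensity_multipliers[[r]]
      }
    }
  }
  cfg <- structure(list(
    n_ec_nodes = as.integer(n_ec_nodes),
    families_per_node = as.integer(families_per_node),
    members_per_family = as.integer(members_per_family),
    seq_length = as.integer(seq_length),
    within_family_identity = within_family_identity,
    between_family_identity_cap = between_family_identity_cap,
    propensity_multipliers = mult,
    background_freqs = background_freqs,
    n_catalytic_per_record = as.integer(n_catalytic_per_record),
    n_binding_per_binding_domain = as.integer(n_binding_per_binding_domain),
    reactant_prob = reactant_prob,
    roles_per_annotation = as.integer(roles_per_annotation),
    role_weights = role_weights,
    cofactor_prob = cofactor_prob,
    organic_cofactor_prob = organic_cofactor_prob,
    architecture_patterns = architecture_patterns,
    cath_pool = cath_pool,
    structure_prob = structure_prob,
    indel_rate = indel_rate,
    rng_seed = as.integer(rng_seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$within_family_identity <= cfg$between_family_identity_cap) {
    stop("infeasible config: within_family_identity (",
         cfg$within_family_identity,
         ") must exceed between_family_identity_cap (",
         cfg$between_family_identity_cap, ")")
  }
  if (any(cfg$propensity_multipliers <= 0)) {
    stop("infeasible config: propensity multipliers must be positive")
  }
  for (kind in c("residue", "metal_ion", "organic_cofactor")) {
    w <- cfg$role_weights[[kind]]
    if (is.null(w) || any(w < 0) || !all(all_roles %in% names(w))) {
      stop("role_weights$", kind,
           " must be non-negative weights named over all roles")
    }
    if (sum(w) == 0) stop("role_weights$", kind, " sums to zero")
  }
  if (any(cfg$architecture_patterns$weight < 0)) {
    stop("architecture pattern weights must be non-negative")
  }
  if (any(cfg$families_per_node < 1L)) {
    stop("families_per_node must be >= 1")
  }
  invisible(cfg)
}

sample_in <- function(x) {
  if (length(x) == 1L) return(x)
  if (length(x) == 2L) return(sample(seq(x[1L], x[2L]), 1L))
  x[sample.int(length(x), 1L)]
}

random_sequence <- function(len, freqs) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

#' Mutate a sequence to a target percent identity
#'
#' Substitution-only divergence model: \code{round(L * (100 - target) / 100)}
#' positions are chosen without replacement and each is replaced by a
#' different residue drawn uniformly from the remaining 19. The positional
#' identity between input and output therefore hits the target up to the
#' rounding of the substitution count. With \code{indel_rate > 0} a single
#' short (1-3 residue) insertion or deletion is additionally applied with
#' that probability.
#'
#' @param seq amino-acid string.
#' @param target_identity target percent identity in [0, 100].
#' @param indel_rate probability of one short indel (default 0).
#' @return the mutated sequence string.
#' @examples
#' set.seed(1)
#' mutate_to_identity("ACDEFGHIKL", 100)  # unchanged
#' @export
mutate_to_identity <- function(seq, target_identity, indel_rate = 0) {
  stopifnot(target_identity >= 0, target_identity <= 100)
  v <- strsplit(seq, "")[[1]]
  n_sub <- round(length(v) * (100 - target_identity) / 100)
  if (n_sub > 0) {
    pos <- sample.int(length(v), n_sub)
    v[pos] <- vapply(v[pos], function(old) {
      sample(setdiff(aa_alphabet, old), 1L)
    }, character(1))
  }
  if (indel_rate > 0 && stats::runif(1) < indel_rate) {
    k <- sample.int(3L, 1L)
    if (stats::runif(1) < 0.5 && length(v) > k + 1L) {
      at <- sample.int(length(v) - k, 1L)
      v <- v[-(at:(at + k - 1L))]
    } else {
      at <- sample.int(length(v), 1L)
      ins <- sample(aa_alphabet, k, replace = TRUE)
      v <- append(v, ins, after = at)
    }
  }
  paste(v, collapse = "")
}

# tokenize "A*B+C" -> data.frame(letter, catalytic, binding)
parse_pattern <- function(pattern) {
  toks <- regmatches(pattern, gregexpr("[A-Z][*+]*", pattern))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(pattern)) {
    stop("bad architecture pattern: ", pattern)
  }
  data.frame(letter = substr(toks, 1, 1),
             catalytic = grepl("*", toks, fixed = TRUE),
             binding = grepl("+", toks, fixed = TRUE),
             stringsAsFactors = FALSE)
}

# canonical signature expected downstream for a planted pattern:
# catalytic domains first, binding marker dropped
planted_signature <- function(pattern) {
  p <- parse_pattern(pattern)
  p <- p[order(!p$catalytic, p$letter), , drop = FALSE]
  letters_seen <- unique(p$letter)
  paste0(LETTERS[match(p$letter, letters_seen)],
         ifelse(p$catalytic, "*", ""), collapse = "")
}

draw_roles <- function(kind, cfg) {
  w <- cfg$role_weights[[kind]]
  k <- sample_in(cfg$roles_per_annotation)
  k <- min(k, sum(w > 0))
  paste(sort(sample(names(w)[w > 0], k, prob = w[w > 0])), collapse = ";")
}

acting_part_for <- function(type) {
  if (type %in% nonpolar_types) {
    sample(c("main_chain_NH", "main_chain_CO"), 1L)
  } else {
    "side_chain"
  }
}

#' Plant catalytic and binding sites in a record
#'
#' Places catalytic residue annotations inside the segments of the record's
#' catalytic domains and three (configurable) binding residues inside each
#' designated binding domain, overwriting the sequence letter at each site
#' so the annotation resolves exactly. Catalytic residue types are drawn
#' with probability proportional to background frequency times the EC-class
#' propensity multiplier; roles follow the per-entity-kind weights (zero
#' \code{hydride_shuttle} weight for residues under the default rule);
#' the acting part is the side chain for polar types while nonpolar types
#' act through a main-chain NH or CO group.
#'
#' @param chains named character vector of chain sequences.
#' @param domains data.frame with \code{chain_id}, \code{cath_code},
#'   \code{segments} plus logical columns \code{catalytic} and
#'   \code{binding} designating the planted domain roles.
#' @param ec_class integer 1..6 selecting the multiplier column.
#' @param cfg a \code{\link{generator_config}}.
#' @param record_id id stamped on the annotation rows.
#' @return list with updated \code{chains} and a \code{residues} data.frame.
#' @export
plant_sites <- function(chains, domains, ec_class, cfg, record_id = "R1") {
  n_cat <- sample_in(cfg$n_catalytic_per_record)
  cat_dom <- which(domains$catalytic)
  if (!length(cat_dom) && n_cat > 0) stop("no catalytic domain to host sites")
  # candidate positions per domain
  dom_pos <- lapply(seq_len(nrow(domains)), function(i) {
    m <- parse_segments(domains$segments[i])
    unlist(lapply(seq_len(nrow(m)), function(j) m[j, 1L]:m[j, 2L]))
  })
  used <- lapply(chains, function(s) integer(0))
  rows <- list()
  take_pos <- function(dom_i) {
    ch <- domains$chain_id[dom_i]
    avail <- setdiff(dom_pos[[dom_i]], used[[ch]])
    if (!length(avail)) stop("record too short to host requested sites")
    p <- if (length(avail) == 1L) avail else sample(avail, 1L)
    used[[ch]] <<- c(used[[ch]], p)
    p
  }
  mult <- cfg$propensity_multipliers[, as.character(ec_class)]
  cat_type_prob <- cfg$background_freqs * mult
  if (n_cat > 0) {
    hosts <- cat_dom[1L + (seq_len(n_cat) - 1L) %% length(cat_dom)]
    for (d in hosts) {
      p <- take_pos(d)
      ch <- domains$chain_id[d]
      type <- sample(aa_alphabet, 1L, prob = cat_type_prob)
      substr(chains[[ch]], p, p) <- type
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = record_id, chain_id = ch, position = p,
        residue_type = type, function_context = "catalytic",
        involvement = if (stats::runif(1) < cfg$reactant_prob) "reactant"
                      else "spectator",
        roles = draw_roles("residue", cfg),
        acting_part = acting_part_for(type), stringsAsFactors = FALSE)
    }
  }
  for (d in which(domains$binding)) {
    for (k in seq_len(cfg$n_binding_per_binding_domain)) {
      p <- take_pos(d)
      ch <- domains$chain_id[d]
      type <- sample(aa_alphabet, 1L, prob = cfg$background_freqs)
      substr(chains[[ch]], p, p) <- type
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = record_id, chain_id = ch, position = p,
        residue_type = type, function_context = "binding",
        involvement = "", roles = "",
        acting_part = acting_part_for(type), stringsAsFactors = FALSE)
    }
  }
  residues <- if (length(rows)) do.call(rbind, rows) else
    empty_df("record_id", "chain_id", "position", "residue_type",
             "function_context", "involvement", "roles", "acting_part")
  list(chains = chains, residues = residues)
}

#' Generate a synthetic enzyme corpus with known ground truth
#'
#' Builds \code{n_ec_nodes} EC nodes; each node holds a planted number of
#' evolutionary families, each family a founder sequence diverged from the
#' other founders of the node (between-family identity capped by rejection
#' sampling) and members mutated from the founder at half the configured
#' divergence, so pairwise member identity lands at
#' \code{within_family_identity}. Each family draws one domain architecture
#' pattern and a set of CATH codes; each member gets catalytic and binding
#' sites planted by \code{\link{plant_sites}}, an optional cofactor, and a
#' structure flag. Fully deterministic for a fixed \code{rng_seed}.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return list with \code{dataset} (an \code{\link{enzyme_dataset}}) and
#'   \code{truth} (class \code{ground_truth}: \code{family_of},
#'   \code{node_family_counts}, \code{planted_propensity},
#'   \code{planted_architecture}, \code{config}).
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$rng_seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  n_fam_per_node <- if (length(cfg$families_per_node) == cfg$n_ec_nodes) {
    cfg$families_per_node
  } else if (length(cfg$families_per_node) == 1L) {
    rep(cfg$families_per_node, cfg$n_ec_nodes)
  } else {
    sample(cfg$families_per_node, cfg$n_ec_nodes, replace = TRUE)
  }
  pat <- cfg$architecture_patterns
  metal_ids <- c("ZN", "MG", "FE", "MN", "CU")
  organic_ids <- c("NAD", "FAD", "PLP", "TPP", "SAM")

  seq_rows <- list(); res_rows <- list(); dom_rows <- list()
  cof_rows <- list(); unit_rows <- list()
  family_of <- character(0)
  planted_arch <- character(0)
  node_counts <- integer(0)

  for (node_i in seq_len(cfg$n_ec_nodes)) {
    ec <- sprintf("%d.%d.%d.%d", 1L + (node_i - 1L) %% 6L,
                  1L + ((node_i - 1L) %/% 6L) %% 15L, 1L, node_i)
    klass <- 1L + (node_i - 1L) %% 6L
    n_fam <- n_fam_per_node[node_i]
    node_label <- sprintf("N%03d", node_i)
    node_counts[ec] <- n_fam

    # founders under the between-family identity cap (rejection sampling)
    founders <- character(0)
    fam_len <- integer(0)
    for (f in seq_len(n_fam)) {
      len <- sample_in(cfg$seq_length)
      ok <- FALSE
      for (try in seq_len(100L)) {
        cand <- random_sequence(len, cfg$background_freqs)
        if (!length(founders)) { ok <- TRUE; break }
        ids <- vapply(founders, function(g) {
          l <- min(nchar(g), len)
          positional_identity(substr(cand, 1, l), substr(g, 1, l))
        }, numeric(1))
        if (all(ids <= cfg$between_family_identity_cap)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not satisfy between_family_identity_cap ",
                    "after 100 retries")
      founders[f] <- cand
      fam_len[f] <- len
    }

    for (f in seq_len(n_fam)) {
      fam_label <- sprintf("%s_F%02d", node_label, f)
      pattern <- sample(pat$pattern, 1L, prob = pat$weight)
      pp <- parse_pattern(pattern)
      codes <- sample(cfg$cath_pool, length(unique(pp$letter)))
      pp$cath_code <- codes[match(pp$letter, unique(pp$letter))]
      n_members <- sample_in(cfg$members_per_family)
      member_target <- 100 - (100 - cfg$within_family_identity) / 2

      for (m in seq_len(n_members)) {
        rec_id <- sprintf("%s_M%02d", fam_label, m)
        s <- mutate_to_identity(founders[f], member_target,
                                indel_rate = cfg$indel_rate)
        chains <- c(A = s)
        # equal contiguous segments over the member's chain
        bounds <- round(seq(0L, nchar(s), length.out = nrow(pp) + 1L))
        domains <- data.frame(
          chain_id = "A", cath_code = pp$cath_code,
          segments = paste0(bounds[-length(bounds)] + 1L, "-", bounds[-1L]),
          catalytic = pp$catalytic, binding = pp$binding,
          stringsAsFactors = FALSE)
        planted <- plant_sites(chains, domains, klass, cfg, rec_id)
        seq_rows[[length(seq_rows) + 1L]] <- data.frame(
          record_id = rec_id, chain_id = "A",
          sequence = planted$chains[["A"]], stringsAsFactors = FALSE)
        if (nrow(planted$residues)) {
          res_rows[[length(res_rows) + 1L]] <- planted$residues
        }
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          record_id = rec_id, chain_id = "A", cath_code = pp$cath_code,
          segments = domains$segments, stringsAsFactors = FALSE)
        if (stats::runif(1) < cfg$cofactor_prob) {
          organic <- stats::runif(1) < cfg$organic_cofactor_prob
          kind <- if (organic) "organic_cofactor" else "metal_ion"
          cof_rows[[length(cof_rows) + 1L]] <- data.frame(
            record_id = rec_id,
            cofactor_id = sample(if (organic) organic_ids else metal_ids, 1L),
            entity_kind = kind, roles = draw_roles(kind, cfg),
            stringsAsFactors = FALSE)
        }
        unit_rows[[length(unit_rows) + 1L]] <- data.frame(
          record_id = rec_id, biological_unit_chains = "A",
          catalytic_unit_chains = "A", ec_nodes = ec,
          has_structure = stats::runif(1) < cfg$structure_prob,
          stringsAsFactors = FALSE)
        family_of[rec_id] <- fam_label
        planted_arch[rec_id] <- planted_signature(pattern)
      }
    }
  }

  dataset <- enzyme_dataset(
    sequences = do.call(rbind, seq_rows),
    residues = if (length(res_rows)) do.call(rbind, res_rows) else NULL,
    domains = do.call(rbind, dom_rows),
    cofactors = if (length(cof_rows)) do.call(rbind, cof_rows) else NULL,
    units = do.call(rbind, unit_rows),
    provenance = sprintf("synthetic corpus, seed %d", cfg$rng_seed),
    validate = TRUE, strict = FALSE)
  truth <- structure(list(
    family_of = family_of,
    node_family_counts = node_counts,
    planted_propensity = cfg$propensity_multipliers,
    planted_architecture = planted_arch,
    config = cfg
  ), class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$family_of), " records, ",
      length(x$node_family_counts), " EC nodes, ",
      sum(x$node_family_counts), " planted families\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus (dataset + truth) to a directory
#'
#' Writes the five dataset files plus \code{truth.json} holding the planted
#' parameters.
#'
#' @param corpus list with \code{dataset} and \code{truth}, as returned by
#'   \code{\link{generate_dataset}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  write_dataset(corpus$dataset, dir)
  truth <- corpus$truth
  jsonlite::write_json(list(
    family_of = as.list(truth$family_of),
    node_family_counts = as.list(truth$node_family_counts),
    planted_propensity = truth$planted_propensity,
    planted_architecture = as.list(truth$planted_architecture)
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
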