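# Lower-bound family estimates per EC node from structure: records are
# grouped by the canonical multiset of CATH H-level codes over their
# catalytic-unit chains, then each group is split by single-linkage on
# sequence identity so analogous same-fold pairs do not collapse.

# order CATH codes numerically field by field
cath_order <- function(codes) {
  f <- do.call(rbind, lapply(strsplit(codes, ".", fixed = TRUE), as.integer))
  do.call(order, as.data.frame(f))
}

#' Canonical CATH domain-combination key of a record
#'
#' The sorted multiset of H-level CATH codes over the record's
#' catalytic-unit chains (the whole biological unit with
#' \code{whole_unit = TRUE}), serialized with \code{+} separators.
#' Multiplicity is preserved — two copies of the same domain yield
#' \code{"code+code"} — and the key is invariant under chain and domain
#' listing order.
#'
#' @param record an \code{enzyme_record} (see \code{\link{get_record}}).
#' @param whole_unit use all biological-unit chains instead of the
#'   catalytic unit.
#' @return the key string, or \code{NA_character_} (with a warning) when the
#'   record has no domain on the selected chains.
#' @examples
#' \dontrun{domain_combination(get_record(ds, "R1"))}
#' @export
domain_combination <- function(record, whole_unit = FALSE) {
  stopifnot(inherits(record, "enzyme_record"))
  chains <- if (whole_unit) unique(record$biological_unit_chains)
            else unique(record$catalytic_unit_chains)
  if (!length(chains)) chains <- names(record$chains)
  codes <- record$domains$cath_code[record$domains$chain_id %in% chains]
  if (!length(codes)) {
    warning("record ", record$record_id,
            " has no domain on its catalytic unit; excluded from ",
            "structural analysis")
    return(NA_character_)
  }
  paste(codes[cath_order(codes)], collapse = "+")
}

# concatenated catalytic-unit sequence of each record id
catalytic_unit_sequences <- function(x, ids) {
  vapply(ids, function(id) {
    rec <- get_record(x, id)
    chains <- unique(rec$catalytic_unit_chains)
    if (!length(chains)) chains <- names(rec$chains)
    paste(rec$chains[sort(chains)], collapse = "")
  }, character(1))
}

#' Structural partition of one EC node
#'
#' Records are grouped by identical domain-combination key; each group is
#' then split by single-linkage on the concatenated catalytic-unit
#' sequences at \code{identity >= identity_floor} (no coverage requirement),
#' so that records sharing a fold combination but with no detectable
#' sequence kinship count as distinct families. Deterministic.
#'
#' @param x an \code{enzyme_dataset}.
#' @param ids record ids of the node (structure-bearing).
#' @param node EC node label.
#' @param identity_floor percent identity for the refinement split
#'   (default 20); \code{seq_refine = FALSE} disables the split and counts
#'   pure combinations.
#' @param seq_refine logical.
#' @param whole_unit passed to \code{\link{domain_combination}}.
#' @param params \code{\link{alignment_params}}.
#' @return a \code{\link{cluster_set}} over the ids with a combination key.
#' @export
structural_partition <- function(x, ids, node = "", identity_floor = 20,
                                 seq_refine = TRUE, whole_unit = FALSE,
                                 params = alignment_params()) {
  keys <- vapply(ids, function(id) {
    domain_combination(get_record(x, id), whole_unit = whole_unit)
  }, character(1))
  ids <- ids[!is.na(keys)]
  keys <- keys[!is.na(keys)]
  if (!length(ids)) return(cluster_set(list(), node = node))
  blocks <- list()
  seqs <- catalytic_unit_sequences(x, ids)
  for (key in unique(keys)) {
    grp <- ids[keys == key]
    if (!seq_refine || length(grp) == 1L) {
      blocks[[length(blocks) + 1L]] <- grp
      next
    }
    g <- identity_graph(seqs[grp], identity_threshold = identity_floor,
                        coverage_threshold = 0, params = params)
    sub <- single_linkage_partition(g)
    blocks <- c(blocks, unname(sub$clusters))
  }
  cluster_set(blocks, node = node, stage = "raw")
}

#' Structural families per EC node
#'
#' Counts domain-combination families over the structure-bearing records of
#' every complete EC node; nodes with no structures are skipped with a
#' message. This is the lower-bound counterpart of
#' \code{\link{families_per_node}}: structural similarity persists long
#' after sequence similarity decays, so combination clusters merge families
#' the sequence analysis keeps apart.
#'
#' @param x an \code{enzyme_dataset}.
#' @inheritParams structural_partition
#' @return object of class \code{struct_family_counts}: data.frame
#'   \code{per_node} (\code{node}, \code{n_records}, \code{families}),
#'   \code{cluster_sets}, parameter echo.
#' @export
structural_families_per_node <- function(x, identity_floor = 20,
                                         seq_refine = TRUE,
                                         whole_unit = FALSE,
                                         params = alignment_params()) {
  stopifnot(inherits(x, "enzyme_dataset"))
  x <- select_complete_ec(restrict_to_structures(x))
  node_of <- split_ec_field(x$units$ec_nodes)
  node_map <- list()
  for (i in seq_along(node_of)) {
    nodes <- node_of[[i]][is_complete_ec(node_of[[i]])]
    for (nd in nodes) {
      node_map[[nd]] <- c(node_map[[nd]], x$units$record_id[i])
    }
  }
  nodes <- sort(names(node_map))
  per_node <- data.frame(node = nodes, n_records = 0L,
                         families = NA_integer_, stringsAsFactors = FALSE)
  csets <- list()
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    cs <- structural_partition(x, node_map[[nd]], node = nd,
                               identity_floor = identity_floor,
                               seq_refine = seq_refine,
                               whole_unit = whole_unit, params = params)
    per_node$n_records[k] <- length(unlist(cs$clusters))
    per_node$families[k] <- n_clusters(cs)
    csets[[nd]] <- cs
  }
  per_node <- per_node[per_node$n_records > 0L, , drop = FALSE]
  rownames(per_node) <- NULL
  structure(list(per_node = per_node, cluster_sets = csets,
                 params = list(identity_floor = identity_floor,
                               seq_refine = seq_refine,
                               whole_unit = whole_unit)),
            class = "struct_family_counts")
}

#' @export
print.struct_family_counts <- function(x, ...) {
  cat("Structural families per EC node (", nrow(x$per_node), " nodes)\n",
      "  clusters: ", sum(x$per_node$families), " (mean ",
      format(mean_per_node(x$per_node$families)$display, nsmall = 2),
      ", singleton nodes ",
      round(100 * singleton_node_fraction(x$per_node$families)), "%)\n",
      sep = "")
  invisible(x)
}
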