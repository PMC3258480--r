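# Evolutionary families per EC node from sequences: pairwise global
# identity, a threshold graph, single-linkage (connected-component)
# clustering, and a profile-based merge that places singleton clusters with
# multi-member clusters. In-house analogue of blastclust followed by
# profile/HMM assignment, with exact alignment instead of BLAST heuristics.

#' Construct a cluster set
#'
#' A partition of the records of one EC node into evolutionary families.
#' Blocks are relabelled \code{C001, C002, ...} in order of their smallest
#' member id, so the labelling is invariant under input ordering.
#'
#' @param blocks list of character vectors of record ids (disjoint).
#' @param node the EC node the partition belongs to.
#' @param stage \code{"raw"} (post single-linkage) or \code{"merged"}
#'   (post singleton merge).
#' @return object of class \code{cluster_set}.
#' @export
cluster_set <- function(blocks, node = "", stage = "raw") {
  blocks <- lapply(blocks, function(b) sort(as.character(b)))
  ids <- unlist(blocks)
  if (anyDuplicated(ids)) stop("cluster blocks are not disjoint")
  ord <- order(vapply(blocks, function(b) b[1L], character(1)))
  blocks <- blocks[ord]
  names(blocks) <- sprintf("C%03d", seq_along(blocks))
  structure(list(node = node, clusters = blocks, stage = stage),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> node ", x$node, " (", x$stage, "): ",
      length(x$clusters), " cluster(s), ",
      length(unlist(x$clusters)), " record(s)\n", sep = "")
  invisible(x)
}

#' Number of clusters in a cluster set
#' @param x a \code{cluster_set}.
#' @export
n_clusters <- function(x) length(x$clusters)

#' Identity threshold graph over sequences
#'
#' All-vs-all global alignment; an undirected edge joins two sequences iff
#' percent identity >= \code{identity_threshold} and coverage >=
#' \code{coverage_threshold}. No self loops.
#'
#' @param sequences named character vector (names = record ids).
#' @param identity_threshold percent, in [0, 100].
#' @param coverage_threshold fraction of the shorter sequence, in [0, 1].
#' @param params \code{\link{alignment_params}}.
#' @return an \code{igraph} undirected graph whose vertices are the
#'   record ids.
#' @export
identity_graph <- function(sequences, identity_threshold = 30,
                           coverage_threshold = 0.8,
                           params = alignment_params()) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 100,
            coverage_threshold >= 0, coverage_threshold <= 1)
  ids <- sort(names(sequences))
  sequences <- sequences[ids]
  n <- length(ids)
  edges <- character(0)
  if (n > 1L) {
    for (j in 2:n) {
      res <- identity_to_subject(unname(sequences[1:(j - 1L)]),
                                 unname(sequences[j]), params)
      hit <- res$identity >= identity_threshold &
        res$coverage >= coverage_threshold
      if (any(hit)) {
        edges <- c(edges, rbind(ids[1:(j - 1L)][hit], ids[j]))
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Single-linkage partition of an identity graph
#'
#' Clusters are the connected components: two records share a family iff a
#' chain of above-threshold pairwise similarities joins them (the blastclust
#' criterion). Deterministic and invariant under input ordering.
#'
#' @param graph an undirected \code{igraph} graph with named vertices.
#' @param node EC node label carried into the result.
#' @return a \code{\link{cluster_set}} with \code{stage = "raw"}.
#' @export
single_linkage_partition <- function(graph, node = "") {
  if (igraph::vcount(graph) == 0L) {
    return(cluster_set(list(), node = node, stage = "raw"))
  }
  comp <- igraph::components(graph)
  blocks <- split(igraph::V(graph)$name, comp$membership)
  cluster_set(unname(blocks), node = node, stage = "raw")
}

#' Position-frequency profile of a cluster
#'
#' Center-star construction: the longest member (ties broken toward the
#' lexicographically smallest id) is the center; every other member is
#' globally aligned to it and residues falling on center columns are
#' counted. Column frequencies get a +0.1 pseudocount per residue type:
#' \code{(count + 0.1) / (n_aligned + 2)}, where \code{n_aligned} is the
#' number of members contributing a residue at that column, so each column
#' sums to 1.
#'
#' @param sequences named character vector, at least two members.
#' @param params \code{\link{alignment_params}}.
#' @param source_cluster label carried along.
#' @return object of class \code{sequence_profile}: \code{freqs} (20 x L
#'   matrix), \code{consensus} (modal residue string, length = center
#'   length), \code{center_id}, \code{source_cluster}.
#' @export
build_profile <- function(sequences, params = alignment_params(),
                          source_cluster = "") {
  if (length(sequences) < 2L) stop("profile needs >= 2 members")
  ord <- order(-nchar(sequences), names(sequences))
  center_id <- names(sequences)[ord[1L]]
  center <- sequences[[center_id]]
  L <- nchar(center)
  counts <- matrix(0, nrow = 20, ncol = L,
                   dimnames = list(aa_alphabet, NULL))
  vc <- strsplit(center, "")[[1]]
  for (j in seq_len(L)) counts[vc[j], j] <- counts[vc[j], j] + 1
  n_aligned <- rep(1, L)
  others <- sequences[setdiff(names(sequences), center_id)]
  if (length(others)) {
    submat <- get_submat(params)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(unname(others)), Biostrings::AAString(center),
      substitutionMatrix = submat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = "global")
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")
    for (k in seq_along(pat)) {
      col <- 0L
      p <- pat[[k]]; s <- sub[[k]]
      for (t in seq_along(s)) {
        if (s[t] != "-") {
          col <- col + 1L
          if (p[t] != "-" && p[t] %in% aa_alphabet) {
            counts[p[t], col] <- counts[p[t], col] + 1
            n_aligned[col] <- n_aligned[col] + 1
          }
        }
      }
    }
  }
  freqs <- sweep(counts + 0.1, 2, n_aligned + 2, "/")
  consensus <- paste(aa_alphabet[apply(freqs, 2, which.max)], collapse = "")
  structure(list(freqs = freqs, consensus = consensus,
                 center_id = center_id, source_cluster = source_cluster),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat("<sequence_profile> ", ncol(x$freqs), " columns, center ",
      x$center_id, "\n", sep = "")
  invisible(x)
}

# mean log column frequency of the singleton's residues along a global
# alignment to the profile consensus; -Inf if nothing aligns
profile_score <- function(profile, seq, params = alignment_params()) {
  submat <- get_submat(params)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(profile$consensus),
    substitutionMatrix = submat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  col <- 0L
  total <- 0
  n <- 0L
  for (t in seq_along(s)) {
    if (s[t] != "-") {
      col <- col + 1L
      if (p[t] != "-" && p[t] %in% aa_alphabet) {
        total <- total + log(profile$freqs[p[t], col])
        n <- n + 1L
      }
    }
  }
  if (n == 0L) -Inf else total / n
}

#' Merge singleton clusters into multi-member clusters
#'
#' Each singleton is scored against the position-frequency profile of every
#' multi-member cluster (mean log column frequency along a global alignment
#' of the singleton to the profile consensus) and absorbed into the
#' best-scoring cluster when the score reaches \code{tau}; ties break toward
#' the lexicographically smallest cluster label. Never splits a block, so
#' the merged cluster count is at most the raw count.
#'
#' @param cs a raw \code{\link{cluster_set}}.
#' @param sequences named character vector covering the cluster members.
#' @param tau acceptance threshold on the per-column mean log frequency
#'   (default -1.0).
#' @param params \code{\link{alignment_params}}.
#' @return a \code{\link{cluster_set}} with \code{stage = "merged"}.
#' @export
merge_singletons <- function(cs, sequences, tau = -1.0,
                             params = alignment_params()) {
  stopifnot(inherits(cs, "cluster_set"))
  sizes <- lengths(cs$clusters)
  singles <- names(cs$clusters)[sizes == 1L]
  multis <- names(cs$clusters)[sizes >= 2L]
  if (!length(singles) || !length(multis)) {
    out <- cs
    out$stage <- "merged"
    return(out)
  }
  profiles <- lapply(multis, function(lb) {
    build_profile(sequences[cs$clusters[[lb]]], params, source_cluster = lb)
  })
  names(profiles) <- multis
  blocks <- cs$clusters
  for (lb in singles) {
    id <- blocks[[lb]]
    scores <- vapply(multis, function(m) {
      profile_score(profiles[[m]], sequences[[id]], params)
    }, numeric(1))
    best <- max(scores)
    if (best >= tau) {
      target <- sort(multis[scores == best])[1L]  # tie -> smallest label
      blocks[[target]] <- c(blocks[[target]], id)
      blocks[[lb]] <- NULL
    }
  }
  cluster_set(unname(blocks), node = cs$node, stage = "merged")
}

#' Families per EC node from sequences
#'
#' Runs the full chain for every complete EC node of the corpus: collect the
#' node's records (a record's sequence is the concatenation of its chains;
#' records carrying several nodes are clustered independently within each),
#' build the identity graph, take connected components, then merge singleton
#' clusters by profile scoring. Clustering is all-vs-all within one node
#' only, never across nodes.
#'
#' @param x an \code{enzyme_dataset} (typically after
#'   \code{\link{select_complete_ec}}).
#' @param identity_threshold,coverage_threshold edge criteria of
#'   \code{\link{identity_graph}} (defaults 30 percent, 0.8).
#' @param tau singleton-merge acceptance threshold
#'   (\code{\link{merge_singletons}}).
#' @param merge run the singleton merge stage? Default \code{TRUE}.
#' @param params \code{\link{alignment_params}}.
#' @return object of class \code{family_counts}: data.frame \code{per_node}
#'   with columns \code{node}, \code{n_records}, \code{raw},
#'   \code{merged}; list \code{cluster_sets} (per node, raw and merged);
#'   echoed parameters.
#' @examples
#' corpus <- generate_dataset(generator_config(n_ec_nodes = 4, rng_seed = 7))
#' fc <- families_per_node(corpus$dataset)
#' summary(fc)
#' @export
families_per_node <- function(x, identity_threshold = 30,
                              coverage_threshold = 0.8, tau = -1.0,
                              merge = TRUE, params = alignment_params()) {
  stopifnot(inherits(x, "enzyme_dataset"))
  x <- select_complete_ec(x)
  node_of <- split_ec_field(x$units$ec_nodes)
  node_map <- list()
  for (i in seq_along(node_of)) {
    nodes <- node_of[[i]][is_complete_ec(node_of[[i]])]
    for (nd in nodes) {
      node_map[[nd]] <- c(node_map[[nd]], x$units$record_id[i])
    }
  }
  seq_of <- record_sequences(x)
  nodes <- sort(names(node_map))
  per_node <- data.frame(node = nodes, n_records = 0L, raw = NA_integer_,
                         merged = NA_integer_, stringsAsFactors = FALSE)
  csets <- list()
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    ids <- node_map[[nd]]
    seqs <- seq_of[ids]
    if (!length(seqs)) {
      message("node ", nd, ": no sequences, skipped")
      next
    }
    g <- identity_graph(seqs, identity_threshold, coverage_threshold, params)
    raw <- single_linkage_partition(g, node = nd)
    per_node$n_records[k] <- length(ids)
    per_node$raw[k] <- n_clusters(raw)
    entry <- list(raw = raw)
    if (merge) {
      merged <- merge_singletons(raw, seqs, tau, params)
      per_node$merged[k] <- n_clusters(merged)
      entry$merged <- merged
    }
    csets[[nd]] <- entry
  }
  structure(list(per_node = per_node, cluster_sets = csets,
                 params = list(identity_threshold = identity_threshold,
                               coverage_threshold = coverage_threshold,
                               tau = tau, merge = merge)),
            class = "family_counts")
}

# record id -> concatenation of its chain sequences (chain order)
record_sequences <- function(x) {
  s <- x$sequences[order(x$sequences$record_id, x$sequences$chain_id), ]
  vapply(split(s$sequence, factor(s$record_id, levels = unique(s$record_id))),
         paste, character(1), collapse = "")
}

#' @export
print.family_counts <- function(x, ...) {
  cat("Sequence families per EC node (", nrow(x$per_node), " nodes)\n",
      "  raw clusters:    ", sum(x$per_node$raw), " (mean ",
      format(mean_per_node(x$per_node$raw)$display, nsmall = 2), ")\n",
      sep = "")
  if (x$params$merge) {
    cat("  merged clusters: ", sum(x$per_node$merged), " (mean ",
        format(mean_per_node(x$per_node$merged)$display, nsmall = 2),
        ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.family_counts <- function(object, ...) {
  p <- object$per_node
  out <- list(
    n_nodes = nrow(p),
    total_raw = sum(p$raw),
    mean_raw = mean_per_node(p$raw),
    singleton_fraction_raw = singleton_node_fraction(p$raw),
    total_merged = if (object$params$merge) sum(p$merged) else NA,
    mean_merged = if (object$params$merge) mean_per_node(p$merged) else NULL,
    singleton_fraction_merged =
      if (object$params$merge) singleton_node_fraction(p$merged) else NA
  )
  class(out) <- "summary.family_counts"
  out
}

#' @export
print.summary.family_counts <- function(x, ...) {
  cat("EC nodes:            ", x$n_nodes, "\n",
      "raw clusters:        ", x$total_raw, " (mean/node ",
      format(x$mean_raw$display, nsmall = 2), ", singleton nodes ",
      round(100 * x$singleton_fraction_raw), "%)\n", sep = "")
  if (!is.null(x$mean_merged)) {
    cat("merged clusters:     ", x$total_merged, " (mean/node ",
        format(x$mean_merged$display, nsmall = 2), ", singleton nodes ",
        round(100 * x$singleton_fraction_merged), "%)\n", sep = "")
  }
  invisible(x)
}
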