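# Domain roles, catalytic units, architecture signatures, the configuration
# census, and domain-to-EC promiscuity.
#
# A catalytic domain furnishes at least one catalytic residue; a binding
# domain furnishes none but at least three binding residues; everything
# else is "other". The catalytic unit is the smallest assembly required for
# activity: the annotated catalytic-unit chains when present, otherwise the
# chains carrying at least one catalytic or binding domain.

#' Classify the domains of a record as catalytic, binding or other
#'
#' Tallies the catalytic and binding residue annotations falling inside
#' each domain's segments. \code{label = "catalytic"} iff the domain hosts
#' at least one catalytic residue; \code{"binding"} iff it hosts none but at
#' least three binding residues; otherwise \code{"other"}. Catalytic
#' residues outside every segment (linker residues) never create a domain;
#' they are reported in the \code{"unassigned_catalytic"} attribute.
#'
#' @param record an \code{enzyme_record}.
#' @return data.frame with one row per domain: \code{record_id},
#'   \code{chain_id}, \code{cath_code}, \code{segments},
#'   \code{n_catalytic_residues}, \code{n_binding_residues}, \code{label};
#'   attribute \code{unassigned_catalytic} counts linker catalytic
#'   residues.
#' @export
classify_domain_roles <- function(record) {
  stopifnot(inherits(record, "enzyme_record"))
  d <- record$domains
  r <- record$residues
  n_cat <- integer(nrow(d))
  n_bind <- integer(nrow(d))
  assigned <- rep(FALSE, nrow(r))
  for (i in seq_len(nrow(d))) {
    if (nrow(r)) {
      inside <- r$chain_id == d$chain_id[i] &
        vapply(r$position, in_segments, logical(1), s = d$segments[i])
      n_cat[i] <- sum(inside & r$function_context == "catalytic")
      n_bind[i] <- sum(inside & r$function_context == "binding")
      assigned <- assigned | inside
    }
  }
  label <- ifelse(n_cat >= 1L, "catalytic",
                  ifelse(n_bind >= 3L, "binding", "other"))
  out <- data.frame(record_id = rep(record$record_id, nrow(d)),
                    chain_id = d$chain_id, cath_code = d$cath_code,
                    segments = d$segments,
                    n_catalytic_residues = n_cat,
                    n_binding_residues = n_bind,
                    label = label, stringsAsFactors = FALSE)
  unassigned <- sum(!assigned & r$function_context == "catalytic")
  if (unassigned > 0L) {
    message(record$record_id, ": ", unassigned,
            " catalytic residue(s) outside every domain segment")
  }
  attr(out, "unassigned_catalytic") <- unassigned
  out
}

#' Catalytic unit of a record
#'
#' The annotated \code{catalytic_unit_chains} take precedence; when absent,
#' the unit is derived as the set of chains carrying at least one catalytic
#' or binding domain (always a subset of the biological unit). A record
#' with neither an annotation nor catalytic machinery is flagged.
#'
#' @param record an \code{enzyme_record}.
#' @param roles optional precomputed \code{\link{classify_domain_roles}}
#'   table.
#' @return list with \code{chains} (chain ids), \code{domains} (role table
#'   restricted to those chains), \code{source} (\code{"annotated"} or
#'   \code{"derived"}), \code{flagged} (logical).
#' @export
catalytic_unit <- function(record, roles = NULL) {
  stopifnot(inherits(record, "enzyme_record"))
  if (is.null(roles)) roles <- classify_domain_roles(record)
  flagged <- FALSE
  if (length(record$catalytic_unit_chains)) {
    chains <- unique(record$catalytic_unit_chains)
    source <- "annotated"
  } else {
    chains <- unique(roles$chain_id[roles$label %in% c("catalytic",
                                                       "binding")])
    source <- "derived"
    if (!length(chains)) {
      warning("record ", record$record_id,
              ": no catalytic unit annotation and no catalytic domain")
      flagged <- TRUE
    }
  }
  list(chains = chains,
       domains = roles[roles$chain_id %in% chains, , drop = FALSE],
       source = source, flagged = flagged)
}

#' Architecture signature of a record
#'
#' Canonical letter string over the catalytic-unit domains with catalytic
#' domains marked by \code{*}: domains are sorted catalytic-first, then by
#' CATH code; letters are assigned in first-occurrence order after that
#' sort, with identical CATH codes sharing a letter (so one catalytic
#' domain in a one-domain unit is \code{"A*"}, a catalytic domain plus a
#' distinct partner is \code{"A*B"}, two copies of the same catalytic
#' domain are \code{"A*A*"}). \code{n_bio_domains} counts every domain of
#' the biological unit.
#'
#' @param record an \code{enzyme_record}.
#' @param roles optional precomputed role table.
#' @return list of class \code{architecture_signature}:
#'   \code{catalytic_unit_pattern}, \code{n_bio_domains},
#'   \code{n_catalytic_unit_domains}.
#' @export
architecture_signature <- function(record, roles = NULL) {
  stopifnot(inherits(record, "enzyme_record"))
  if (is.null(roles)) roles <- classify_domain_roles(record)
  cu <- catalytic_unit(record, roles)
  d <- cu$domains
  n_bio <- sum(roles$chain_id %in% unique(record$biological_unit_chains))
  if (n_bio == 0L) n_bio <- nrow(roles)
  pattern <- ""
  if (nrow(d)) {
    is_cat <- d$label == "catalytic"
    # sort catalytic-first, then by numeric CATH rank
    rk <- integer(nrow(d))
    rk[cath_order(d$cath_code)] <- seq_len(nrow(d))
    ord <- order(!is_cat, rk)
    d <- d[ord, , drop = FALSE]
    letters_seen <- unique(d$cath_code)
    pattern <- paste0(LETTERS[match(d$cath_code, letters_seen)],
                      ifelse(d$label[seq_len(nrow(d))] == "catalytic",
                             "*", ""), collapse = "")
  }
  structure(list(catalytic_unit_pattern = pattern,
                 n_bio_domains = n_bio,
                 n_catalytic_unit_domains = nrow(d)),
            class = "architecture_signature")
}

#' @export
print.architecture_signature <- function(x, ...) {
  cat("<architecture_signature> ", x$catalytic_unit_pattern,
      " (biological unit: ", x$n_bio_domains, " domain(s))\n", sep = "")
  invisible(x)
}

#' Domain-configuration census
#'
#' Tallies the corpus by (catalytic-unit pattern, number of domains in the
#' biological unit), the two axes of the configuration diagram: e.g. the
#' single catalytic domain pattern \code{"A*"} split by whether the
#' biological unit holds one, two or more domains. Rows sort canonically;
#' counts sum to the number of records.
#'
#' @param x an \code{enzyme_dataset}.
#' @return object of class \code{architecture_census}: data.frame
#'   \code{census} (\code{pattern}, \code{n_bio_domains}, \code{count}) and
#'   \code{signatures} (per-record table).
#' @export
configuration_census <- function(x) {
  stopifnot(inherits(x, "enzyme_dataset"))
  ids <- record_ids(x)
  sig <- lapply(ids, function(id) {
    architecture_signature(get_record(x, id))
  })
  signatures <- data.frame(
    record_id = ids,
    pattern = vapply(sig, `[[`, "", "catalytic_unit_pattern"),
    n_bio_domains = vapply(sig, `[[`, 0L, "n_bio_domains"),
    n_catalytic_unit_domains =
      vapply(sig, `[[`, 0L, "n_catalytic_unit_domains"),
    stringsAsFactors = FALSE)
  if (length(ids)) {
    tab <- stats::aggregate(list(count = seq_along(ids)),
                            by = list(pattern = signatures$pattern,
                                      n_bio_domains =
                                        signatures$n_bio_domains),
                            FUN = length)
    tab <- tab[order(tab$pattern, tab$n_bio_domains), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(pattern = character(0), n_bio_domains = integer(0),
                      count = integer(0))
  }
  structure(list(census = tab, signatures = signatures),
            class = "architecture_census")
}

#' @export
print.architecture_census <- function(x, ...) {
  cat("Domain-configuration census (", sum(x$census$count),
      " records)\n", sep = "")
  print(x$census)
  invisible(x)
}

#' Fraction of truly single-domain enzymes
#'
#' The proportion of records with a single domain in both the catalytic and
#' the biological assembly.
#'
#' @param x an \code{enzyme_dataset}.
#' @return a number in [0, 1].
#' @export
single_domain_fraction <- function(x) {
  cc <- configuration_census(x)
  s <- cc$signatures
  if (!nrow(s)) return(NaN)
  mean(s$n_bio_domains == 1L & s$n_catalytic_unit_domains == 1L)
}

#' Domain-to-EC promiscuity
#'
#' For every CATH code that is catalytic in at least one record (or every
#' code with \code{all_domains = TRUE}), the number of distinct complete EC
#' nodes and distinct EC classes over the records carrying that code;
#' multi-EC records contribute each of their complete nodes. Histogram
#' tables count CATH codes by node count and by class count.
#'
#' @param x an \code{enzyme_dataset}.
#' @param all_domains widen from catalytic codes to all codes.
#' @return object of class \code{promiscuity}: data.frame \code{table}
#'   (\code{cath_code}, \code{ec_node_count}, \code{ec_class_count},
#'   \code{nodes}), plus \code{hist_nodes} and \code{hist_classes}.
#' @export
domain_ec_promiscuity <- function(x, all_domains = FALSE) {
  stopifnot(inherits(x, "enzyme_dataset"))
  x <- select_complete_ec(x)
  ids <- record_ids(x)
  cat_codes <- character(0)
  node_lists <- list()
  for (id in ids) {
    rec <- get_record(x, id)
    if (!nrow(rec$domains)) next
    roles <- classify_domain_roles(rec)
    cat_codes <- union(cat_codes,
                       roles$cath_code[roles$label == "catalytic"])
    nodes <- rec$ec_nodes[is_complete_ec(rec$ec_nodes)]
    for (code in unique(rec$domains$cath_code)) {
      node_lists[[code]] <- union(node_lists[[code]], nodes)
    }
  }
  codes <- if (all_domains) names(node_lists) else cat_codes
  codes <- sort(codes)
  tab <- data.frame(
    cath_code = codes,
    ec_node_count = vapply(codes, function(cd) length(node_lists[[cd]]), 0L),
    ec_class_count = vapply(codes, function(cd) {
      length(unique(ec_class(node_lists[[cd]])))
    }, 0L),
    nodes = vapply(codes, function(cd) {
      paste(sort(node_lists[[cd]]), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 hist_nodes = table(tab$ec_node_count),
                 hist_classes = table(tab$ec_class_count)),
            class = "promiscuity")
}

#' @export
print.promiscuity <- function(x, ...) {
  cat("Domain-to-EC promiscuity: ", nrow(x$table), " CATH code(s)\n",
      sep = "")
  if (nrow(x$table)) {
    top <- x$table[order(-x$table$ec_node_count), , drop = FALSE]
    print(utils::head(top[, c("cath_code", "ec_node_count",
                              "ec_class_count")], 5))
  }
  invisible(x)
}
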