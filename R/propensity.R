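# Catalytic-residue propensities per EC class and role profiles per
# catalytic entity kind.
#
# Propensity of residue type r in class C:
#   (catalytic residues of type r in C / all catalytic residues in C)
#   -------------------------------------------------------------------
#   (residues of type r in C        / all residues in C)
# i.e. the fraction of the catalytic toolkit that is type r, over the
# background fraction of type r. 1 = no enrichment; > 1 = more catalytic
# than chance. The composition-weighted mean of each class column is
# exactly 1.

class_cols <- c(as.character(1:6), "all")

records_in_class <- function(x, ec_class) {
  nodes <- split_ec_field(x$units$ec_nodes)
  keep <- vapply(nodes, function(v) {
    if (!length(v)) return(FALSE)
    v <- v[is_complete_ec(v)]
    length(v) > 0L && ec_class %in% ec_class(v)
  }, logical(1))
  x$units$record_id[keep]
}

selection_ids <- function(x, ec_class = "all") {
  if (identical(ec_class, "all")) record_ids(x)
  else records_in_class(x, as.integer(ec_class))
}

#' Background amino-acid composition
#'
#' Frequency of each of the 20 residue types over every chain of the
#' selected records (\code{X} excluded from numerator and denominator).
#'
#' @param x an \code{enzyme_dataset}.
#' @param ec_class \code{"all"} or an integer 1..6; class membership uses
#'   the first digit of each complete EC node, and multi-EC records count
#'   in each of their classes.
#' @return named numeric vector over \code{\link{aa_alphabet}} summing to 1.
#' @export
background_composition <- function(x, ec_class = "all") {
  ids <- selection_ids(x, ec_class)
  seqs <- x$sequences$sequence[x$sequences$record_id %in% ids]
  if (!length(seqs)) stop("empty selection: no sequences in class ", ec_class)
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                      levels = aa_alphabet))
  cnt <- as.numeric(tab)
  names(cnt) <- aa_alphabet
  cnt / sum(cnt)
}

#' Catalytic amino-acid composition
#'
#' Frequency of each residue type among the catalytic residue annotations of
#' the selected records; each annotation counts once per record.
#'
#' @inheritParams background_composition
#' @return named numeric vector over \code{\link{aa_alphabet}} summing to 1.
#' @export
catalytic_composition <- function(x, ec_class = "all") {
  ids <- selection_ids(x, ec_class)
  r <- x$residues[x$residues$record_id %in% ids &
                    x$residues$function_context == "catalytic", ]
  if (!nrow(r)) stop("empty selection: no catalytic annotations in class ",
                     ec_class)
  tab <- table(factor(r$residue_type, levels = aa_alphabet))
  cnt <- as.numeric(tab)
  names(cnt) <- aa_alphabet
  cnt / sum(cnt)
}

#' Catalytic propensity table
#'
#' For every residue type and EC class (plus an all-classes column), the
#' ratio of the type's share of the catalytic toolkit to its background
#' share. Cells whose background count is zero are undefined and flagged in
#' \code{undefined}, never silently set to 0. Classes present in the corpus
#' but lacking catalytic annotations get a flagged (all-NA) column rather
#' than fabricated values. The underlying tallies are kept in \code{counts}:
#' catalytic residues of type r in the class, all catalytic residues in the
#' class, residues of type r in the class, all residues in the class.
#'
#' @param x an \code{enzyme_dataset}.
#' @param convention \code{"toolkit_share"} (default; numerator is the
#'   fraction of catalytic residues that are of type r, the convention under
#'   which the composition-weighted column mean is exactly 1) or
#'   \code{"per_residue_rate"} (numerator is the fraction of type-r residues
#'   that are catalytic, divided by the overall catalytic rate; the
#'   alternative reading of the ambiguous definition). The two coincide
#'   algebraically; the switch controls which tallies populate
#'   \code{counts} and how undefined cells are flagged.
#' @return An object of class \code{propensity_table}: list with
#'   \code{values} (20 x 7 matrix), \code{counts} (list of four matrices),
#'   \code{undefined} (logical matrix), \code{convention}.
#' @examples
#' corpus <- generate_dataset(generator_config(n_ec_nodes = 6, rng_seed = 1))
#' pt <- catalytic_propensity(corpus$dataset)
#' pt$values["H", "all"]
#' @export
catalytic_propensity <- function(x, convention = c("toolkit_share",
                                                   "per_residue_rate")) {
  convention <- match.arg(convention)
  present <- Filter(function(cl) {
    cl == "all" || length(selection_ids(x, cl)) > 0L
  }, class_cols)
  dims <- list(aa_alphabet, class_cols)
  values <- matrix(NA_real_, 20, 7, dimnames = dims)
  undefined <- matrix(TRUE, 20, 7, dimnames = dims)
  cat_r <- matrix(0, 20, 7, dimnames = dims)
  cat_tot <- matrix(0, 20, 7, dimnames = dims)
  bg_r <- matrix(0, 20, 7, dimnames = dims)
  bg_tot <- matrix(0, 20, 7, dimnames = dims)

  for (cl in present) {
    ids <- selection_ids(x, cl)
    seqs <- x$sequences$sequence[x$sequences$record_id %in% ids]
    bg_cnt <- as.numeric(table(factor(
      strsplit(paste(seqs, collapse = ""), "")[[1]], levels = aa_alphabet)))
    r <- x$residues[x$residues$record_id %in% ids &
                      x$residues$function_context == "catalytic", ]
    cat_cnt <- as.numeric(table(factor(r$residue_type,
                                       levels = aa_alphabet)))
    bg_r[, cl] <- bg_cnt
    bg_tot[, cl] <- sum(bg_cnt)
    cat_r[, cl] <- cat_cnt
    cat_tot[, cl] <- sum(cat_cnt)
    if (sum(cat_cnt) == 0) next  # class with sequences but no annotations:
                                 # column stays flagged
    ok <- bg_cnt > 0
    if (convention == "toolkit_share") {
      values[ok, cl] <- (cat_cnt[ok] / sum(cat_cnt)) /
        (bg_cnt[ok] / sum(bg_cnt))
    } else {
      overall_rate <- sum(cat_cnt) / sum(bg_cnt)
      values[ok, cl] <- (cat_cnt[ok] / bg_cnt[ok]) / overall_rate
    }
    undefined[ok, cl] <- FALSE
  }
  structure(list(values = values,
                 counts = list(cat_r = cat_r, cat_tot = cat_tot,
                               bg_r = bg_r, bg_tot = bg_tot),
                 undefined = undefined, convention = convention),
            class = "propensity_table")
}

#' @export
print.propensity_table <- function(x, digits = 2, ...) {
  cat("Catalytic propensity table (", x$convention, " convention)\n",
      sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' Balloon plot of catalytic propensities
#'
#' One circle per residue type and EC class; the diameter scales with the
#' propensity, blue marks propensity >= 1 and red < 1. Undefined cells are
#' left blank.
#'
#' @param x a \code{propensity_table}.
#' @param types residue types (rows) to show; defaults to the rows with any
#'   defined value.
#' @param ... unused.
#' @return \code{x}, invisibly.
#' @export
plot.propensity_table <- function(x, types = NULL, ...) {
  v <- x$values[, class_cols[1:6], drop = FALSE]
  if (is.null(types)) types <- rownames(v)[rowSums(!is.na(v)) > 0]
  v <- v[types, , drop = FALSE]
  nr <- nrow(v); nc <- ncol(v)
  graphics::plot(NULL, xlim = c(0.5, nc + 0.5), ylim = c(0.5, nr + 0.5),
                 xlab = "EC class", ylab = "", axes = FALSE,
                 main = "Catalytic propensity")
  graphics::axis(1, at = seq_len(nc), labels = colnames(v))
  graphics::axis(2, at = seq_len(nr), labels = rownames(v), las = 1)
  mx <- max(v, na.rm = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    val <- v[i, j]
    if (is.na(val)) next
    graphics::symbols(j, i, circles = 0.45 * sqrt(val / mx),
                      inches = FALSE, add = TRUE,
                      bg = if (val >= 1) "steelblue" else "indianred")
  }
  invisible(x)
}

#' Role-incidence profile per catalytic entity kind
#'
#' Tallies, for each entity kind (residue, metal ion, organic cofactor),
#' each role category (the seven residue roles plus \code{hydride_shuttle})
#' and each EC class column, the number of role incidences: an annotation
#' carrying k roles contributes k incidences.
#'
#' @param x an \code{enzyme_dataset}.
#' @return An object of class \code{role_profile}: a 3 x 8 x 7 array
#'   \code{counts} with dimensions entity kind, role, EC class.
#' @export
role_profile <- function(x) {
  kinds <- c("residue", "metal_ion", "organic_cofactor")
  counts <- array(0L, dim = c(3, 8, 7),
                  dimnames = list(kinds, all_roles, class_cols))
  tally <- function(kind, roles_str, cl_cols) {
    roles <- split_roles(roles_str)
    bad <- setdiff(roles, all_roles)
    if (length(bad)) stop("format error: unknown role label(s) ",
                          paste(bad, collapse = ";"))
    for (ro in roles) for (cl in cl_cols) {
      counts[kind, ro, cl] <<- counts[kind, ro, cl] + 1L
    }
  }
  classes_of_record <- function(id) {
    i <- match(id, x$units$record_id)
    nodes <- split_ec_field(x$units$ec_nodes[i])[[1]]
    nodes <- nodes[is_complete_ec(nodes)]
    unique(c(as.character(ec_class(nodes)), "all"))
  }
  r <- x$residues[x$residues$function_context == "catalytic", ]
  for (i in seq_len(nrow(r))) {
    tally("residue", r$roles[i], classes_of_record(r$record_id[i]))
  }
  cf <- x$cofactors
  for (i in seq_len(nrow(cf))) {
    tally(cf$entity_kind[i], cf$roles[i], classes_of_record(cf$record_id[i]))
  }
  structure(list(counts = counts), class = "role_profile")
}

#' @export
print.role_profile <- function(x, ...) {
  cat("Role-incidence profile (all classes column):\n")
  print(x$counts[, , "all"])
  invisible(x)
}

#' Side-chain versus main-chain usage per residue type
#'
#' For each residue type with catalytic annotations, the fraction acting
#' through the side chain versus the main-chain NH or CO groups; the
#' nonpolar types act mainly through their main-chain portions.
#'
#' @param x an \code{enzyme_dataset}.
#' @return data.frame with columns \code{residue_type}, \code{n},
#'   \code{side_chain}, \code{main_chain_NH}, \code{main_chain_CO};
#'   fractions in each row sum to 1.
#' @export
acting_part_summary <- function(x) {
  r <- x$residues[x$residues$function_context == "catalytic", ]
  if (!nrow(r)) stop("no catalytic annotations")
  types <- sort(unique(r$residue_type))
  out <- data.frame(residue_type = types,
                    n = 0L, side_chain = 0, main_chain_NH = 0,
                    main_chain_CO = 0, stringsAsFactors = FALSE)
  for (i in seq_along(types)) {
    sub <- r[r$residue_type == types[i], ]
    out$n[i] <- nrow(sub)
    for (part in acting_parts) {
      out[[part]][i] <- mean(sub$acting_part == part)
    }
  }
  out
}
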