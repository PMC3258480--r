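# Data model for mechanism-level enzyme records and the on-disk formats
# every analysis consumes. Residue indexing is 1-based and segment ranges are
# inclusive (PDB-like convention) in every file and in memory.

#' @importFrom utils read.delim write.table head
NULL

# -- controlled vocabularies --------------------------------------------------

#' Amino-acid and annotation vocabularies
#'
#' Constants used throughout the package: the 20 standard amino acids
#' (one-letter codes), the seven catalytic role categories plus the
#' cofactor-only \code{hydride_shuttle} role, the ten "essential" catalytic
#' residue types (Arg, Asp, Cys, Glu, His, Lys, Ser, Thr, Trp, Tyr) that act
#' through their side chains, and the nonpolar types that act mainly through
#' their main-chain NH or CO groups. Selenocysteine (U) and pyrrolysine (O)
#' are rejected at parse time: mechanism-level catalytic annotation does not
#' cover them.
#'
#' @name vocabularies
#' @aliases aa_alphabet catalytic_roles all_roles essential_types
#'   nonpolar_types
NULL

#' @rdname vocabularies
#' @export
aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname vocabularies
#' @export
catalytic_roles <- c("activation", "steric", "stabilization",
                     "proton_shuttle", "h_radical_shuttle",
                     "electron_shuttle", "covalent_catalysis")

#' @rdname vocabularies
#' @export
all_roles <- c(catalytic_roles, "hydride_shuttle")

#' @rdname vocabularies
#' @export
essential_types <- c("R", "D", "C", "E", "H", "K", "S", "T", "W", "Y")

#' @rdname vocabularies
#' @export
nonpolar_types <- c("I", "L", "P", "G", "A", "F", "M", "V")

acting_parts <- c("side_chain", "main_chain_NH", "main_chain_CO")
entity_kinds <- c("metal_ion", "organic_cofactor")

# -- segments -----------------------------------------------------------------

# "10-40,55-90" -> 2x2 matrix of inclusive 1-based ranges
parse_segments <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- t(vapply(strsplit(parts, "-", fixed = TRUE),
                function(p) as.integer(p[1:2]), integer(2)))
  colnames(m) <- c("start", "end")
  m
}

format_segments <- function(m) {
  paste(paste0(m[, 1L], "-", m[, 2L]), collapse = ",")
}

segments_valid <- function(s) {
  m <- tryCatch(parse_segments(s), error = function(e) NULL)
  if (is.null(m) || anyNA(m) || any(m < 1L) || any(m[, 2L] < m[, 1L])) {
    return(FALSE)
  }
  if (nrow(m) > 1L) {
    o <- order(m[, 1L])
    m <- m[o, , drop = FALSE]
    if (any(m[-1L, 1L] <= m[-nrow(m), 2L])) return(FALSE)  # overlap
  }
  TRUE
}

segment_length <- function(s) {
  m <- parse_segments(s)
  sum(m[, 2L] - m[, 1L] + 1L)
}

in_segments <- function(pos, s) {
  m <- parse_segments(s)
  any(pos >= m[, 1L] & pos <= m[, 2L])
}

# -- constructor --------------------------------------------------------------

empty_df <- function(...) {
  cols <- c(...)
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out
}

#' Construct an enzyme dataset
#'
#' Bundles the five annotation tables of a mechanism-level enzyme corpus into
#' one validated object. Most users get one from \code{\link{read_dataset}}
#' or \code{\link{generate_dataset}} rather than building the tables by hand.
#'
#' @param sequences data.frame with columns \code{record_id},
#'   \code{chain_id}, \code{sequence} (20-letter alphabet plus X).
#' @param residues data.frame of catalytic/binding residue annotations:
#'   \code{record_id}, \code{chain_id}, \code{position} (1-based),
#'   \code{residue_type}, \code{function_context} (\code{catalytic} or
#'   \code{binding}), \code{involvement} (\code{reactant}/\code{spectator},
#'   catalytic only), \code{roles} (semicolon-joined), \code{acting_part}.
#' @param domains data.frame of CATH H-level domain assignments:
#'   \code{record_id}, \code{chain_id}, \code{cath_code} (four dotted
#'   integers), \code{segments} (comma-joined inclusive \code{start-end}).
#' @param cofactors data.frame: \code{record_id}, \code{cofactor_id},
#'   \code{entity_kind} (\code{metal_ion}/\code{organic_cofactor}),
#'   \code{roles}.
#' @param units data.frame, one row per record: \code{record_id},
#'   \code{biological_unit_chains} (comma-joined, repeats allowed),
#'   \code{catalytic_unit_chains} (comma-joined subset),
#'   \code{ec_nodes} (semicolon-joined EC codes), \code{has_structure}
#'   (\code{TRUE}/\code{FALSE}).
#' @param provenance free-text metadata string.
#' @param validate run \code{\link{validate_dataset}}? Default \code{TRUE}.
#' @param strict enforce the catalytic-machinery invariant (every record has
#'   at least one catalytic residue or cofactor)? See
#'   \code{\link{validate_dataset}}.
#' @return An object of class \code{enzyme_dataset}.
#' @export
enzyme_dataset <- function(sequences, residues = NULL, domains = NULL,
                           cofactors = NULL, units = NULL,
                           provenance = "", validate = TRUE, strict = TRUE) {
  if (is.null(residues)) {
    residues <- empty_df("record_id", "chain_id", "position", "residue_type",
                         "function_context", "involvement", "roles",
                         "acting_part")
  }
  if (is.null(domains)) {
    domains <- empty_df("record_id", "chain_id", "cath_code", "segments")
  }
  if (is.null(cofactors)) {
    cofactors <- empty_df("record_id", "cofactor_id", "entity_kind", "roles")
  }
  if (is.null(units)) {
    ids <- unique(sequences$record_id)
    chains <- vapply(ids, function(i) {
      paste(sequences$chain_id[sequences$record_id == i], collapse = ",")
    }, character(1))
    units <- data.frame(record_id = ids, biological_unit_chains = chains,
                        catalytic_unit_chains = chains,
                        ec_nodes = rep("", length(ids)),
                        has_structure = rep(FALSE, length(ids)),
                        stringsAsFactors = FALSE)
  }
  if (is.null(units$has_structure)) units$has_structure <- FALSE
  units$has_structure <- as.logical(units$has_structure)
  residues$position <- as.integer(residues$position)
  x <- structure(list(sequences = as.data.frame(sequences),
                      residues = as.data.frame(residues),
                      domains = as.data.frame(domains),
                      cofactors = as.data.frame(cofactors),
                      units = as.data.frame(units),
                      provenance = provenance),
                 class = "enzyme_dataset")
  x <- canonicalize_dataset(x)
  if (validate) validate_dataset(x, strict = strict)
  x
}

# deterministic row order so writes are byte-stable
canonicalize_dataset <- function(x) {
  x$sequences <- x$sequences[order(x$sequences$record_id,
                                   x$sequences$chain_id), , drop = FALSE]
  x$residues <- x$residues[order(x$residues$record_id, x$residues$chain_id,
                                 x$residues$position,
                                 x$residues$function_context), , drop = FALSE]
  x$domains <- x$domains[order(x$domains$record_id, x$domains$chain_id,
                               x$domains$cath_code,
                               x$domains$segments), , drop = FALSE]
  x$cofactors <- x$cofactors[order(x$cofactors$record_id,
                                   x$cofactors$cofactor_id), , drop = FALSE]
  x$units <- x$units[order(x$units$record_id), , drop = FALSE]
  for (nm in c("sequences", "residues", "domains", "cofactors", "units")) {
    rownames(x[[nm]]) <- NULL
  }
  x
}

#' Record identifiers of a dataset
#' @param x an \code{enzyme_dataset}.
#' @return character vector of record ids.
#' @export
record_ids <- function(x) {
  stopifnot(inherits(x, "enzyme_dataset"))
  x$units$record_id
}

#' Number of records
#' @param x an \code{enzyme_dataset}.
#' @export
n_records <- function(x) length(record_ids(x))

split_csv <- function(s) {
  v <- strsplit(s, ",", fixed = TRUE)[[1]]
  trimws(v[nzchar(trimws(v))])
}

split_roles <- function(s) {
  v <- strsplit(s, ";", fixed = TRUE)[[1]]
  trimws(v[nzchar(trimws(v))])
}

# -- validation ---------------------------------------------------------------

#' Validate an enzyme dataset
#'
#' Checks every structural invariant of the data model: unique record ids;
#' non-empty sequences over the 20-letter alphabet plus X (selenocysteine
#' \code{U} and pyrrolysine \code{O} are rejected); every residue annotation
#' resolving to a chain position whose sequence letter equals its
#' \code{residue_type}; catalytic annotations carrying at least one of the
#' seven roles while binding annotations carry none; well-formed,
#' non-overlapping domain segments and four-field CATH codes; cofactor roles
#' drawn from the seven categories plus \code{hydride_shuttle}; and the
#' catalytic unit being a subset of the biological unit.
#'
#' @param x an \code{enzyme_dataset}.
#' @param strict also require every record to possess catalytic machinery
#'   (at least one catalytic residue annotation or one cofactor). Reading
#'   partially annotated corpora uses \code{strict = FALSE} so that records
#'   whose chains are absent from the annotation tables are retained.
#' @return \code{x}, invisibly; errors describe the offending rows.
#' @export
validate_dataset <- function(x, strict = TRUE) {
  stopifnot(inherits(x, "enzyme_dataset"))
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  u <- x$units
  if (anyDuplicated(u$record_id)) {
    note("duplicated record_id in units: ",
         paste(unique(u$record_id[duplicated(u$record_id)]), collapse = ", "))
  }
  seqs <- x$sequences
  if (any(!nzchar(seqs$sequence))) {
    note("empty sequence for ",
         paste(seqs$record_id[!nzchar(seqs$sequence)], collapse = ", "))
  }
  letters_used <- unique(strsplit(paste(seqs$sequence, collapse = ""), "")[[1]])
  bad_letters <- setdiff(letters_used, c(aa_alphabet, "X"))
  if (length(bad_letters)) {
    if (any(c("U", "O") %in% bad_letters)) {
      note("selenocysteine/pyrrolysine (U/O) are not supported")
    } else {
      note("sequence letters outside alphabet: ",
           paste(bad_letters, collapse = ""))
    }
  }
  orphan <- !(seqs$record_id %in% u$record_id)
  if (any(orphan)) {
    note("sequences for unknown record(s): ",
         paste(unique(seqs$record_id[orphan]), collapse = ", "))
  }

  chain_key <- paste(seqs$record_id, seqs$chain_id)
  chain_len <- setNames(nchar(seqs$sequence), chain_key)

  r <- x$residues
  if (nrow(r)) {
    for (i in seq_len(nrow(r))) {
      key <- paste(r$record_id[i], r$chain_id[i])
      if (!key %in% chain_key) {
        note("residues row ", i, ": unknown chain ", key)
        next
      }
      if (is.na(r$position[i]) || r$position[i] < 1L ||
          r$position[i] > chain_len[[key]]) {
        note("residues row ", i, ": position ", r$position[i],
             " outside chain ", key, " (length ", chain_len[[key]], ")")
        next
      }
      letter <- substr(seqs$sequence[match(key, chain_key)],
                       r$position[i], r$position[i])
      if (letter != r$residue_type[i]) {
        note("residues row ", i, ": residue_type ", r$residue_type[i],
             " != sequence letter ", letter, " at ", key, ":", r$position[i])
      }
      roles_i <- split_roles(r$roles[i])
      if (r$function_context[i] == "catalytic") {
        if (!length(roles_i)) note("residues row ", i, ": catalytic with no role")
        if (length(setdiff(roles_i, catalytic_roles))) {
          note("residues row ", i, ": unknown role(s) ",
               paste(setdiff(roles_i, catalytic_roles), collapse = ";"))
        }
        if (!r$involvement[i] %in% c("reactant", "spectator")) {
          note("residues row ", i, ": bad involvement ", r$involvement[i])
        }
      } else if (r$function_context[i] == "binding") {
        if (length(roles_i)) note("residues row ", i, ": binding with roles")
      } else {
        note("residues row ", i, ": bad function_context ",
             r$function_context[i])
      }
      if (!r$acting_part[i] %in% acting_parts) {
        note("residues row ", i, ": bad acting_part ", r$acting_part[i])
      }
    }
  }

  d <- x$domains
  if (nrow(d)) {
    cath_ok <- grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", d$cath_code)
    for (i in which(!cath_ok)) {
      note("domains row ", i, ": cath_code ", d$cath_code[i],
           " is not four dotted integers")
    }
    for (i in seq_len(nrow(d))) {
      key <- paste(d$record_id[i], d$chain_id[i])
      if (!key %in% chain_key) {
        note("domains row ", i, ": unknown chain ", key)
        next
      }
      if (!segments_valid(d$segments[i])) {
        note("domains row ", i, ": bad segments ", d$segments[i])
        next
      }
      if (max(parse_segments(d$segments[i])[, 2L]) > chain_len[[key]]) {
        note("domains row ", i, ": segment beyond chain length")
      }
    }
  }

  cf <- x$cofactors
  if (nrow(cf)) {
    for (i in seq_len(nrow(cf))) {
      if (!cf$entity_kind[i] %in% entity_kinds) {
        note("cofactors row ", i, ": bad entity_kind ", cf$entity_kind[i])
      }
      roles_i <- split_roles(cf$roles[i])
      if (!length(roles_i)) note("cofactors row ", i, ": no roles")
      if (length(setdiff(roles_i, all_roles))) {
        note("cofactors row ", i, ": unknown role(s) ",
             paste(setdiff(roles_i, all_roles), collapse = ";"))
      }
      if (!cf$record_id[i] %in% u$record_id) {
        note("cofactors row ", i, ": unknown record ", cf$record_id[i])
      }
    }
  }

  for (i in seq_len(nrow(u))) {
    bio <- split_csv(u$biological_unit_chains[i])
    cat_ch <- split_csv(u$catalytic_unit_chains[i])
    if (!all(cat_ch %in% bio)) {
      note("units row ", i, " (", u$record_id[i],
           "): catalytic unit not a subset of biological unit")
    }
    known <- seqs$chain_id[seqs$record_id == u$record_id[i]]
    if (!all(unique(bio) %in% known)) {
      note("units row ", i, " (", u$record_id[i], "): unknown chain(s) ",
           paste(setdiff(unique(bio), known), collapse = ","))
    }
    if (nzchar(u$ec_nodes[i])) {
      tryCatch(parse_ec(split_ec_field(u$ec_nodes[i])[[1]]),
               error = function(e) note("units row ", i, ": ",
                                        conditionMessage(e)))
    }
  }

  if (strict) {
    has_cat <- u$record_id %in%
      r$record_id[r$function_context == "catalytic"] |
      u$record_id %in% cf$record_id
    if (any(!has_cat)) {
      note("record(s) without catalytic machinery: ",
           paste(u$record_id[!has_cat], collapse = ", "))
    }
  }

  if (length(problems)) {
    stop("invalid enzyme_dataset:\n  ",
         paste(head(problems, 20L), collapse = "\n  "), call. = FALSE)
  }
  invisible(x)
}

# -- IO -----------------------------------------------------------------------

dataset_files <- c(sequences = "sequences.fasta", residues = "residues.tsv",
                   domains = "domains.tsv", cofactors = "cofactors.tsv",
                   units = "units.tsv")

#' Read an enzyme dataset from disk
#'
#' Loads the five-file on-disk representation: a FASTA of chain sequences
#' (headers \code{record_id|chain_id}) and four TSV annotation tables
#' (\code{residues.tsv}, \code{domains.tsv}, \code{cofactors.tsv},
#' \code{units.tsv}). Positions are 1-based, segment ranges inclusive.
#' Records present in the FASTA but absent from the annotation tables are
#' retained with empty annotations; annotation rows referencing unknown
#' chains or out-of-range positions raise a linkage error naming the row.
#'
#' @param dir directory containing the files.
#' @param strict passed to \code{\link{validate_dataset}}; default
#'   \code{FALSE} so that partially annotated corpora load.
#' @return An \code{enzyme_dataset}.
#' @seealso \code{\link{write_dataset}}
#' @export
read_dataset <- function(dir, strict = FALSE) {
  paths <- file.path(dir, dataset_files)
  names(paths) <- names(dataset_files)
  if (!file.exists(paths[["sequences"]])) {
    stop("missing sequence file: ", paths[["sequences"]])
  }
  fa <- Biostrings::readAAStringSet(paths[["sequences"]])
  hdr <- strsplit(names(fa), "|", fixed = TRUE)
  if (any(lengths(hdr) != 2L)) {
    stop("FASTA headers must be record_id|chain_id")
  }
  sequences <- data.frame(
    record_id = vapply(hdr, `[`, "", 1L),
    chain_id = vapply(hdr, `[`, "", 2L),
    sequence = as.character(fa),
    stringsAsFactors = FALSE
  )

  read_tsv <- function(path, required) {
    if (!file.exists(path)) return(NULL)
    df <- read.delim(path, colClasses = "character", comment.char = "#",
                     stringsAsFactors = FALSE)
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("format error in ", basename(path), ": missing column(s) ",
           paste(missing, collapse = ", "))
    }
    df
  }
  residues <- read_tsv(paths[["residues"]],
                       c("record_id", "chain_id", "position", "residue_type",
                         "function_context", "involvement", "roles",
                         "acting_part"))
  domains <- read_tsv(paths[["domains"]],
                      c("record_id", "chain_id", "cath_code", "segments"))
  cofactors <- read_tsv(paths[["cofactors"]],
                        c("record_id", "cofactor_id", "entity_kind", "roles"))
  units <- read_tsv(paths[["units"]],
                    c("record_id", "biological_unit_chains",
                      "catalytic_unit_chains", "ec_nodes"))
  if (!is.null(units) && !is.null(units$has_structure)) {
    units$has_structure <- toupper(units$has_structure) == "TRUE"
  }
  if (is.null(units)) units_arg <- NULL else {
    # records only in the FASTA are retained with default unit annotations
    extra <- setdiff(unique(sequences$record_id), units$record_id)
    if (length(extra)) {
      chains <- vapply(extra, function(i) {
        paste(sequences$chain_id[sequences$record_id == i], collapse = ",")
      }, character(1))
      units <- rbind(units[, c("record_id", "biological_unit_chains",
                               "catalytic_unit_chains", "ec_nodes",
                               "has_structure")],
                     data.frame(record_id = extra,
                                biological_unit_chains = chains,
                                catalytic_unit_chains = chains,
                                ec_nodes = "", has_structure = FALSE,
                                stringsAsFactors = FALSE))
    }
    units_arg <- units
  }
  enzyme_dataset(sequences, residues, domains, cofactors, units_arg,
                 provenance = paste0("read from ", dir),
                 validate = TRUE, strict = strict)
}

#' Write an enzyme dataset to disk
#'
#' Writes the five-file representation read back by
#' \code{\link{read_dataset}}. Rows are emitted in a canonical sort order so
#' repeated writes of the same dataset are byte-identical, and
#' \code{read_dataset(write_dataset(d))} reproduces \code{d} field for field.
#'
#' @param x an \code{enzyme_dataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "enzyme_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- canonicalize_dataset(x)
  hdr <- if (nrow(x$sequences)) {
    paste0(x$sequences$record_id, "|", x$sequences$chain_id)
  } else character(0)
  fa <- Biostrings::AAStringSet(setNames(x$sequences$sequence, hdr))
  Biostrings::writeXStringSet(fa, file.path(dir, dataset_files[["sequences"]]))
  wt <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(x$residues, dataset_files[["residues"]])
  wt(x$domains, dataset_files[["domains"]])
  wt(x$cofactors, dataset_files[["cofactors"]])
  u <- x$units
  u$has_structure <- ifelse(u$has_structure, "TRUE", "FALSE")
  wt(u, dataset_files[["units"]])
  invisible(dir)
}

# -- selection ----------------------------------------------------------------

#' Keep records with at least one complete EC node
#'
#' The families-per-node analyses operate on EC nodes (fully defined
#' four-level EC numbers). This filter retains records carrying at least one
#' complete node; records with several nodes are retained once and later
#' counted under each of their complete nodes. Idempotent.
#'
#' @param x an \code{enzyme_dataset}.
#' @return the filtered \code{enzyme_dataset}.
#' @export
select_complete_ec <- function(x) {
  stopifnot(inherits(x, "enzyme_dataset"))
  keep <- vapply(split_ec_field(x$units$ec_nodes), function(nodes) {
    length(nodes) > 0L && any(is_complete_ec(nodes))
  }, logical(1))
  subset_dataset(x, x$units$record_id[keep])
}

#' Subset a dataset to a set of record ids
#' @param x an \code{enzyme_dataset}.
#' @param ids record ids to keep.
#' @return the filtered \code{enzyme_dataset}.
#' @export
subset_dataset <- function(x, ids) {
  stopifnot(inherits(x, "enzyme_dataset"))
  out <- x
  out$units <- x$units[x$units$record_id %in% ids, , drop = FALSE]
  for (nm in c("sequences", "residues", "domains", "cofactors")) {
    out[[nm]] <- x[[nm]][x[[nm]]$record_id %in% ids, , drop = FALSE]
  }
  canonicalize_dataset(out)
}

#' Keep records with an associated structure
#'
#' Restricts the corpus to records flagged \code{has_structure}, enabling
#' matched-subset comparisons between the sequence-based and structure-based
#' family counts.
#'
#' @param x an \code{enzyme_dataset}.
#' @return the filtered \code{enzyme_dataset}.
#' @export
restrict_to_structures <- function(x) {
  stopifnot(inherits(x, "enzyme_dataset"))
  subset_dataset(x, x$units$record_id[x$units$has_structure])
}

# -- per-record view ----------------------------------------------------------

#' Extract one enzyme record
#'
#' @param x an \code{enzyme_dataset}.
#' @param id a record id.
#' @return An \code{enzyme_record} list: \code{record_id}, \code{ec_nodes}
#'   (character vector), \code{chains} (named character vector of sequences),
#'   \code{domains}, \code{residues}, \code{cofactors} (data.frame slices),
#'   \code{biological_unit_chains} (with multiplicity),
#'   \code{catalytic_unit_chains}, \code{has_structure}.
#' @export
get_record <- function(x, id) {
  stopifnot(inherits(x, "enzyme_dataset"))
  i <- match(id, x$units$record_id)
  if (is.na(i)) stop("unknown record id: ", id)
  s <- x$sequences[x$sequences$record_id == id, , drop = FALSE]
  structure(list(
    record_id = id,
    ec_nodes = split_ec_field(x$units$ec_nodes[i])[[1]],
    chains = setNames(s$sequence, s$chain_id),
    domains = x$domains[x$domains$record_id == id, , drop = FALSE],
    residues = x$residues[x$residues$record_id == id, , drop = FALSE],
    cofactors = x$cofactors[x$cofactors$record_id == id, , drop = FALSE],
    biological_unit_chains = split_csv(x$units$biological_unit_chains[i]),
    catalytic_unit_chains = split_csv(x$units$catalytic_unit_chains[i]),
    has_structure = x$units$has_structure[i]
  ), class = "enzyme_record")
}

#' @export
print.enzyme_record <- function(x, ...) {
  cat("<enzyme_record> ", x$record_id, "\n",
      "  EC: ", paste(x$ec_nodes, collapse = "; "), "\n",
      "  chains: ", length(x$chains), "  domains: ", nrow(x$domains),
      "  residue annotations: ", nrow(x$residues),
      "  cofactors: ", nrow(x$cofactors), "\n", sep = "")
  invisible(x)
}

#' @export
print.enzyme_dataset <- function(x, ...) {
  cat("<enzyme_dataset> ", n_records(x), " records, ",
      nrow(x$sequences), " chains, ", nrow(x$residues),
      " residue annotations, ", nrow(x$domains), " domains\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
summary.enzyme_dataset <- function(object, ...) {
  nodes <- unlist(split_ec_field(object$units$ec_nodes))
  complete <- if (length(nodes)) nodes[is_complete_ec(nodes)] else character(0)
  out <- list(
    n_records = n_records(object),
    n_chains = nrow(object$sequences),
    n_catalytic = sum(object$residues$function_context == "catalytic"),
    n_binding = sum(object$residues$function_context == "binding"),
    n_cofactors = nrow(object$cofactors),
    n_complete_ec_nodes = length(unique(complete)),
    n_with_structure = sum(object$units$has_structure)
  )
  class(out) <- "summary.enzyme_dataset"
  out
}

#' @export
print.summary.enzyme_dataset <- function(x, ...) {
  cat("Enzyme dataset summary\n",
      "  records:              ", x$n_records, "\n",
      "  chains:               ", x$n_chains, "\n",
      "  catalytic residues:   ", x$n_catalytic, "\n",
      "  binding residues:     ", x$n_binding, "\n",
      "  cofactors:            ", x$n_cofactors, "\n",
      "  complete EC nodes:    ", x$n_complete_ec_nodes, "\n",
      "  records w/ structure: ", x$n_with_structure, "\n", sep = "")
  invisible(x)
}
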