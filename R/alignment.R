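# Pairwise global alignment and percent identity. Stands in for BLAST-style
# pairwise identity: exact Needleman-Wunsch via Biostrings with BLOSUM62,
# affordable and deterministic at corpus scale.

#' Alignment parameters
#'
#' @param substitution_matrix name of a substitution matrix shipped with
#'   Biostrings (default \code{"BLOSUM62"}).
#' @param gap_open gap opening penalty (positive number, applied as a cost).
#' @param gap_extend gap extension penalty per residue.
#' @return A list of class \code{alignment_params}.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.5) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 mode = "global"),
            class = "alignment_params")
}

.submat_cache <- new.env(parent = emptyenv())

get_submat <- function(params) {
  nm <- params$substitution_matrix
  if (!exists(nm, envir = .submat_cache)) {
    e <- new.env()
    utils::data(list = nm, package = "Biostrings", envir = e)
    assign(nm, get(nm, envir = e), envir = .submat_cache)
  }
  get(nm, envir = .submat_cache)
}

#' Global percent identity between two sequences
#'
#' Aligns the two sequences globally (Needleman-Wunsch) and reports
#' \code{identity} = identical aligned pairs / alignment columns x 100, and
#' \code{coverage} = aligned non-gap span / length of the shorter sequence.
#' Identity is symmetric in its arguments.
#'
#' @param seq_a,seq_b amino-acid strings (non-empty).
#' @param params an \code{\link{alignment_params}} object.
#' @return list with \code{identity} (percent) and \code{coverage} (0..1).
#' @examples
#' global_identity("ACDEF", "ACDEG")$identity  # 80
#' @export
global_identity <- function(seq_a, seq_b, params = alignment_params()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  res <- identity_to_subject(seq_a, seq_b, params)
  list(identity = res$identity[1L], coverage = res$coverage[1L])
}

# Vectorized form: identities of many patterns against one subject.
# Used by the clustering stages to amortize alignment set-up cost.
identity_to_subject <- function(patterns, subject,
                                params = alignment_params()) {
  submat <- get_submat(params)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = submat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "global")
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ni <- Biostrings::nindel(aln)
  gap_cols <- unname(Biostrings::insertion(ni)[, "WidthSum"] +
                       Biostrings::deletion(ni)[, "WidthSum"])
  cols <- nm + nmm + gap_cols       # alignment length including gaps
  span <- nm + nmm                  # columns where neither row has a gap
  shorter <- pmin(nchar(patterns), nchar(subject))
  list(identity = 100 * nm / cols, coverage = span / shorter)
}

# positional identity between equal-length strings (no alignment); used by
# the generator for its substitution-only model
positional_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  100 * sum(va == vb) / length(va)
}
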