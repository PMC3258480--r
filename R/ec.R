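# EC number helpers. An EC node is the four-level Enzyme Commission code
# "class.subclass.sub-subclass.serial"; unassigned levels are written "-".

#' Parse EC number strings
#'
#' Splits EC codes of the form \code{"2.7.11.1"} (or with \code{"-"} for
#' unassigned levels, e.g. \code{"3.4.-.-"}) into their four levels.
#'
#' @param ec character vector of EC codes.
#' @return A data.frame with integer columns \code{class_digit},
#'   \code{subclass}, \code{sub_subclass}, \code{serial} (\code{NA} where the
#'   level is unassigned) and the input string as \code{ec}.
#' @examples
#' parse_ec(c("2.7.11.1", "3.4.-.-"))
#' @export
parse_ec <- function(ec) {
  stopifnot(is.character(ec))
  parts <- strsplit(ec, ".", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed EC code(s): ", paste(ec[bad], collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  m[m == "-"] <- NA_character_
  out <- data.frame(
    ec = ec,
    class_digit = as.integer(m[, 1L]),
    subclass = as.integer(m[, 2L]),
    sub_subclass = as.integer(m[, 3L]),
    serial = as.integer(m[, 4L]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$class_digit) || any(!out$class_digit %in% 1:6)) {
    stop("EC class digit must be in 1..6: ",
         paste(ec[is.na(out$class_digit) | !out$class_digit %in% 1:6],
               collapse = ", "))
  }
  out
}

#' Test whether EC codes are complete four-level nodes
#'
#' A complete EC node has all four levels assigned to integers; such nodes
#' define a specific overall reaction and are the unit of the
#' families-per-node analyses.
#'
#' @param ec character vector of EC codes.
#' @return logical vector.
#' @examples
#' is_complete_ec(c("2.7.11.1", "3.4.-.-"))
#' @export
is_complete_ec <- function(ec) {
  p <- parse_ec(ec)
  !is.na(p$subclass) & !is.na(p$sub_subclass) & !is.na(p$serial)
}

#' First digit (enzyme class) of EC codes
#'
#' @param ec character vector of EC codes.
#' @return integer vector in 1..6.
#' @export
ec_class <- function(ec) parse_ec(ec)$class_digit

# Split a semicolon-joined multi-EC field into per-record character vectors.
split_ec_field <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}
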