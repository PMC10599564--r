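#' Construct a donor-sequence ensemble
#'
#' A donor ensemble is a multiset of 9-nucleotide 5' splice-site sequences:
#' the last three exonic bases (positions -3..-1) followed by the first six
#' intronic bases (+1..+6), over the alphabet A/C/G/T.
#'
#' @param sequences character vector of 9-mers over \{A,C,G,T\}.
#' @param species optional species label.
#' @param gt_restricted logical; if `TRUE` every member is checked to carry
#'   the canonical GT dinucleotide at intronic positions +1/+2.
#' @param origin optional provenance string (e.g. `"synthetic"`, a file path).
#' @return an object of class `donor_ensemble`.
#' @export
donor_ensemble <- function(sequences, species = NA_character_,
                           gt_restricted = FALSE, origin = NA_character_) {
  sequences <- as.character(sequences)
  cpp_encode_donor(sequences) # validates length-9 / alphabet, names entry
  if (gt_restricted && length(sequences) &&
      !all(substr(sequences, 4, 5) == "GT")) {
    stop("gt_restricted ensemble contains members without GT at +1/+2")
  }
  structure(
    list(sequences = sequences, species = species,
         gt_restricted = gt_restricted, origin = origin),
    class = "donor_ensemble"
  )
}

#' @export
length.donor_ensemble <- function(x) length(x$sequences)

#' @export
print.donor_ensemble <- function(x, ...) {
  cat(sprintf("donor_ensemble: %d sequences%s%s\n", length(x),
              if (!is.na(x$species)) paste0(" [", x$species, "]") else "",
              if (isTRUE(x$gt_restricted)) " (GT-restricted)" else ""))
  if (length(x)) {
    show <- head(x$sequences, 5)
    cat(paste0("  ", show, collapse = "\n"), "\n")
    if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5))
  }
  invisible(x)
}

#' Restrict an ensemble to canonical GT donors
#'
#' Keeps exactly the members whose intronic +1/+2 positions read `GT`,
#' mirroring the distinction between complete and GT-restricted donor sets.
#'
#' @param ensemble a [donor_ensemble()].
#' @return a `donor_ensemble` with `gt_restricted = TRUE`.
#' @export
restrict_gt <- function(ensemble) {
  stopifnot(inherits(ensemble, "donor_ensemble"))
  keep <- substr(ensemble$sequences, 4, 5) == "GT"
  donor_ensemble(ensemble$sequences[keep], species = ensemble$species,
                 gt_restricted = TRUE, origin = ensemble$origin)
}

#' Read a donor ensemble from a plain-text 9-mer list
#'
#' One sequence per line, no header; lines must be 9 characters over
#' \{A,C,G,T\} (lowercase accepted and uppercased, U mapped to T).
#'
#' @param path file path.
#' @param species optional species label.
#' @return a `donor_ensemble`.
#' @export
read_ensemble <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty ensemble file: ", path)
  lines <- chartr("u", "t", toupper(lines))
  lines <- chartr("U", "T", lines)
  ok <- tryCatch({ cpp_encode_donor(lines); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) {
    # re-raise naming the line number instead of the vector entry
    msg <- sub("^entry ([0-9]+):", "line \\1:", conditionMessage(ok))
    stop(path, ": ", msg)
  }
  donor_ensemble(lines, species = species, origin = path)
}

#' Write a donor ensemble as a plain-text 9-mer list
#'
#' @param ensemble a `donor_ensemble`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "donor_ensemble"))
  writeLines(ensemble$sequences, path)
  invisible(path)
}
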