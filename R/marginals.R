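#' Estimate one- and two-site marginal frequencies of a donor ensemble
#'
#' One-site frequencies are `f1[i,a] = (n_i(a) + alpha) / (N + 4 alpha)`;
#' two-site frequencies use a per-cell pseudocount of `alpha/4`, i.e.
#' `f2[ij,ab] = (n_ij(a,b) + alpha/4) / (N + 4 alpha)`, so that summing a
#' pair block over either member reproduces the one-site table exactly for
#' any pseudocount.
#'
#' @param ensemble a [donor_ensemble()]; must be non-empty.
#' @param pseudocount non-negative smoothing count `alpha` per
#'   (position, letter) cell.  Use a positive value (default 1 is
#'   conventional) before model fitting so all target marginals are
#'   strictly positive; use 0 for reporting raw frequencies.
#' @return an object of class `marginal_set` with elements `f1` (9 x 4),
#'   `f2` (36 pairs x 16 letter pairs), `n_sequences`, `pseudocount`.
#' @export
estimate_marginals <- function(ensemble, pseudocount = 0) {
  stopifnot(inherits(ensemble, "donor_ensemble"))
  if (!length(ensemble)) stop("cannot estimate marginals of an empty ensemble")
  stopifnot(pseudocount >= 0)
  codes <- cpp_encode_donor(ensemble$sequences)
  cts <- cpp_donor_counts(codes)
  n <- length(ensemble)
  denom <- n + 4 * pseudocount
  structure(
    list(f1 = .name_f1((cts$c1 + pseudocount) / denom),
         f2 = .name_f2((cts$c2 + pseudocount / 4) / denom),
         n_sequences = n, pseudocount = pseudocount),
    class = "marginal_set"
  )
}

.validate_marginal_set <- function(m) {
  stopifnot(inherits(m, "marginal_set"),
            identical(dim(m$f1), c(9L, 4L)),
            identical(dim(m$f2), c(36L, 16L)))
  invisible(m)
}

#' @export
print.marginal_set <- function(x, ...) {
  cat(sprintf(
    "marginal_set: %s sequences, pseudocount %g, consensus %s\n",
    format(x$n_sequences), x$pseudocount, consensus_sequence(x, quiet = TRUE)))
  invisible(x)
}

#' Consensus sequence of a marginal set
#'
#' The per-position argmax letter of the one-site frequencies; ties are
#' broken alphabetically with a warning.
#'
#' @param m a `marginal_set` (or model marginals of the same shape).
#' @param quiet suppress tie warnings.
#' @return a single 9-character string.
#' @export
consensus_sequence <- function(m, quiet = FALSE) {
  .validate_marginal_set(m)
  picks <- vapply(seq_len(9), function(i) {
    row <- m$f1[i, ]
    best <- which(row == max(row))
    if (length(best) > 1L && !quiet) {
      warning("tie for consensus letter at position ", DONOR_POSITIONS[i],
              "; using alphabetically first of {",
              paste(DONOR_LETTERS[best], collapse = ","), "}", call. = FALSE)
    }
    DONOR_LETTERS[best[1L]]
  }, character(1))
  paste(picks, collapse = "")
}

#' Per-position information content (bits)
#'
#' `IC_i = 2 + sum_a f1[i,a] log2 f1[i,a]` with `0 log 0 := 0`; values lie
#' in `[0, 2]` bits.
#'
#' @param m a `marginal_set`.
#' @return named numeric vector of 9 non-negative values.
#' @export
information_content <- function(m) {
  .validate_marginal_set(m)
  ic <- apply(m$f1, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  # clamp tiny negative rounding residue at the uniform end
  pmin(pmax(ic, 0), 2)
}

#' Write a marginal set as TSV tables
#'
#' Writes `<prefix>_f1.tsv`, `<prefix>_f2.tsv` and `<prefix>_ic.tsv` with
#' explicit position labels.
#'
#' @param m a `marginal_set`.
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_marginals <- function(m, prefix) {
  .validate_marginal_set(m)
  p1 <- paste0(prefix, "_f1.tsv")
  p2 <- paste0(prefix, "_f2.tsv")
  p3 <- paste0(prefix, "_ic.tsv")
  write.table(data.frame(position = rownames(m$f1), m$f1,
                         check.names = FALSE),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(pair = rownames(m$f2), m$f2, check.names = FALSE),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(position = rownames(m$f1),
                         ic_bits = information_content(m)),
              p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
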