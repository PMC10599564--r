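#' Score an ensemble's energies under a model
#'
#' @param model a [potts_model()].
#' @param ensemble a [donor_ensemble()] (or character vector of 9-mers).
#' @return an `energy_profile`: list with `energies` (aligned to the
#'   ensemble) and `summary` (mean, sd, quantiles incl. 5% and 95%).
#' @export
score_ensemble <- function(model, ensemble) {
  e <- energy(model, ensemble)
  structure(
    list(energies = e,
         summary = list(
           n = length(e),
           mean = mean(e),
           sd = if (length(e) > 1) sd(e) else 0,
           quantiles = quantile(e, c(0.05, 0.25, 0.5, 0.75, 0.95),
                                names = TRUE))),
    class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("energy_profile: n = %d, mean = %.3f, sd = %.3f, 90%% in [%.3f, %.3f]\n",
              x$summary$n, x$summary$mean, x$summary$sd,
              x$summary$quantiles[["5%"]], x$summary$quantiles[["95%"]]))
  invisible(x)
}

#' Uniformly random 9-mers
#'
#' The fully disordered null ensemble: i.i.d. uniform letters at every
#' position.
#'
#' @param n number of sequences.
#' @param seed optional integer for reproducibility.
#' @return a [donor_ensemble()].
#' @export
sample_random_sequences <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  seqs <- .with_seed(seed, {
    m <- matrix(sample(DONOR_LETTERS, 9 * n, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m))
  })
  donor_ensemble(seqs, origin = "synthetic")
}

#' Sample decoy 9-mers around genomic GT loci
#'
#' Samples `n_loci` GT dinucleotide positions uniformly with replacement
#' from both strands of the genome, keeps the 9-mer window (3 nt upstream +
#' GT + 4 nt downstream), drops windows with ambiguous bases or truncated
#' by a contig edge, reduces to unique sequences, and splits them by
#' whether the sequence occurs among the annotated donor sequences:
#' decoy-A sequences never do, decoy-B sequences match at least one
#' annotated donor.
#'
#' @param genome a `DNAStringSet` (or FASTA path).
#' @param annotated a [donor_ensemble()] of annotated donor sequences.
#' @param n_loci number of GT loci to sample.
#' @param seed optional integer.
#' @return list with `decoy_a`, `decoy_b` (disjoint `donor_ensemble`s of
#'   unique sequences), and counts `n_sampled`, `n_windows`, `n_unique`.
#' @export
sample_decoys <- function(genome, annotated, n_loci, seed = NULL) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  stopifnot(inherits(genome, "DNAStringSet"),
            inherits(annotated, "donor_ensemble"), n_loci >= 1)
  contigs <- as.character(genome)
  rc <- as.character(Biostrings::reverseComplement(genome))
  strands <- c(setNames(contigs, paste0(names(contigs), "+")),
               setNames(rc, paste0(names(contigs), "-")))
  loci <- do.call(rbind, lapply(names(strands), function(nm) {
    hits <- gregexpr("GT", strands[[nm]], fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    data.frame(seq = nm, at = as.integer(hits), stringsAsFactors = FALSE)
  }))
  if (is.null(loci) || !nrow(loci)) stop("genome contains no GT loci")
  pick <- .with_seed(seed, sample.int(nrow(loci), n_loci, replace = TRUE))
  loci <- loci[pick, , drop = FALSE]
  w_start <- loci$at - 3L
  w_end <- loci$at + 5L
  len <- nchar(strands)[loci$seq]
  inb <- w_start >= 1L & w_end <= len
  seqs <- substr(strands[loci$seq[inb]], w_start[inb], w_end[inb])
  seqs <- seqs[!grepl("[^ACGT]", seqs)]
  uniq <- unique(unname(seqs))
  in_annotated <- uniq %in% annotated$sequences
  list(
    decoy_a = donor_ensemble(uniq[!in_annotated], origin = "decoy-A",
                             gt_restricted = TRUE),
    decoy_b = donor_ensemble(uniq[in_annotated], origin = "decoy-B",
                             gt_restricted = TRUE),
    n_sampled = as.integer(n_loci),
    n_windows = length(seqs),
    n_unique = length(uniq))
}

#' Wilcoxon rank-sum comparison of two energy profiles
#'
#' Two-sided Mann-Whitney test with normal approximation and tie
#' correction.
#'
#' @param a,b `energy_profile` objects (or bare numeric vectors).
#' @return list with `statistic` (the Mann-Whitney U for the first sample)
#'   and `p_value`.
#' @export
rank_sum_compare <- function(a, b) {
  ea <- if (inherits(a, "energy_profile")) a$energies else as.numeric(a)
  eb <- if (inherits(b, "energy_profile")) b$energies else as.numeric(b)
  if (!length(ea) || !length(eb)) stop("both samples must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(ea, eb, alternative = "two.sided", exact = FALSE,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Minimum-energy sequence
#'
#' @param model a `potts_model`.
#' @param scope `"all_states"` (exhaustive scan over all 4^9 sequences) or
#'   `"ensemble"` (argmin within `ensemble`).  Ties break lexicographically.
#' @param ensemble required when `scope = "ensemble"`.
#' @return list with `sequence` and `energy`.
#' @export
minimum_energy_sequence <- function(model, scope = c("all_states", "ensemble"),
                                    ensemble = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(model, "potts_model"))
  if (scope == "all_states") {
    E <- cpp_all_energies(model$h, model$J)
    # state order is lexicographic, so which.min's first hit is the tie rule
    best <- which.min(E)
    list(sequence = cpp_decode_donor(best - 1L), energy = E[best])
  } else {
    if (is.null(ensemble)) stop("scope = 'ensemble' requires an ensemble")
    seqs <- if (inherits(ensemble, "donor_ensemble")) ensemble$sequences
            else as.character(ensemble)
    e <- energy(model, seqs)
    ord <- order(e, seqs)
    list(sequence = seqs[ord[1]], energy = e[ord[1]])
  }
}

#' Export per-sequence energies as TSV
#'
#' @param ensemble a `donor_ensemble`.
#' @param profile the matching `energy_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_energies <- function(ensemble, profile, path) {
  stopifnot(length(ensemble) == length(profile$energies))
  write.table(data.frame(sequence = ensemble$sequences,
                         energy = profile$energies),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
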