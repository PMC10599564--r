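#' Construct a Potts model for donor sequences
#'
#' The model assigns each 9-mer `S = (s_-3,...,s_+6)` a data-driven energy
#' `E(S) = - sum_i h_i(s_i) - sum_{i<j} J_ij(s_i, s_j)` and probability
#' `P(S) = exp(-E(S)) / Z` with `Z` summed over all 4^9 states.
#'
#' @param h 9 x 4 field matrix (positions x letters A,C,G,T).
#' @param J 36 x 16 coupling matrix (position pairs x letter pairs);
#'   couplings shrunk away by the fitter are exact zeros.
#' @param gamma the L1 regularization level the model was fitted at
#'   (`NA` for hand-built models).
#' @param gauge_tag gauge convention label; `"zero-sum-h"` means the fields
#'   sum to zero over letters at every position.
#' @param fit_metadata optional list of fitter diagnostics.
#' @return an object of class `potts_model`.
#' @export
potts_model <- function(h, J, gamma = NA_real_, gauge_tag = "none",
                        fit_metadata = NULL) {
  h <- .name_f1(as.matrix(h))
  J <- .name_f2(as.matrix(J))
  stopifnot(identical(dim(h), c(9L, 4L)), identical(dim(J), c(36L, 16L)),
            all(is.finite(h)), all(is.finite(J)))
  if (identical(gauge_tag, "zero-sum-h") &&
      max(abs(rowSums(h))) > 1e-10) {
    stop("gauge_tag is 'zero-sum-h' but fields do not sum to zero per position")
  }
  structure(list(h = h, J = J, gamma = gamma, gauge_tag = gauge_tag,
                 fit_metadata = fit_metadata),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  nz <- sum(x$J != 0)
  cat(sprintf(
    "potts_model: 36 field and 576 coupling parameters (%d nonzero J)%s, gauge %s\n",
    nz, if (is.na(x$gamma)) "" else sprintf(", gamma = %g", x$gamma),
    x$gauge_tag))
  invisible(x)
}

# coerce sequences argument (ensemble / character) to encoded states
.as_states <- function(seqs) {
  if (inherits(seqs, "donor_ensemble")) seqs <- seqs$sequences
  cpp_encode_donor(as.character(seqs))
}

#' Data-driven energy of donor sequences under a model
#'
#' @param model a [potts_model()].
#' @param seqs a [donor_ensemble()] or character vector of 9-mers.
#' @return numeric vector of energies `E(S)`.
#' @export
energy <- function(model, seqs) {
  stopifnot(inherits(model, "potts_model"))
  states <- .as_states(seqs)
  if (!length(states)) return(numeric(0))
  # digits of each state, 1..4, position -3 most significant
  dig <- matrix(0L, length(states), 9)
  tmp <- states
  for (i in 9:1) {
    dig[, i] <- tmp %% 4L
    tmp <- tmp %/% 4L
  }
  e <- numeric(length(states))
  for (i in 1:9) e <- e - model$h[cbind(i, dig[, i] + 1L)]
  for (k in 1:36) {
    a <- dig[, .pair_table$i[k]]
    b <- dig[, .pair_table$j[k]]
    e <- e - model$J[cbind(k, a * 4L + b + 1L)]
  }
  e
}

#' Log partition function
#'
#' `log Z = log sum_S exp(-E(S))` over all 262144 states, computed by
#' exact enumeration with log-sum-exp stabilization.
#'
#' @param model a `potts_model`.
#' @return the scalar `log Z`.
#' @export
partition_function <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  cpp_enumerate(model$h, model$J, FALSE)$logZ
}

#' Normalized sequence probabilities
#'
#' @param model a `potts_model`.
#' @param seqs ensemble or character vector of 9-mers.
#' @return numeric vector of probabilities `P(S) = exp(-E(S) - log Z)`.
#' @export
sequence_probability <- function(model, seqs) {
  exp(-energy(model, seqs) - partition_function(model))
}

#' Exact model marginals
#'
#' One- and two-site probabilities `P_i(a)`, `P_ij(a,b)` obtained by
#' summing the Boltzmann weights over the enumerated state space.
#'
#' @param model a `potts_model`.
#' @return a `marginal_set` whose `f1`/`f2` are the model probabilities
#'   (`n_sequences = NA`, `pseudocount = NA`, attribute `source = "model"`).
#' @export
model_marginals <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  en <- cpp_enumerate(model$h, model$J, TRUE)
  out <- structure(
    list(f1 = .name_f1(en$P1), f2 = .name_f2(en$P2),
         n_sequences = NA_integer_, pseudocount = NA_real_),
    class = "marginal_set")
  attr(out, "source") <- "model"
  attr(out, "logZ") <- en$logZ
  out
}

#' Nonzero couplings of a fitted model
#'
#' @param model a `potts_model`.
#' @return a data.frame with one row per exactly-nonzero coupling, sorted by
#'   `|J|` descending: `id` (field notation, e.g. `"-1G:+6T"`), positions,
#'   letters and `value`.
#' @export
active_couplings <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  nz <- which(model$J != 0, arr.ind = TRUE)
  if (!nrow(nz)) {
    return(data.frame(id = character(0), pos_i = character(0),
                      letter_i = character(0), pos_j = character(0),
                      letter_j = character(0), value = numeric(0)))
  }
  k <- nz[, "row"]; cell <- nz[, "col"]
  a <- (cell - 1L) %/% 4L + 1L
  b <- (cell - 1L) %% 4L + 1L
  out <- data.frame(
    id = .coupling_id(k, cell),
    pos_i = DONOR_POSITIONS[.pair_table$i[k]],
    letter_i = DONOR_LETTERS[a],
    pos_j = DONOR_POSITIONS[.pair_table$j[k]],
    letter_j = DONOR_LETTERS[b],
    value = model$J[nz],
    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$value), out$id), ]
  rownames(out) <- NULL
  out
}

#' Sample donor sequences exactly from a model
#'
#' Draws i.i.d. sequences from the enumerated categorical distribution over
#' all 4^9 states (no MCMC).
#'
#' @param model a `potts_model`.
#' @param n number of draws.
#' @param seed optional integer; if given, sampling is reproducible and the
#'   caller's RNG state is left untouched.
#' @param species species label for the resulting ensemble.
#' @return a [donor_ensemble()] of `n` sequences.
#' @export
sample_sequences <- function(model, n, seed = NULL,
                             species = NA_character_) {
  stopifnot(inherits(model, "potts_model"), n >= 1)
  en <- cpp_enumerate(model$h, model$J, FALSE)
  E <- cpp_all_energies(model$h, model$J)
  p <- exp(-E - en$logZ)
  states <- .with_seed(seed, cpp_sample_states(p, as.integer(n)))
  donor_ensemble(cpp_decode_donor(states), species = species,
                 origin = "synthetic")
}

#' Serialize a Potts model to JSON
#'
#' Zero couplings are omitted from the document and restored as exact zeros
#' on read.
#'
#' @param model a `potts_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_potts <- function(model, path) {
  stopifnot(inherits(model, "potts_model"))
  ac <- active_couplings(model)
  doc <- list(
    format = "splicepotts-model",
    positions = DONOR_POSITIONS,
    letters = DONOR_LETTERS,
    h = unname(apply(model$h, 1, as.numeric, simplify = FALSE)),
    couplings = if (nrow(ac)) ac[c("id", "value")] else
      data.frame(id = character(0), value = numeric(0)),
    gamma = model$gamma,
    gauge_tag = model$gauge_tag,
    fit_metadata = model$fit_metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a Potts model from JSON
#'
#' @param path path written by [write_potts()].
#' @return a `potts_model`.
#' @export
read_potts <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "splicepotts-model")) {
    stop("not a splicepotts model document: ", path)
  }
  h <- doc$h
  if (is.list(h)) h <- do.call(rbind, h)
  h <- as.matrix(h)
  J <- matrix(0, 36, 16)
  ids <- doc$couplings$id
  if (length(ids)) {
    all_ids <- outer(seq_len(36), seq_len(16), .coupling_id)
    hit <- match(ids, all_ids)
    if (anyNA(hit)) stop("unknown coupling id in ", path)
    J[cbind((hit - 1L) %% 36L + 1L, (hit - 1L) %/% 36L + 1L)] <-
      doc$couplings$value
  }
  potts_model(h, J, gamma = doc$gamma %||% NA_real_,
              gauge_tag = doc$gauge_tag %||% "none",
              fit_metadata = doc$fit_metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
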