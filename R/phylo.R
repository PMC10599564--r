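#' Sankoff parsimony score of a binary trait on a tree
#'
#' Minimum total substitution cost over all ancestral state assignments,
#' by tip-to-root dynamic programming.  Polytomies are handled naturally;
#' under the default unit cost matrix the score is the integer minimum
#' number of state changes.
#'
#' @param tree an [ape::phylo] tree (rooted; branch lengths are ignored).
#' @param tip_states named vector (names = tip labels) of states coercible
#'   to 0/1 (logical or integer).
#' @param cost 2 x 2 substitution cost matrix, zero diagonal and positive
#'   off-diagonal (default unit costs).
#' @return the minimum total cost (an integer under unit costs).
#' @export
sankoff_parsimony <- function(tree, tip_states, cost = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(cost)) cost <- matrix(c(0, 1, 1, 0), 2, 2)
  stopifnot(all(dim(cost) == 2), all(diag(cost) == 0),
            all(cost[row(cost) != col(cost)] > 0))
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss)) {
    stop("no state for leaf '", miss[1], "'",
         if (length(miss) > 1) paste0(" (and ", length(miss) - 1, " more)"))
  }
  st <- as.integer(tip_states[tree$tip.label])
  if (anyNA(st) || !all(st %in% c(0L, 1L))) {
    stop("tip states must be binary (0/1)")
  }
  po <- ape::reorder.phylo(tree, "postorder")
  cpp_sankoff(po$edge[, 1], po$edge[, 2], length(tree$tip.label),
              tree$Nnode, st, cost)
}

#' Maddison-Slatkin randomization test for phylogenetic signal
#'
#' Permutes the tip-state assignment uniformly (preserving the number of
#' present/absent tips), recomputes the Sankoff parsimony score for each
#' permutation, and reports `p_raw = (1 + #\{null <= observed\}) /
#' (1 + n_perm)`: a small observed score relative to the null indicates
#' phylogenetic clustering of the trait.
#'
#' @inheritParams sankoff_parsimony
#' @param n_perm number of random tip assignments.
#' @param seed optional integer for reproducibility.
#' @return an object of class `phylo_signal_result`: list with `observed`,
#'   `null_min`, `null_median`, `null_max`, `p_raw`, `p_bonferroni` (`NA`
#'   until [bonferroni_adjust()]), `n_perm`, and `constant` flagging traits
#'   with a single state (reported as `observed = 0`, `p_raw = 1`).
#' @export
maddison_slatkin <- function(tree, tip_states, n_perm = 10000L,
                             seed = NULL, cost = NULL) {
  stopifnot(inherits(tree, "phylo"), n_perm >= 1)
  if (is.null(cost)) cost <- matrix(c(0, 1, 1, 0), 2, 2)
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss)) stop("no state for leaf '", miss[1], "'")
  st <- as.integer(tip_states[tree$tip.label])
  if (length(unique(st)) < 2L) {
    return(structure(list(observed = 0, null_min = 0, null_median = 0,
                          null_max = 0, p_raw = 1, p_bonferroni = NA_real_,
                          n_perm = as.integer(n_perm), constant = TRUE),
                     class = "phylo_signal_result"))
  }
  obs <- sankoff_parsimony(tree, tip_states, cost)
  po <- ape::reorder.phylo(tree, "postorder")
  null <- .with_seed(seed,
    cpp_ms_null(po$edge[, 1], po$edge[, 2], length(tree$tip.label),
                tree$Nnode, st, cost, as.integer(n_perm)))
  structure(list(observed = obs,
                 null_min = min(null),
                 null_median = median(null),
                 null_max = max(null),
                 p_raw = (1 + sum(null <= obs)) / (1 + n_perm),
                 p_bonferroni = NA_real_,
                 n_perm = as.integer(n_perm),
                 constant = FALSE),
            class = "phylo_signal_result")
}

#' @export
print.phylo_signal_result <- function(x, ...) {
  cat(sprintf(
    "phylo_signal_result: observed %g, null %g/%g/%g (min/median/max), p_raw %.4g%s\n",
    x$observed, x$null_min, x$null_median, x$null_max, x$p_raw,
    if (isTRUE(x$constant)) " [constant trait]" else ""))
  invisible(x)
}

#' Bonferroni correction across tested couplings
#'
#' Sets `p_bonferroni = min(1, p_raw * m)` where `m` is the number of
#' results in the list.
#'
#' @param results a non-empty list of `phylo_signal_result` objects (or a
#'   data.frame with a `p_raw` column).
#' @return the same structure with `p_bonferroni` filled in.
#' @export
bonferroni_adjust <- function(results) {
  if (is.data.frame(results)) {
    if (!nrow(results)) stop("empty result set")
    results$p_bonferroni <- pmin(1, results$p_raw * nrow(results))
    return(results)
  }
  if (!length(results)) stop("empty result set")
  m <- length(results)
  lapply(results, function(r) {
    r$p_bonferroni <- min(1, r$p_raw * m)
    r
  })
}

#' Coupling presence/absence matrix across species models
#'
#' One column per coupling that is exactly nonzero in at least one species
#' model; an entry is 1 iff that coupling is nonzero in that species.
#'
#' @param models named list of `potts_model`s sharing the package's
#'   position/letter conventions.
#' @return integer matrix, species x coupling identifiers (`"-1G:+6T"`
#'   notation).
#' @export
presence_absence_matrix <- function(models) {
  stopifnot(is.list(models), length(models) > 0,
            !is.null(names(models)), all(nzchar(names(models))))
  active <- lapply(models, function(mo) active_couplings(mo)$id)
  ids <- sort(unique(unlist(active)))
  out <- matrix(0L, nrow = length(models), ncol = length(ids),
                dimnames = list(names(models), ids))
  for (sp in names(models)) out[sp, ids %in% active[[sp]]] <- 1L
  out
}

#' Maddison-Slatkin scan over a trait matrix
#'
#' Runs [maddison_slatkin()] on every column of a presence/absence matrix
#' and applies the Bonferroni correction across the tested couplings.
#' Species absent from the tree are dropped with a warning.
#'
#' @param tree an `ape::phylo` tree.
#' @param traits matrix from [presence_absence_matrix()] (rows = species).
#' @param n_perm permutations per coupling.
#' @param seed optional integer; per-coupling seeds are derived from it.
#' @param cost optional 2 x 2 cost matrix.
#' @return data.frame with one row per coupling: `coupling`, `observed`,
#'   `null_min`, `null_median`, `null_max`, `p_raw`, `p_bonferroni`,
#'   `constant`.
#' @export
phylo_signal_scan <- function(tree, traits, n_perm = 10000L, seed = NULL,
                              cost = NULL) {
  stopifnot(inherits(tree, "phylo"), is.matrix(traits))
  drop <- setdiff(rownames(traits), tree$tip.label)
  if (length(drop)) {
    warning("dropping ", length(drop),
            " species absent from the tree: ",
            paste(head(drop, 3), collapse = ", "),
            if (length(drop) > 3) ", ...", call. = FALSE)
    traits <- traits[setdiff(rownames(traits), drop), , drop = FALSE]
  }
  miss <- setdiff(tree$tip.label, rownames(traits))
  if (length(miss)) {
    tree <- ape::drop.tip(tree, miss)
  }
  res <- lapply(seq_len(ncol(traits)), function(k) {
    maddison_slatkin(tree, traits[, k], n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else seed + k,
                     cost = cost)
  })
  out <- data.frame(
    coupling = colnames(traits),
    observed = vapply(res, `[[`, numeric(1), "observed"),
    null_min = vapply(res, `[[`, numeric(1), "null_min"),
    null_median = vapply(res, `[[`, numeric(1), "null_median"),
    null_max = vapply(res, `[[`, numeric(1), "null_max"),
    p_raw = vapply(res, `[[`, numeric(1), "p_raw"),
    constant = vapply(res, `[[`, logical(1), "constant"),
    stringsAsFactors = FALSE)
  bonferroni_adjust(out)
}
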