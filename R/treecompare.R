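#' Vectorized two-site probabilities of a model
#'
#' The 36 x 16 model two-site probability table flattened (pair blocks in
#' the fixed lexicographic order, 16 letter-pair cells each) into the
#' 576-entry feature vector used for inter-species distances.
#'
#' @param model a `potts_model`.
#' @param empirical optional `marginal_set`; if supplied, its `f2` is
#'   vectorized instead of the model's `P_ij` (empirical mode).
#' @return named numeric vector of length 576.
#' @export
pij_feature_vector <- function(model, empirical = NULL) {
  f2 <- if (is.null(empirical)) {
    model_marginals(model)$f2
  } else {
    .validate_marginal_set(empirical)
    empirical$f2
  }
  v <- as.vector(t(f2))
  names(v) <- as.vector(t(outer(rownames(f2), colnames(f2),
                                function(p, l) paste0(p, "_", l))))
  v
}

#' Pairwise distance matrix between species models
#'
#' Euclidean distance between the vectorized two-site probabilities of
#' each pair of models.
#'
#' @param models named list of `potts_model`s.
#' @param empirical optional named list of `marginal_set`s (same names) to
#'   use empirical `f_ij` instead of model `P_ij`.
#' @return a symmetric matrix with species names.
#' @export
pij_distance_matrix <- function(models, empirical = NULL) {
  stopifnot(is.list(models), !is.null(names(models)))
  feats <- if (is.null(empirical)) {
    vapply(models, pij_feature_vector, numeric(576))
  } else {
    stopifnot(identical(names(models), names(empirical)))
    vapply(names(models), function(nm) {
      pij_feature_vector(models[[nm]], empirical = empirical[[nm]])
    }, numeric(576))
  }
  as.matrix(dist(t(feats), method = "euclidean"))
}

#' Complete-linkage dendrogram from a distance matrix
#'
#' @param d symmetric non-negative matrix with zero diagonal (labelled),
#'   or a `dist` object.
#' @return an `hclust` object.
#' @export
complete_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
    if (anyNA(d) || any(!is.finite(d))) stop("distance matrix contains NA/Inf")
    if (any(d < 0)) stop("distance matrix has negative entries")
    d <- as.dist(d)
  }
  if (anyNA(d)) stop("distance matrix contains NA/Inf")
  hclust(d, method = "complete")
}

# cophenetic distance matrix from hclust / dendrogram / phylo, labelled
.coph_matrix <- function(x) {
  if (inherits(x, "phylo")) {
    return(as.matrix(ape::cophenetic.phylo(x)))
  }
  if (inherits(x, "dendrogram")) x <- as.hclust(x)
  if (inherits(x, "hclust")) {
    return(as.matrix(cophenetic(x)))
  }
  stop("expected an hclust, dendrogram or phylo object")
}

#' Cophenetic correlation between two trees/dendrograms
#'
#' Pearson correlation between the two cophenetic distance matrices
#' (merge heights for dendrograms, patristic distances for phylogenies)
#' over all label pairs.  The two objects must carry identical label sets.
#'
#' @param a,b `hclust`, `dendrogram`, or `ape::phylo` objects.
#' @return correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(a, b) {
  ma <- .coph_matrix(a)
  mb <- .coph_matrix(b)
  only_a <- setdiff(rownames(ma), rownames(mb))
  only_b <- setdiff(rownames(mb), rownames(ma))
  if (length(only_a) || length(only_b)) {
    stop("label sets differ; only in first: {",
         paste(only_a, collapse = ","), "}, only in second: {",
         paste(only_b, collapse = ","), "}")
  }
  lab <- rownames(ma)
  mb <- mb[lab, lab]
  lt <- lower.tri(ma)
  cor(ma[lt], mb[lt], method = "pearson")
}

# phylo -> hclust: directly when ultrametric (exact), otherwise by
# complete linkage on patristic distances (a faithful hierarchical
# rendering of the tree's distance structure)
.phylo_as_hclust <- function(x) {
  xb <- ape::multi2di(x)
  if (ape::is.ultrametric(xb, tol = 1e-8)) {
    as.hclust(xb)
  } else {
    hclust(as.dist(ape::cophenetic.phylo(x)), method = "complete")
  }
}

# k-cluster memberships from hclust / dendrogram / phylo
.cut_memberships <- function(x, k) {
  if (inherits(x, "phylo")) x <- .phylo_as_hclust(x)
  if (inherits(x, "dendrogram")) x <- as.hclust(x)
  cutree(x, k = k)
}

.bk_index <- function(ca, cb) {
  n <- length(ca)
  tab <- table(ca, cb)
  Tk <- sum(tab^2) - n
  Pk <- sum(rowSums(tab)^2) - n
  Qk <- sum(colSums(tab)^2) - n
  if (Pk == 0 || Qk == 0) return(NA_real_)
  Tk / sqrt(Pk * Qk)
}

#' Fowlkes-Mallows Bk comparison of two dendrograms
#'
#' For each `k`, both dendrograms are cut into `k` clusters and the
#' Fowlkes-Mallows index `Bk = Tk / sqrt(Pk Qk)` is computed from the
#' cluster contingency table.  Significance is assessed by permuting one
#' side's labels `n_perm` times:
#' `p = (1 + #\{null >= Bk\}) / (1 + n_perm)`.
#'
#' @param a,b `hclust` / `dendrogram` / ultrametric `phylo` objects with
#'   identical label sets.
#' @param k_range integer vector of cut levels, each in `[2, n - 1]`.
#' @param n_perm number of label permutations per `k`.
#' @param seed optional integer.
#' @return data.frame with columns `k`, `bk`, `p_value`.
#' @export
fowlkes_mallows_bk <- function(a, b, k_range = NULL, n_perm = 1000L,
                               seed = NULL) {
  la <- .tree_labels(a); lb <- .tree_labels(b)
  if (!setequal(la, lb)) stop("label sets differ between the dendrograms")
  n <- length(la)
  if (is.null(k_range)) k_range <- 2:(n - 1)
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k must lie in [2, n-1] = [2, ", n - 1, "]")
  }
  .with_seed(seed, {
    out <- lapply(k_range, function(k) {
      ca <- .cut_memberships(a, k)
      cb <- .cut_memberships(b, k)[names(ca)]
      bk <- .bk_index(ca, cb)
      null <- vapply(seq_len(n_perm), function(r) {
        .bk_index(ca, sample(cb))
      }, numeric(1))
      data.frame(k = k, bk = bk,
                 p_value = (1 + sum(null >= bk, na.rm = TRUE)) / (1 + n_perm))
    })
    do.call(rbind, out)
  })
}

# label set of hclust/dendrogram/phylo
.tree_labels <- function(x) {
  if (inherits(x, "phylo")) return(x$tip.label)
  if (inherits(x, "hclust")) return(x$labels)
  labels(x)
}

#' Entanglement of two dendrograms
#'
#' After an alternating two-sided untangling pass (each side's nodes are
#' rotated to sort its leaves by the other side's current leaf ranks),
#' entanglement is `sum |rank_a - rank_b|^L / worst`, where the worst case
#' is a leaf order against its reverse and `L = 1.5`; 0 means a perfectly
#' aligned tanglegram, values near 1 a maximally crossed one.
#'
#' @param a,b `hclust` / `dendrogram` / ultrametric `phylo` objects with
#'   identical label sets.
#' @param L exponent of the rank-difference norm.
#' @param untangle run the alternating rotation search (default) or score
#'   the current leaf orders as-is.
#' @param max_pass maximum alternation passes.
#' @return entanglement in `[0, 1]`, with attribute `leaf_orders` (the
#'   untangled orders of both sides).
#' @export
entanglement <- function(a, b, L = 1.5, untangle = TRUE, max_pass = 10L) {
  da <- .as_dendro(a)
  db <- .as_dendro(b)
  la <- labels(da); lb <- labels(db)
  if (!setequal(la, lb)) {
    stop("label sets differ: only in first {",
         paste(setdiff(la, lb), collapse = ","), "}, only in second {",
         paste(setdiff(lb, la), collapse = ","), "}")
  }
  score <- function(da, db) {
    la <- labels(da); lb <- labels(db)
    n <- length(la)
    ra <- seq_len(n)
    rb <- match(la, lb)
    worst <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
    if (worst == 0) return(0)
    sum(abs(ra - rb)^L) / worst
  }
  if (untangle) {
    best <- score(da, db)
    for (pass in seq_len(max_pass)) {
      improved <- FALSE
      da2 <- .reorder_by_target(da, labels(db))
      if (score(da2, db) < best - 1e-12) {
        da <- da2; best <- score(da, db); improved <- TRUE
      }
      db2 <- .reorder_by_target(db, labels(da))
      if (score(da, db2) < best - 1e-12) {
        db <- db2; best <- score(da, db); improved <- TRUE
      }
      if (!improved) break
    }
  }
  out <- score(da, db)
  attr(out, "leaf_orders") <- list(a = labels(da), b = labels(db))
  out
}

.as_dendro <- function(x) {
  if (inherits(x, "phylo")) x <- .phylo_as_hclust(x)
  if (inherits(x, "hclust")) x <- as.dendrogram(x)
  stopifnot(inherits(x, "dendrogram"))
  x
}

# Rotate a dendrogram's nodes so leaves sort (by subtree mean rank) toward
# a target label order.  reorder.dendrogram indexes its weights by the
# leaf's original observation index, so map display labels back first.
.reorder_by_target <- function(dend, target_labels) {
  ord <- order.dendrogram(dend)
  labs <- labels(dend)
  orig_labels <- character(length(ord))
  orig_labels[ord] <- labs
  wts <- match(orig_labels, target_labels)
  reorder(dend, wts = wts, agglo.FUN = mean)
}
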