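# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths (C++ kernels, DP recursions).

# all 4^9 state digit matrix (1..4), rows in lexicographic sequence order
state_digits <- function() {
  n <- 4^9
  s <- 0:(n - 1)
  d <- matrix(0L, n, 9)
  tmp <- s
  for (i in 9:1) {
    d[, i] <- tmp %% 4L + 1L
    tmp <- tmp %/% 4L
  }
  d
}

# vectorized base-R energy of every state: term-by-term summation
r_all_state_energies <- function(model) {
  d <- state_digits()
  e <- numeric(nrow(d))
  for (i in 1:9) e <- e - model$h[cbind(i, d[, i])]
  pt <- splicepotts:::.pair_table
  for (k in 1:36) {
    a <- d[, pt$i[k]]
    b <- d[, pt$j[k]]
    e <- e - model$J[cbind(k, (a - 1L) * 4L + b)]
  }
  e
}

# brute-force Sankoff: minimize total edge cost over all 2^Nnode internal
# assignments (binary states, small trees only)
brute_sankoff <- function(tree, states, cost = matrix(c(0, 1, 1, 0), 2)) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  stopifnot(nnode <= 12)
  tip_state <- as.integer(states[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(nnode)]
    node_state <- c(tip_state, internal)
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- node_state[tree$edge[e, 1]]
      c_ <- node_state[tree$edge[e, 2]]
      tot <- tot + cost[p + 1, c_ + 1]
    }
    if (tot < best) best <- tot
  }
  best
}

# independent Fitch change-count for binary characters (set-based DP);
# valid on bifurcating trees
fitch_count <- function(tree, states) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- states[tree$tip.label[i]]
  changes <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (node in unique(po$edge[, 1])) {
    ch <- kids[[as.character(node)]]
    inter <- Reduce(intersect, sets[ch])
    if (length(inter)) {
      sets[[node]] <- inter
    } else {
      sets[[node]] <- Reduce(union, sets[ch])
      changes <- changes + length(ch) - 1
    }
  }
  changes
}

# a small fitted model cache so several test files can share one fit
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, maker) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- maker()
  .fit_cache[[key]]
}
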