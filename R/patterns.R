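#' Classify the 36 site-base combinations
#'
#' Each (position, letter) combination is labelled exonic (positions
#' -3..-1) or intronic (+1..+6) and consensus or non-consensus (relative to
#' the consensus sequence of `m`).
#'
#' @param m a `marginal_set` (empirical or model-derived).
#' @return a data.frame of 36 rows: `position`, `letter`, `region`
#'   (`"exon"`/`"intron"`), `status` (`"consensus"`/`"non-consensus"`),
#'   `category` (`"EC"`, `"EN"`, `"IC"`, `"IN"`), `freq`.
#' @export
classify_site_bases <- function(m) {
  .validate_marginal_set(m)
  cons <- strsplit(consensus_sequence(m), "")[[1]]
  grid <- expand.grid(letter = DONOR_LETTERS, position = DONOR_POSITIONS,
                      stringsAsFactors = FALSE)[, c("position", "letter")]
  pos_index <- match(grid$position, DONOR_POSITIONS)
  region <- ifelse(pos_index <= 3, "exon", "intron")
  status <- ifelse(grid$letter == cons[pos_index],
                   "consensus", "non-consensus")
  category <- paste0(ifelse(region == "exon", "E", "I"),
                     ifelse(status == "consensus", "C", "N"))
  data.frame(position = grid$position, letter = grid$letter,
             region = region, status = status, category = category,
             freq = m$f1[cbind(pos_index, match(grid$letter, DONOR_LETTERS))],
             stringsAsFactors = FALSE)
}

# canonical unordered category-pair label, EC < EN < IC < IN
.category_pair <- function(a, b) {
  lv <- c("EC", "EN", "IC", "IN")
  swap <- match(a, lv) > match(b, lv)
  paste0(ifelse(swap, b, a), "-", ifelse(swap, a, b))
}

#' Mean coupling strength per site-base category pair
#'
#' Averages the couplings `J_ij(s,t)` over all cells whose two site-base
#' endpoints fall in a given pair of categories (exonic/intronic x
#' consensus/non-consensus).  By default structural zeros (couplings shrunk
#' away by the L1 penalty) are included in the mean; `nonzero_only = TRUE`
#' averages over nonzero contributors instead.
#'
#' @param model a `potts_model`.
#' @param classes output of [classify_site_bases()] sharing the model's
#'   conventions.
#' @param nonzero_only average over nonzero couplings only.
#' @return data.frame with one row per category pair: `pair`, `mean_J`,
#'   `n_cells`, `n_nonzero`.
#' @export
group_mean_couplings <- function(model, classes, nonzero_only = FALSE) {
  stopifnot(inherits(model, "potts_model"),
            is.data.frame(classes), nrow(classes) == 36)
  cat_of <- matrix(classes$category,
                   nrow = 4, ncol = 9,
                   dimnames = list(DONOR_LETTERS, DONOR_POSITIONS))
  # category of each J cell's two endpoints
  k <- rep(seq_len(36), each = 16)
  cell <- rep(seq_len(16), times = 36)
  a <- (cell - 1L) %/% 4L + 1L
  b <- (cell - 1L) %% 4L + 1L
  cat_i <- cat_of[cbind(a, .pair_table$i[k])]
  cat_j <- cat_of[cbind(b, .pair_table$j[k])]
  pair_cat <- .category_pair(cat_i, cat_j)
  vals <- as.vector(t(model$J)) # row-major: pair k block of 16 cells
  lv <- c("EC", "EN", "IC", "IN")
  all_pairs <- c()
  for (x in seq_along(lv)) for (y in x:length(lv)) {
    all_pairs <- c(all_pairs, paste0(lv[x], "-", lv[y]))
  }
  out <- do.call(rbind, lapply(all_pairs, function(pc) {
    sel <- pair_cat == pc
    v <- vals[sel]
    data.frame(pair = pc,
               mean_J = if (nonzero_only) {
                 if (any(v != 0)) mean(v[v != 0]) else 0
               } else if (length(v)) mean(v) else NA_real_,
               n_cells = sum(sel),
               n_nonzero = sum(v != 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export coupling structure for circos-style plotting
#'
#' Writes `<prefix>_nodes.tsv` (the 36 site-base boxes with their observed
#' frequencies and categories) and `<prefix>_edges.tsv` (the exactly
#' nonzero couplings with sign and magnitude), consumable by any plotting
#' tool.
#'
#' @param model a `potts_model`.
#' @param m the `marginal_set` the model was fitted to.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
export_couplings <- function(model, m, prefix) {
  nodes <- classify_site_bases(m)
  nodes$site_base <- paste0(nodes$position, nodes$letter)
  edges <- active_couplings(model)
  edges$sign <- ifelse(edges$value >= 0, "positive", "negative")
  edges$magnitude <- abs(edges$value)
  pn <- paste0(prefix, "_nodes.tsv")
  pe <- paste0(prefix, "_edges.tsv")
  ok <- tryCatch({
    write.table(nodes, pn, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(edges, pe, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write coupling export: ",
                        conditionMessage(ok))
  invisible(c(pn, pe))
}
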