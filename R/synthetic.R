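#' Ground-truth random sparse Potts model
#'
#' Fields are i.i.d. normal (zero-sum shifted per position); a random set
#' of coupling cells is planted at magnitude `coupling_scale` with random
#' signs.  Pure function of its seed and parameters.
#'
#' @param seed integer seed.
#' @param n_couplings number of nonzero coupling cells (<= 576).
#' @param field_scale standard deviation of the fields.
#' @param coupling_scale absolute value of planted couplings.
#' @return a `potts_model` with attribute `planted` (the active-coupling
#'   data.frame of the truth).
#' @export
make_random_potts <- function(seed, n_couplings = 10, field_scale = 0.5,
                              coupling_scale = 0.5) {
  stopifnot(n_couplings >= 0, n_couplings <= 576)
  .with_seed(seed, {
    h <- matrix(rnorm(36, 0, field_scale), 9, 4)
    h <- h - rowMeans(h)
    J <- matrix(0, 36, 16)
    if (n_couplings > 0) {
      cells <- sample.int(576, n_couplings)
      J[cells] <- coupling_scale * sample(c(-1, 1), n_couplings,
                                          replace = TRUE)
    }
    mo <- potts_model(h, J, gauge_tag = "zero-sum-h")
    attr(mo, "planted") <- active_couplings(mo)
    mo
  })
}

# random background bases
.random_bases <- function(n) {
  paste(sample(DONOR_LETTERS, n, replace = TRUE), collapse = "")
}

#' Toy genome with planted donor sites
#'
#' Builds one gene per donor 9-mer: two exons separated by an intron whose
#' junction spells exactly the given sequence (last 3 exonic + first 6
#' intronic bases), with random background elsewhere and the intron closed
#' by a canonical AG.  Roughly half the genes are placed on the minus
#' strand (the gene block is reverse-complemented in the contig; the
#' annotation marks strand `-`), so extraction must reverse-complement to
#' recover the planted sequences.  No ambiguous bases are emitted.
#'
#' @param ensemble a [donor_ensemble()] of sequences to plant.
#' @param seed integer seed.
#' @param intergenic_length bases of random background between genes.
#' @param genes_per_contig genes placed on each contig.
#' @return list with `genome` (named character vector of contigs),
#'   `annotation` (GFF3-style exon table: data.frame with seqid, start,
#'   end, strand, transcript), and `truth` (the planted ensemble).
#'   Use [write_genome()] and [write_gff3()] to materialize files.
#' @export
make_planted_genome <- function(ensemble, seed, intergenic_length = 50,
                                genes_per_contig = 100) {
  stopifnot(inherits(ensemble, "donor_ensemble"), length(ensemble) > 0)
  .with_seed(seed, {
    n <- length(ensemble)
    contig_of <- rep(seq_len(ceiling(n / genes_per_contig)),
                     each = genes_per_contig)[seq_len(n)]
    minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
    contigs <- character(max(contig_of))
    ann <- vector("list", n)
    for (ci in seq_len(max(contig_of))) {
      parts <- character(0)
      cursor <- 0L
      for (g in which(contig_of == ci)) {
        s <- ensemble$sequences[g]
        exon1_extra <- sample(12:30, 1)
        intron_fill <- sample(20:40, 1)
        exon2_len <- sample(15:30, 1)
        exon1 <- paste0(.random_bases(exon1_extra), substr(s, 1, 3))
        intron <- paste0(substr(s, 4, 9), .random_bases(intron_fill), "AG")
        exon2 <- .random_bases(exon2_len)
        gene <- paste0(exon1, intron, exon2)
        glen <- nchar(gene)
        e1 <- nchar(exon1)
        il <- nchar(intron)
        # transcript-oriented exon coordinates within the gene block
        ex_start <- c(1L, e1 + il + 1L)
        ex_end <- c(e1, glen)
        gap <- .random_bases(intergenic_length)
        offset <- cursor + nchar(gap)
        if (minus[g]) {
          gene <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(gene)))
          # flip coordinates within the block
          new_start <- glen - ex_end + 1L
          new_end <- glen - ex_start + 1L
          ex_start <- sort(new_start)
          ex_end <- sort(new_end)
        }
        ann[[g]] <- data.frame(
          seqid = paste0("contig", ci),
          start = offset + ex_start,
          end = offset + ex_end,
          strand = if (minus[g]) "-" else "+",
          transcript = paste0("tx", g),
          stringsAsFactors = FALSE)
        parts <- c(parts, gap, gene)
        cursor <- offset + glen
      }
      parts <- c(parts, .random_bases(intergenic_length))
      contigs[ci] <- paste(parts, collapse = "")
    }
    names(contigs) <- paste0("contig", seq_along(contigs))
    list(genome = contigs,
         annotation = do.call(rbind, ann),
         truth = ensemble)
  })
}

#' Write an exon table as GFF3
#'
#' Emits gene, mRNA and exon features with `ID`/`Parent` linkage from the
#' flat exon table produced by [make_planted_genome()].
#'
#' @param annotation data.frame with columns seqid, start, end, strand,
#'   transcript.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(all(c("seqid", "start", "end", "strand", "transcript") %in%
                  names(annotation)))
  lines <- "##gff-version 3"
  for (tx in unique(annotation$transcript)) {
    ex <- annotation[annotation$transcript == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    gene_id <- paste0("gene_", tx)
    lines <- c(lines,
      sprintf("%s\tsplicepotts\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              ex$seqid[1], min(ex$start), max(ex$end), ex$strand[1], gene_id),
      sprintf("%s\tsplicepotts\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              ex$seqid[1], min(ex$start), max(ex$end), ex$strand[1], tx,
              gene_id),
      sprintf("%s\tsplicepotts\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              ex$seqid, ex$start, ex$end, ex$strand, tx,
              seq_len(nrow(ex)), tx))
  }
  writeLines(lines, path)
  invisible(path)
}

# Default field template: preference for the U1-complementary CAGGTAAGT
# consensus, with A and G co-dominant at +3 (as in real donor ensembles,
# where +3 is the least conserved intronic position).  Moderate strength
# keeps non-consensus letters frequent enough that planted couplings leave
# a detectable two-site footprint: a coupling J perturbs the pair marginal
# by roughly J * p(1-p) * q(1-q), which must clear the L1 level gamma.
.default_field_template <- function(strength = 1.2) {
  cons <- strsplit("CAGGTAAGT", "")[[1]]
  h <- matrix(0, 9, 4)
  h[cbind(seq_len(9), match(cons, DONOR_LETTERS))] <- strength
  h[6, ] <- c(0.8, 0, 0.8, 0) # +3: A and G co-dominant
  h - rowMeans(h)
}

# coupling list entry: list(pos_i, pos_j, letter_i, letter_j, value)
.apply_couplings <- function(J, couplings) {
  for (cp in couplings) {
    i <- match(cp[[1]], DONOR_POSITIONS)
    j <- match(cp[[2]], DONOR_POSITIONS)
    a <- match(cp[[3]], DONOR_LETTERS)
    b <- match(cp[[4]], DONOR_LETTERS)
    stopifnot(!is.na(i), !is.na(j), i != j, !is.na(a), !is.na(b))
    if (i > j) { tmp <- i; i <- j; j <- tmp; tmp <- a; a <- b; b <- tmp }
    k <- which(.pair_table$i == i & .pair_table$j == j)
    J[k, (a - 1L) * 4L + b] <- cp[[5]]
  }
  J
}

#' Default group-specific coupling design
#'
#' Three groups carrying the lineage-style signatures seen across
#' eukaryotic donor sites: a `-1G:+6T` destabilizing coupling
#' (animal/fungus-like), a `-1G:+5G` destabilizing coupling (plant-like),
#' and a `+3G:+5G` stabilizing coupling (metazoan-like).
#'
#' @return list of per-group coupling lists.
#' @export
default_group_couplings <- function() {
  list(
    g1 = list(list("-1", "+6", "G", "T", -0.8)),
    g2 = list(list("-1", "+5", "G", "G", -0.8)),
    g3 = list(list("+3", "+5", "G", "G", 0.8)))
}

#' Default backbone (shared) couplings
#'
#' Conserved-style interactions present in every species of a panel:
#' stabilizing consensus couplings within the exonic and intronic parts
#' plus a destabilizing cross-boundary interaction.
#'
#' @return list of couplings.
#' @export
default_backbone_couplings <- function() {
  list(
    list("-2", "-1", "A", "G", 0.6),
    list("+5", "+6", "G", "T", 0.6),
    list("-2", "+5", "A", "G", -0.5))
}

#' Synthetic multi-species donor panel
#'
#' Emulates a panel of related species in `n_groups` lineages: every
#' species shares a consensus-favoring field template and a set of
#' backbone couplings; each group adds its own group-specific couplings;
#' species-level normal jitter on the fields makes within-group models
#' distinct.  Ensembles are sampled exactly from each species' model, and
#' the generating group tree is returned (ultrametric, species of a group
#' in one clade).
#'
#' @param n_groups number of groups (default 3).
#' @param species_per_group species per group (default 4).
#' @param n_sequences sequences sampled per species (default 50000).
#' @param backbone_couplings list of couplings shared by all species.
#' @param group_couplings list (length `n_groups`) of per-group coupling
#'   lists.
#' @param field_template 9 x 4 field matrix shared by all species.
#' @param jitter_sd sd of the species-level normal jitter on fields.
#' @param seed integer seed.
#' @return list with `ensembles` (named list of `donor_ensemble`s),
#'   `truth_models` (named list of `potts_model`s), `groups` (named group
#'   vector), `tree` (`ape::phylo` group tree), `group_tree_newick`.
#' @export
make_species_panel <- function(n_groups = 3, species_per_group = 4,
                               n_sequences = 50000,
                               backbone_couplings =
                                 default_backbone_couplings(),
                               group_couplings = default_group_couplings(),
                               field_template =
                                 .default_field_template(),
                               jitter_sd = 0.05, seed = 1) {
  stopifnot(length(group_couplings) >= n_groups, species_per_group >= 1)
  .with_seed(seed, {
    species <- character(0)
    groups <- character(0)
    truth <- list()
    ensembles <- list()
    for (g in seq_len(n_groups)) {
      Jg <- .apply_couplings(matrix(0, 36, 16), backbone_couplings)
      Jg <- .apply_couplings(Jg, group_couplings[[g]])
      for (s in seq_len(species_per_group)) {
        sp <- sprintf("g%d_s%d", g, s)
        h <- field_template + matrix(rnorm(36, 0, jitter_sd), 9, 4)
        h <- h - rowMeans(h)
        mo <- potts_model(h, Jg, gauge_tag = "zero-sum-h")
        truth[[sp]] <- mo
        ensembles[[sp]] <- sample_sequences(mo, n_sequences, species = sp)
        species <- c(species, sp)
        groups <- c(groups, paste0("g", g))
      }
    }
    names(groups) <- species
    # ultrametric group tree: within-group caterpillar distances,
    # large across-group separation; complete linkage renders it exactly
    if (length(species) >= 2) {
      dm <- matrix(6, length(species), length(species),
                   dimnames = list(species, species))
      for (g in unique(groups)) {
        idx <- which(groups == g)
        for (x in seq_along(idx)) for (y in seq_along(idx)) {
          dm[idx[x], idx[y]] <- 2 * abs(x - y) / max(1, species_per_group)
        }
      }
      diag(dm) <- 0
      tree <- ape::as.phylo(complete_linkage(dm))
      newick <- ape::write.tree(tree)
    } else {
      tree <- NULL
      newick <- NA_character_
    }
    list(ensembles = ensembles, truth_models = truth, groups = groups,
         tree = tree, group_tree_newick = newick)
  })
}

#' Binary trait on a tree, clustered or random
#'
#' `clustered`: presence is assigned to the tips of the clade whose size
#' is closest to `n_present` (deterministic given the seed; a warning is
#' issued if no clade of the exact size exists).  `random`: presence is
#' assigned to a uniform random subset of `n_present` tips.
#'
#' @param tree an `ape::phylo` tree.
#' @param mode `"clustered"` or `"random"`.
#' @param n_present number of present tips (1 <= n_present <= n_tips - 1).
#' @param seed optional integer.
#' @return named 0/1 vector over the tree's tips.
#' @export
make_trait_on_tree <- function(tree, mode = c("clustered", "random"),
                               n_present, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  stopifnot(n_present >= 1, n_present <= ntip - 1)
  .with_seed(seed, {
    states <- setNames(integer(ntip), tree$tip.label)
    if (mode == "random") {
      states[sample.int(ntip, n_present)] <- 1L
    } else {
      clades <- ape::prop.part(tree)
      sizes <- lengths(clades)
      ok <- which(sizes <= ntip - 1)
      gap <- abs(sizes[ok] - n_present)
      cands <- ok[gap == min(gap)]
      if (min(gap) > 0) {
        warning("no clade of size ", n_present, "; using nearest size ",
                sizes[cands[1]], call. = FALSE)
      }
      pick <- if (length(cands) > 1) cands[sample.int(length(cands), 1)]
              else cands[1]
      states[clades[[pick]]] <- 1L
    }
    states
  })
}
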