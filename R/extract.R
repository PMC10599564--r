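#' Read genome sequences from a FASTA file
#'
#' Residues are uppercased on read and U is mapped to T; the resulting
#' alphabet is restricted to A/C/G/T/N.
#'
#' @param path path to a (multi-record, possibly wrapped) FASTA file.
#' @return a [Biostrings::DNAStringSet] with one entry per FASTA record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (!length(recs)) stop("empty FASTA file: ", path)
  chars <- toupper(as.character(recs))
  chars <- chartr("U", "T", chars)
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("FASTA record '", names(recs)[which(bad)[1]],
         "' contains letters outside {A,C,G,T,N,U}")
  }
  if (any(!nzchar(chars))) {
    stop("FASTA record '", names(recs)[which(!nzchar(chars))[1]], "' is empty")
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- sub("\\s.*$", "", names(recs)) # first token = sequence id
  out
}

#' Write genome sequences to FASTA
#'
#' @param genome a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

# exon table (seqid, start, end, strand, transcript) from a GFF3/GTF file
.read_exon_table <- function(annotation) {
  if (!file.exists(annotation)) stop("no such file: ", annotation)
  gr <- rtracklayer::import(annotation)
  md <- S4Vectors::mcols(gr)
  keep <- !is.na(md$type) & tolower(as.character(md$type)) == "exon"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (!length(gr)) stop("annotation contains no exon features: ", annotation)
  if ("Parent" %in% names(md) && any(lengths(md$Parent) > 0)) {
    # GFF3: exons may list several parent transcripts; expand
    parents <- md$Parent
    reps <- lengths(parents)
    gr <- gr[rep(seq_along(gr), reps)]
    tx <- unlist(parents, use.names = FALSE)
  } else if ("transcript_id" %in% names(md)) {
    tx <- as.character(md$transcript_id)
  } else {
    stop("exon features carry neither Parent nor transcript_id attributes")
  }
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript = tx,
    id = if ("ID" %in% names(S4Vectors::mcols(gr)) &&
             !all(is.na(S4Vectors::mcols(gr)$ID)))
      as.character(S4Vectors::mcols(gr)$ID) else paste0("exon", seq_along(gr)),
    stringsAsFactors = FALSE
  )
}

#' Extract the 9-nt donor ensemble from a genome and its annotation
#'
#' For every intron (the gap between consecutive exons of a transcript, in
#' transcript order) the donor 9-mer is read off as the last 3 exonic plus
#' the first 6 intronic bases in 5'-to-3' transcript orientation;
#' minus-strand donors are reverse-complemented.
#'
#' @param genome a `DNAStringSet` from [read_genome()], or a FASTA path.
#' @param annotation path to a GFF3 or GTF file (1-based inclusive
#'   coordinates; exon features linked to transcripts via `Parent` or
#'   `transcript_id`).  Non-exon features are ignored.
#' @param dedupe if `TRUE` (default) one donor per unique genomic site
#'   (sequence id, donor position, strand), however many transcript isoforms
#'   share it.
#' @param drop_ambiguous if `TRUE` (default) windows containing N or
#'   truncated by a contig edge are dropped (with a logged count); if
#'   `FALSE`, an N-containing window is an error.
#' @param species optional species label for the resulting ensemble.
#' @return a [donor_ensemble()]; attributes `n_dropped_edge` and
#'   `n_dropped_ambiguous` record discarded windows.
#' @export
extract_donor_sites <- function(genome, annotation, dedupe = TRUE,
                                drop_ambiguous = TRUE,
                                species = NA_character_) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  stopifnot(inherits(genome, "DNAStringSet"))
  contigs <- as.character(genome)
  exons <- .read_exon_table(annotation)

  missing_contig <- !(exons$seqid %in% names(contigs))
  if (any(missing_contig)) {
    stop("exon '", exons$id[which(missing_contig)[1]],
         "' lies on unknown sequence '",
         exons$seqid[which(missing_contig)[1]], "'")
  }
  clen <- nchar(contigs)[exons$seqid]
  oob <- exons$start < 1L | exons$end > clen | exons$start > exons$end
  if (any(oob)) {
    k <- which(oob)[1]
    stop("exon '", exons$id[k], "' (", exons$seqid[k], ":", exons$start[k],
         "-", exons$end[k], ") exceeds contig bounds")
  }

  sites <- list()
  for (tx in split(exons, exons$transcript)) {
    if (nrow(tx) < 2L) next
    if (length(unique(tx$strand)) != 1L || length(unique(tx$seqid)) != 1L) {
      stop("transcript '", tx$transcript[1],
           "' mixes strands or sequences")
    }
    tx <- tx[order(tx$start), ]
    gs <- tx$end[-nrow(tx)] + 1L   # first gap base
    ge <- tx$start[-1L] - 1L       # last gap base
    real <- ge >= gs               # overlapping/adjacent exons: no intron
    if (!any(real)) next
    gs <- gs[real]; ge <- ge[real]
    if (tx$strand[1] == "+") {
      sites[[length(sites) + 1L]] <- data.frame(
        seqid = tx$seqid[1], pos = gs, strand = "+",
        w_start = gs - 3L, w_end = gs + 5L, stringsAsFactors = FALSE)
    } else {
      sites[[length(sites) + 1L]] <- data.frame(
        seqid = tx$seqid[1], pos = ge, strand = "-",
        w_start = ge - 5L, w_end = ge + 3L, stringsAsFactors = FALSE)
    }
  }
  n_edge <- 0L
  n_amb <- 0L
  if (!length(sites)) {
    out <- donor_ensemble(character(0), species = species,
                          origin = annotation)
  } else {
    sites <- do.call(rbind, sites)
    if (dedupe) {
      sites <- sites[!duplicated(sites[c("seqid", "pos", "strand")]), ]
    }
    inb <- sites$w_start >= 1L & sites$w_end <= nchar(contigs)[sites$seqid]
    n_edge <- sum(!inb)
    if (n_edge > 0L && !drop_ambiguous) {
      stop(n_edge, " donor window(s) cross a contig edge; ",
           "set drop_ambiguous = TRUE to drop them")
    }
    sites <- sites[inb, , drop = FALSE]
    seqs <- substr(rep(contigs[sites$seqid], 1L), sites$w_start, sites$w_end)
    minus <- sites$strand == "-"
    if (any(minus)) {
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    }
    amb <- grepl("[^ACGT]", seqs)
    n_amb <- sum(amb)
    if (n_amb > 0L && !drop_ambiguous) {
      stop(n_amb, " donor window(s) contain ambiguous bases; ",
           "set drop_ambiguous = TRUE to drop them")
    }
    seqs <- seqs[!amb]
    out <- donor_ensemble(unname(seqs), species = species,
                          origin = annotation)
  }
  if (n_edge + n_amb > 0L) {
    message("extract_donor_sites: dropped ", n_edge, " contig-edge and ",
            n_amb, " ambiguous window(s)")
  }
  attr(out, "n_dropped_edge") <- n_edge
  attr(out, "n_dropped_ambiguous") <- n_amb
  out
}
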