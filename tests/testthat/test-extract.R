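toy_plus_gene <- function() {
  # exon1 = 1..20, exon2 = 31..50; positions 18..26 spell CAGGTAAGT
  contig <- paste0(strrep("A", 17), "CAGGTAAGT", strrep("C", 24))
  list(genome = Biostrings::DNAStringSet(c(chr1 = contig)),
       ann = data.frame(seqid = "chr1", start = c(1L, 31L),
                        end = c(20L, 50L), strand = "+",
                        transcript = "t1", stringsAsFactors = FALSE))
}

test_that("FASTA reading normalizes case and U, round-trips wrapping", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 first contig", "acgtacgtu", ">s2", "GGGG", "CCCC"), path)
  g <- read_genome(path)
  expect_equal(length(g), 2L)
  expect_equal(as.character(g[["s1"]]), "ACGTACGTT")
  expect_equal(as.character(g[["s2"]]), "GGGGCCCC") # wrapped lines joined
  # byte-identical write/read round trip of a planted toy genome
  pg <- make_planted_genome(sample_random_sequences(20, seed = 5), seed = 6)
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(pg$genome, p2)
  back <- read_genome(p2)
  expect_identical(as.character(back), pg$genome)
  writeLines(character(0), path)
  expect_error(read_genome(path), "empty")
})

test_that("plus-strand donor is read off directly", {
  toy <- toy_plus_gene()
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(toy$ann, gff)
  ens <- extract_donor_sites(toy$genome, gff)
  expect_equal(ens$sequences, "CAGGTAAGT")
})

test_that("minus-strand donor equals the reverse-complement construction", {
  toy <- toy_plus_gene()
  # independently reverse-complement the contig and remap coordinates
  contig <- as.character(toy$genome[[1]])
  L <- nchar(contig)
  rc <- as.character(Biostrings::reverseComplement(toy$genome[[1]]))
  ann_rc <- data.frame(seqid = "chr1",
                       start = L - toy$ann$end + 1L,
                       end = L - toy$ann$start + 1L,
                       strand = "-", transcript = "t1",
                       stringsAsFactors = FALSE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann_rc, gff)
  ens <- extract_donor_sites(Biostrings::DNAStringSet(c(chr1 = rc)), gff)
  expect_equal(ens$sequences, "CAGGTAAGT")
})

test_that("planted genomes return the exact planted multiset, both strands", {
  planted <- sample_random_sequences(500, seed = 11)
  pg <- make_planted_genome(planted, seed = 12)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(pg$genome, fa)
  write_gff3(pg$annotation, gff)
  ens <- extract_donor_sites(read_genome(fa), gff, dedupe = FALSE)
  expect_equal(sort(ens$sequences), sort(planted$sequences))
  # both strands actually exercised
  expect_setequal(unique(pg$annotation$strand), c("+", "-"))
  # drop_ambiguous is a no-op on planted genomes (no N emitted)
  ens2 <- extract_donor_sites(read_genome(fa), gff, dedupe = FALSE,
                              drop_ambiguous = FALSE)
  expect_equal(sort(ens2$sequences), sort(planted$sequences))
})

test_that("strand symmetry: extraction from the reverse-complement genome", {
  planted <- sample_random_sequences(60, seed = 21)
  pg <- make_planted_genome(planted, seed = 22)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(pg$annotation, gff)
  fwd <- extract_donor_sites(Biostrings::DNAStringSet(pg$genome), gff,
                             dedupe = FALSE)
  # reverse-complement every contig, remap all exon coordinates and flip
  # strands: the extracted ensemble must be identical
  g2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(pg$genome))
  names(g2) <- names(pg$genome)
  L <- setNames(nchar(pg$genome), names(pg$genome))[pg$annotation$seqid]
  ann2 <- pg$annotation
  ann2$start <- L - pg$annotation$end + 1L
  ann2$end <- L - pg$annotation$start + 1L
  ann2$strand <- ifelse(pg$annotation$strand == "+", "-", "+")
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann2, gff2)
  rev <- extract_donor_sites(g2, gff2, dedupe = FALSE)
  expect_equal(sort(fwd$sequences), sort(rev$sequences))
})

test_that("dedupe collapses isoform-shared donors and is idempotent", {
  toy <- toy_plus_gene()
  ann <- rbind(toy$ann,
               transform(toy$ann, transcript = "t2")) # same exons, 2nd isoform
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, gff)
  deduped <- extract_donor_sites(toy$genome, gff, dedupe = TRUE)
  expect_equal(length(deduped), 1L)
  kept <- extract_donor_sites(toy$genome, gff, dedupe = FALSE)
  expect_equal(length(kept), 2L)
})

test_that("extraction errors and edge cases behave per contract", {
  toy <- toy_plus_gene()
  gff <- withr::local_tempfile(fileext = ".gff3")
  # exon beyond contig bounds names the feature
  bad <- toy$ann
  bad$end[2] <- 2000L
  write_gff3(bad, gff)
  expect_error(extract_donor_sites(toy$genome, gff), "contig bounds")
  # single-exon transcript contributes nothing (not an error)
  write_gff3(toy$ann[1, ], gff)
  expect_equal(length(extract_donor_sites(toy$genome, gff)), 0L)
  # N in the donor window is dropped with a message
  contigN <- paste0(strrep("A", 17), "CAGGTANGT", strrep("C", 24))
  gN <- Biostrings::DNAStringSet(c(chr1 = contigN))
  write_gff3(toy$ann, gff)
  expect_message(ensN <- extract_donor_sites(gN, gff), "ambiguous")
  expect_equal(length(ensN), 0L)
  expect_error(extract_donor_sites(gN, gff, drop_ambiguous = FALSE),
               "ambiguous")
})

test_that("GTF input with transcript_id linkage is accepted", {
  toy <- toy_plus_gene()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(sprintf(
    "chr1\ttoy\texon\t%d\t%d\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
    toy$ann$start, toy$ann$end), gtf)
  ens <- extract_donor_sites(toy$genome, gtf)
  expect_equal(ens$sequences, "CAGGTAAGT")
})
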