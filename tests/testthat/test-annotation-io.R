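test_that("FASTA records are parsed, concatenated and uppercased", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr2 some description", "acg", "tac"),
             fa)
  g <- load_genome(fa)
  expect_equal(g$chromosomes$chr1, "ACGT")
  expect_equal(g$chromosomes$chr2, "ACGTAC")
  expect_equal(genome_slice(g, "chr1", 0, 4), "ACGT")
  expect_equal(genome_slice(g, "chr2", 2, 5), "GTA")
  expect_error(genome_slice(g, "chr1", 0, 5), "out of bounds")
  expect_error(genome_slice(g, "chrZ", 0, 1), "unknown chromosome")
})

test_that("duplicate record names and bad characters are rejected", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrX", "ACGT", ">chrX", "TTTT"), fa)
  expect_error(load_genome(fa), "duplicate.*chrX")
  # ambiguity codes other than N are normalised to N
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">c", "ACGRYT"), fa2)
  g <- load_genome(fa2)
  expect_equal(g$chromosomes$c, "ACGNNT")
})

test_that("a plus-strand toy gene resolves stop codon and 3'UTR", {
  # exon 1-100, CDS 11-40 (1-based, stop codon TAA at 38-40)
  seq <- paste0(strrep("A", 10), strrep("CAT", 9), "TAA", strrep("T", 60))
  fa <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = seq))
  gtf <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 1, 100, "+", "tx1"),
    gtf_row("chr1", "CDS", 11, 40, "+", "tx1")))
  cat <- load_annotation(gtf, load_genome(fa))
  m <- cat$tx1
  expect_s3_class(m, "transcript_model")
  expect_equal(unname(m$stop_codon), c(37, 40))
  expect_equal(m$stop_tx, 37)                 # single exon from position 0
  expect_equal(nchar(m$tx_seq) - m$cds_end_tx, 60)  # 3'UTR
  expect_equal(substr(m$tx_seq, m$stop_tx + 1, m$stop_tx + 3), "TAA")
})

test_that("a minus-strand toy gene places the stop at the transcript end", {
  # transcript-orientation gene: 30 nt CDS ending TAA + 60 nt UTR, placed
  # as the reverse complement on the chromosome (exon 1-100, CDS 61-90)
  tx <- paste0(strrep("CAT", 9), "TAA", strrep("T", 60))
  chrom <- paste0(strrep("G", 10), rc_oracle(tx))
  fa <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = chrom))
  gtf <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 11, 100, "-", "txm"),
    gtf_row("chr1", "CDS", 71, 100, "-", "txm")))
  cat <- load_annotation(gtf, load_genome(fa))
  m <- cat$txm
  expect_equal(substr(m$tx_seq, m$stop_tx + 1, m$stop_tx + 3), "TAA")
  # stop codon genomically at the low end of the CDS
  expect_equal(unname(m$stop_codon), c(70, 73))
  # 3'UTR is genomically upstream of the CDS
  expect_equal(nchar(m$tx_seq) - m$cds_end_tx, 60)
})

test_that("transcripts with no 3'UTR or broken frame are skipped", {
  seq <- paste0(strrep("A", 10), strrep("CAT", 9), "TAA")
  fa <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = seq))
  gtf <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 1, 40, "+", "noutr"),
    gtf_row("chr1", "CDS", 11, 40, "+", "noutr")))
  expect_warning(cat <- load_annotation(gtf, load_genome(fa)),
                 "skipping transcript noutr")
  expect_length(cat, 0)

  seq2 <- paste0(strrep("A", 10), strrep("CAT", 9), "TAAT", strrep("T", 60))
  fa2 <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = seq2))
  gtf2 <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 1, 100, "+", "frame"),
    gtf_row("chr1", "CDS", 11, 41, "+", "frame")))  # 31 nt, no stop at end
  expect_warning(cat2 <- load_annotation(gtf2, load_genome(fa2)),
                 "skipping transcript frame")
  expect_length(cat2, 0)
})

test_that("a stop codon split across a splice junction is rejected", {
  # exon1 ends mid-stop (TA|A): stop_codon annotated as two features
  ex1 <- paste0(strrep("ACT", 10), "TA")      # CDS 1-30 + "TA"
  chrom <- paste0(ex1, strrep("G", 20), "A", strrep("T", 30))
  fa <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = chrom))
  gtf <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 1, 32, "+", "split"),
    gtf_row("chr1", "exon", 53, 83, "+", "split"),
    gtf_row("chr1", "CDS", 1, 30, "+", "split"),
    gtf_row("chr1", "stop_codon", 31, 32, "+", "split"),
    gtf_row("chr1", "stop_codon", 53, 53, "+", "split")))
  expect_warning(cat <- load_annotation(gtf, load_genome(fa)),
                 "split across a splice junction")
  expect_length(cat, 0)
})

test_that("an explicit stop_codon feature is authoritative (CDS excludes stop)", {
  seq <- paste0(strrep("A", 10), strrep("CAT", 9), "TAA", strrep("T", 60))
  fa <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = seq))
  gtf <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 1, 100, "+", "tx1"),
    gtf_row("chr1", "CDS", 11, 37, "+", "tx1"),
    gtf_row("chr1", "stop_codon", 38, 40, "+", "tx1")))
  cat <- load_annotation(gtf, load_genome(fa))
  expect_equal(unname(cat$tx1$stop_codon), c(37, 40))
  expect_equal(cat$tx1$cds_end_tx - cat$tx1$cds_start_tx, 30)
})

test_that("GFF3 annotations with Parent attributes load", {
  seq <- paste0(strrep("A", 10), strrep("CAT", 9), "TAA", strrep("T", 60))
  fa <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = seq))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=transcript:tx1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=transcript:tx1",
    "chr1\ttest\tCDS\t11\t40\t.\t+\t0\tParent=transcript:tx1"), gff)
  cat <- load_annotation(gff, load_genome(fa))
  expect_equal(unname(cat$tx1$stop_codon), c(37, 40))
})

test_that("the design window is stop-centred, truncated at transcript ends", {
  # 150 nt CDS (incl. stop) + 150 nt UTR -> 200-nt region, stop at 100
  seq <- paste0(strrep("ACT", 49), "TAA", strrep("T", 150))
  fa <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = seq))
  gtf <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 1, 297, "+", "tx1"),
    gtf_row("chr1", "CDS", 1, 150, "+", "tx1")))
  g <- load_genome(fa)
  cat <- load_annotation(gtf, g)
  r <- extract_design_region("tx1", cat, g)
  expect_equal(nchar(r$sequence), 200)
  expect_equal(r$stop_offset, 100)
  expect_equal(substr(r$sequence, 101, 103), "TAA")
  expect_true(all(r$labels[1:103] == "CDS"))
  expect_true(all(r$labels[104:200] == "UTR3"))

  # only 20 nt of UTR -> 123-nt region with a short-UTR warning
  seq2 <- paste0(strrep("ACT", 49), "TAA", strrep("T", 20))
  fa2 <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = seq2))
  gtf2 <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 1, 170, "+", "tx2"),
    gtf_row("chr1", "CDS", 1, 150, "+", "tx2")))
  g2 <- load_genome(fa2)
  cat2 <- load_annotation(gtf2, g2)
  expect_warning(r2 <- extract_design_region("tx2", cat2, g2), "short UTR")
  expect_equal(nchar(r2$sequence), 123)
  expect_equal(r2$stop_offset, 100)

  expect_error(extract_design_region("tx1", cat, g, window_nt = 10),
               "window_nt")
  expect_error(extract_design_region("nope", cat, g), "unknown transcript")
})

test_that("a window crossing a splice junction uses spliced sequence and warns", {
  # two exons; the second starts 50 nt downstream on the genome
  ex1 <- paste0(strrep("ACT", 49), "TAA", strrep("T", 10))
  ex2 <- strrep("A", 100)
  chrom <- paste0(ex1, strrep("G", 50), ex2)
  fa <- write_fasta(tempfile(fileext = ".fa"), list(chr1 = chrom))
  gtf <- write_toy_gtf(tempfile(fileext = ".gtf"), list(
    gtf_row("chr1", "exon", 1, 160, "+", "spl"),
    gtf_row("chr1", "exon", 211, 310, "+", "spl"),
    gtf_row("chr1", "CDS", 1, 150, "+", "spl")))
  g <- load_genome(fa)
  cat <- load_annotation(gtf, g)
  expect_warning(r <- extract_design_region("spl", cat, g),
                 "splice junction")
  # spliced sequence: no G (intron) bases leak into the window
  expect_false(grepl("G", r$sequence))
  expect_equal(nchar(r$sequence), 200)
})

test_that("design regions round-trip to genomic coordinates on both strands", {
  for (seed in 1:3) {
    fx <- generate_fixtures(fixture_spec(seed = seed, n_transcripts = 4),
                            dir = tempfile())
    g <- load_genome(fx$paths$fasta)
    cat <- load_annotation(fx$paths$gtf, g)
    for (id in names(cat)) {
      r <- extract_design_region(id, cat, g)
      # re-read every base from the genome via its genomic coordinate
      rebuilt <- vapply(seq_along(r$gpos), function(i) {
        b <- genome_slice(g, r$chrom, r$gpos[i], r$gpos[i] + 1L)
        if (r$strand == "-") rc_oracle(b) else b
      }, "")
      expect_equal(paste(rebuilt, collapse = ""), r$sequence)
      # the codon at stop_offset decodes to a stop
      expect_true(substr(r$sequence, r$stop_offset + 1,
                         r$stop_offset + 3) %in% c("TAA", "TAG", "TGA"))
    }
  }
})

test_that("reverse-complementing the chromosome yields the same design region", {
  dir <- tempfile()
  fx <- generate_fixtures(fixture_spec(seed = 11, n_transcripts = 2,
                                       strands = "+"), dir = dir)
  g <- load_genome(fx$paths$fasta)
  cat <- load_annotation(fx$paths$gtf, g)
  id <- names(cat)[1]
  r_plus <- extract_design_region(id, cat, g)

  # flip the chromosome and all annotations
  chrom <- cat[[id]]$chrom
  L <- nchar(g$chromosomes[[chrom]])
  g2 <- g
  g2$chromosomes[[chrom]] <- rc_oracle(g$chromosomes[[chrom]])
  flip <- function(df) data.frame(start0 = L - df$end0, end0 = L - df$start0)
  m <- cat[[id]]
  m2 <- transcript_model(id, chrom, "-", flip(m$exons), flip(m$cds),
                         genome = g2)
  cat2 <- structure(setNames(list(m2), id), class = "transcript_catalog")
  r_minus <- extract_design_region(id, cat2, g2)
  expect_equal(r_minus$sequence, r_plus$sequence)
  expect_equal(r_minus$stop_offset, r_plus$stop_offset)
  expect_equal(r_minus$labels, r_plus$labels)
})
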