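# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the package
# internals: plain string/regex scans and literal arithmetic.

rc_oracle <- function(x) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1]])), collapse = "")
}

# exhaustive regex-free hand scan of every 23-nt window on both strands
oracle_enumerate <- function(seq) {
  n <- nchar(seq)
  out <- list()
  if (n >= 23L) {
    for (s in 0:(n - 23L)) {
      win <- substr(seq, s + 1L, s + 23L)
      if (grepl("N", win, fixed = TRUE)) next
      if (substr(win, 21L, 23L) %in% paste0(c("A", "C", "G", "T"), "GG")) {
        out[[length(out) + 1L]] <- data.frame(
          protospacer = substr(win, 1L, 20L), pam = substr(win, 21L, 23L),
          strand = "+", stringsAsFactors = FALSE)
      }
      rcw <- rc_oracle(win)
      if (substr(rcw, 21L, 23L) %in% paste0(c("A", "C", "G", "T"), "GG")) {
        out[[length(out) + 1L]] <- data.frame(
          protospacer = substr(rcw, 1L, 20L), pam = substr(rcw, 21L, 23L),
          strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protospacer = character(), pam = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# vectorised sliding Hamming scan: for every 20-nt window on both strands
# of every chromosome, count mismatches to the protospacer and keep PAM
# matches; independent of Biostrings
oracle_offtargets <- function(proto, genome, max_mm = 3L,
                              pams = c("NGG", "NAG")) {
  pam_ok <- function(p) substr(p, 2L, 3L) %in%
    c(NGG = "GG", NAG = "AG")[pams]
  pv <- strsplit(proto, "")[[1]]
  out <- list()
  for (chrom in names(genome$chromosomes)) {
    cseq <- genome$chromosomes[[chrom]]
    cv <- strsplit(cseq, "")[[1]]
    L <- length(cv)
    if (L < 23L) next
    for (strand in c("+", "-")) {
      qv <- if (strand == "+") pv else strsplit(rc_oracle(proto), "")[[1]]
      nw <- L - 19L
      mm <- integer(nw)
      for (k in 1:20) mm <- mm + (cv[k:(k + nw - 1L)] != qv[k])
      for (i in which(mm <= max_mm)) {      # i = 1-based window start
        pos0 <- i - 1L
        if (strand == "+") {
          if (pos0 + 23L > L) next
          pam <- substr(cseq, pos0 + 21L, pos0 + 23L)
          site <- substr(cseq, pos0 + 1L, pos0 + 20L)
        } else {
          if (pos0 - 3L < 0L) next
          pam <- rc_oracle(substr(cseq, pos0 - 2L, pos0))
          site <- rc_oracle(substr(cseq, pos0 + 1L, pos0 + 20L))
        }
        if (!pam_ok(pam)) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, start0 = pos0, pam = pam,
          m = sum(strsplit(site, "")[[1]] != pv), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      start0 = integer(), pam = character(), m = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start0, res$strand), , drop = FALSE]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# write a one-gene plus-strand toy annotation + genome; coordinates are
# the 1-based GTF values given by the caller
write_toy_gtf <- function(path, rows) {
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), ""), path)
  path
}

gtf_row <- function(chrom, feature, start1, end1, strand, tid,
                    gid = paste0("g_", tid)) {
  c(chrom, "test", feature, start1, end1, ".", strand,
    if (feature %in% c("CDS", "stop_codon")) "0" else ".",
    sprintf('gene_id "%s"; transcript_id "%s";', gid, tid))
}

write_fasta <- function(path, seqs) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

# a toy region: `cds_nt` of coding sequence ending in TAA, then `utr_nt`
# of UTR, with a plus-strand guide planted at cut-to-stop distance d
# (its PAM GG written into the UTR); background has no other GG/CC
toy_region_with_guide <- function(cds_nt = 150L, utr_nt = 150L, d = 20L,
                                  seed = 42L) {
  set.seed(seed)
  bg <- function(n) {        # {A,C,T}, no CC
    out <- character(n); prev <- "A"
    for (i in seq_len(n)) {
      prev <- sample(if (prev == "C") c("A", "T") else c("A", "C", "T"), 1)
      out[i] <- prev
    }
    paste(out, collapse = "")
  }
  seq <- paste0(bg(cds_nt - 3L), "TAA", bg(utr_nt))
  stop0 <- cds_nt - 3L
  pam0 <- stop0 + 3L + d + 3L
  substr(seq, pam0 + 2L, pam0 + 3L) <- "GG"
  design_region_from_sequence(seq, stop0)
}
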