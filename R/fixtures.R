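#' Specification of a synthetic test genome
#'
#' Describes a deterministic fixture: one single-exon gene per chromosome
#' on a G-free, CC-free background (so the only Cas9 sites are the planted
#' ones),
#' guide sites planted at chosen cut-to-stop distances by writing a GG PAM
#' dinucleotide at the implied position, and off-target decoys planted on a
#' dedicated decoy chromosome at exact Hamming distances with chosen PAM
#' classes (mutations swap within {A<->T, C->A, G->T}, so planting never
#' creates new PAMs). The same seed always reproduces byte-identical
#' FASTA/GTF/truth outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_transcripts Number of genes.
#' @param cds_len_range Range of CDS lengths (nt, stop included; rounded to
#'   a codon multiple).
#' @param utr_len_range Range of 3'UTR lengths (nt).
#' @param strands Strand per gene (recycled).
#' @param guide_distances Cut-to-stop distances planted for every gene.
#' @param offtarget_mm Hamming distances of the decoys planted for each
#'   gene's first guide (distances beyond the search budget verify the
#'   scanner's cut-off).
#' @param offtarget_pams PAM class per decoy (recycled over
#'   `offtarget_mm`).
#' @param decoy_bad_pam Also plant one exact protospacer copy followed by
#'   TTT (no PAM), which must never be reported.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_transcripts = 4L,
                         cds_len_range = c(150L, 300L),
                         utr_len_range = c(150L, 240L),
                         strands = c("+", "-"),
                         guide_distances = c(10L, 13L, 25L),
                         offtarget_mm = 1:4,
                         offtarget_pams = c("NGG", "NAG", "NGG", "NGG"),
                         decoy_bad_pam = TRUE) {
  stopifnot(n_transcripts >= 1L, all(guide_distances >= 0L))
  structure(list(seed = as.integer(seed),
                 n_transcripts = as.integer(n_transcripts),
                 cds_len_range = as.integer(cds_len_range),
                 utr_len_range = as.integer(utr_len_range),
                 strands = strands,
                 guide_distances = as.integer(guide_distances),
                 offtarget_mm = as.integer(offtarget_mm),
                 offtarget_pams = rep_len(offtarget_pams,
                                          length(offtarget_mm)),
                 decoy_bad_pam = isTRUE(decoy_bad_pam)),
            class = "fixture_spec")
}

# Background sequence uses the {A, C, T} alphabet with CC dinucleotides
# forbidden: without G there is no NGG/NAG PAM on the plus strand and
# without CC none on the minus strand, so the planted GG dinucleotides are
# the only Cas9 sites, while 3-letter protospacers keep spurious
# protospacer re-matches vanishingly unlikely.
bg_string <- function(n, prev = "") {
  out <- character(n)
  for (i in seq_len(n)) {
    pool <- if (prev == "C") c("A", "T") else c("A", "C", "T")
    prev <- sample(pool, 1L)
    out[i] <- prev
  }
  paste(out, collapse = "")
}

# in-frame coding background: same alphabet/CC rule, no in-frame TAA
bg_cds <- function(n_codons, prev = "") {
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      codon <- bg_string(3L, prev)
      if (codon != "TAA") break
    }
    out[i] <- codon
    prev <- substr(codon, 3L, 3L)
  }
  paste(out, collapse = "")
}

#' Generate a synthetic genome, annotation and truth table
#'
#' Builds the fixture described by a [fixture_spec()]; optionally writes
#' `genome.fa`, `annotation.gtf` and `truth.tsv` under `dir`. Every planted
#' feature (guide site with its exact cut distance; off-target decoy with
#' its exact mismatch count and PAM class) is recorded in the truth table,
#' which downstream tests round-trip against the design pipeline.
#'
#' @param spec A `fixture_spec`.
#' @param dir Optional output directory (created if missing).
#' @return A list: `genome` (`genome_seq`), `gtf` (data frame of GTF
#'   fields), `truth` (data frame), and file `paths` when `dir` was given.
#' @export
generate_fixtures <- function(spec, dir = NULL) {
  stopifnot(is(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  chroms <- list()
  gtf <- list()
  truth <- list()
  decoy_parts <- list()
  strands <- rep_len(spec$strands, spec$n_transcripts)

  for (t in seq_len(spec$n_transcripts)) {
    id <- sprintf("FIXT%04d", t)
    chrom <- paste0("chr", id)
    cds_len <- 3L * (sample_range(spec$cds_len_range) %/% 3L)
    utr_len <- sample_range(spec$utr_len_range)
    flank5 <- 80L
    flank3 <- 60L

    flank5_seq <- bg_string(flank5)
    cds <- paste0(bg_cds(cds_len / 3L - 1L,
                         prev = substr(flank5_seq, flank5, flank5)), "TAA")
    seq <- paste0(flank5_seq, cds, bg_string(utr_len, prev = "A"),
                  bg_string(flank3))
    stop_g <- flank5 + cds_len - 3L      # 0-based first stop base

    planted <- list()
    for (d in spec$guide_distances) {
      cut_g <- stop_g + 3L + d
      pam0 <- cut_g + 3L                 # PAM footprint [pam0, pam0+3)
      if (pam0 + 3L > flank5 + cds_len + utr_len) {
        warning("cut distance ", d, " does not fit in the UTR of ", id,
                call. = FALSE)
        next
      }
      substr0(seq, pam0 + 1L, pam0 + 3L) <- "GG"
      planted[[length(planted) + 1L]] <- list(d = d, cut_g = cut_g)
    }
    # read the planted protospacers back off the finished gene sequence
    for (pl in planted) {
      proto <- substr0(seq, pl$cut_g - 17L, pl$cut_g + 3L)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "guide", transcript_id = id, chrom = chrom,
        strand = strands[t],
        start0 = NA_integer_, cut_to_stop = pl$d, mm = NA_integer_,
        pam_class = "NGG", protospacer = proto, stringsAsFactors = FALSE)
    }

    exon <- c(flank5, flank5 + cds_len + utr_len)       # 0-based half-open
    cds_iv <- c(flank5, flank5 + cds_len - 3L)          # stop excluded
    stop_iv <- c(stop_g, stop_g + 3L)
    L <- nchar(seq)
    if (strands[t] == "-") {
      seq <- revcomp(seq)
      flip <- function(iv) c(L - iv[2], L - iv[1])
      exon <- flip(exon); cds_iv <- flip(cds_iv); stop_iv <- flip(stop_iv)
    }
    chroms[[chrom]] <- seq
    add <- function(type, iv) {
      gtf[[length(gtf) + 1L]] <<- data.frame(
        seqname = chrom, source = "fixture", feature = type,
        start = iv[1] + 1L, end = iv[2], score = ".", strand = strands[t],
        frame = if (type %in% c("CDS", "stop_codon")) "0" else ".",
        attribute = sprintf('gene_id "g%s"; transcript_id "%s";', id, id),
        stringsAsFactors = FALSE)
    }
    add("exon", exon); add("CDS", cds_iv); add("stop_codon", stop_iv)

    # off-target decoys for this gene's first planted guide
    if (length(planted) > 0L && length(spec$offtarget_mm) > 0L) {
      proto <- truth[[length(truth) - length(planted) + 1L]]$protospacer
      for (k in seq_along(spec$offtarget_mm)) {
        mm <- spec$offtarget_mm[k]
        pam_class <- spec$offtarget_pams[k]
        decoy <- mutate_protospacer(proto, mm)
        pam <- if (pam_class == "NGG") "TGG" else "TAG"
        decoy_parts[[length(decoy_parts) + 1L]] <- list(
          transcript_id = id, site = paste0(decoy, pam), mm = mm,
          pam_class = pam_class, protospacer = proto, decoy = decoy)
      }
      if (spec$decoy_bad_pam) {
        decoy_parts[[length(decoy_parts) + 1L]] <- list(
          transcript_id = id, site = paste0(proto, "TTT"), mm = 0L,
          pam_class = "none", protospacer = proto, decoy = proto)
      }
    }
  }

  # assemble the decoy chromosome with A/T spacers between planted sites
  if (length(decoy_parts) > 0L) {
    pieces <- character()
    pos <- 0L
    for (dp in decoy_parts) {
      spacer <- paste0(bg_string(29L), "T")   # T-terminal: no CC junction
      pieces <- c(pieces, spacer, dp$site)
      pos <- pos + 30L
      if (dp$pam_class != "none") {
        truth[[length(truth) + 1L]] <- data.frame(
          type = "offtarget", transcript_id = dp$transcript_id,
          chrom = "chrDecoy", strand = "+", start0 = pos,
          cut_to_stop = NA_integer_, mm = dp$mm, pam_class = dp$pam_class,
          protospacer = dp$protospacer, stringsAsFactors = FALSE)
      }
      pos <- pos + nchar(dp$site)
    }
    chroms[["chrDecoy"]] <- paste0(paste(pieces, collapse = ""),
                                   bg_string(30L, prev = "A"))
  }

  genome <- genome_seq(chroms)
  gtf <- do.call(rbind, gtf)
  truth <- do.call(rbind, truth)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  truth = file.path(dir, "truth.tsv"))
    write_genome_fasta(genome, paths$fasta)
    write_gtf(gtf, paths$gtf)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(genome = genome, gtf = gtf, truth = truth, paths = paths)
}

# k mismatches at the most PAM-proximal positions (deterministic, and the
# positions where the MIT weights keep single-hit scores low, so planted
# decoys do not push a guide's aggregate specificity below the floor);
# substitutions stay within {A->T, T->A, C->A, G->T} so no GG/CC (hence no
# PAM) is ever created by mutation
mutate_protospacer <- function(proto, k) {
  if (k == 0L) return(proto)
  positions <- (21L - k):20L
  cc <- chars(proto)
  swap <- c(A = "T", T = "A", C = "A", G = "T")
  cc[positions] <- swap[cc[positions]]
  paste(cc, collapse = "")
}

# guard against sample()'s scalar expansion when the range is degenerate
sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

write_gtf <- function(gtf, path) {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   gtf$seqname, gtf$source, gtf$feature, gtf$start, gtf$end,
                   gtf$score, gtf$strand, gtf$frame, gtf$attribute)
  writeLines(lines, path)
  invisible(path)
}
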