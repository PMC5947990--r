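#' Load transcript models from a GTF or GFF3 annotation
#'
#' Builds an in-memory catalogue of transcript models (exon/CDS structure,
#' stop-codon position, spliced sequence) for every transcript that carries
#' CDS features. Coordinates are converted from the 1-based inclusive GTF/GFF
#' convention to 0-based half-open internally.
#'
#' Stop-codon handling tolerates both GTF dialects: an explicit `stop_codon`
#' feature is authoritative; otherwise the last 3 CDS bases are checked
#' against TAA/TAG/TGA, and failing that the 3 exonic bases immediately after
#' the CDS are tried. Transcripts whose resolved coding length is not
#' divisible by 3, that lack any 3'UTR, or whose stop codon is split across a
#' splice junction are skipped with a warning: no C-terminal knock-in site
#' can be designed for them.
#'
#' @param path GTF or GFF3 file (format detected from the extension).
#' @param genome A `genome_seq`, used to verify coordinates and stop codons.
#' @return A `transcript_catalog`: a named list of `transcript_model`s.
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  if (!is.null(mc$transcript_id)) {
    tid <- as.character(mc$transcript_id)
  } else if (!is.null(mc$Parent)) {
    # GFF3: exon/CDS features point at their transcript via Parent
    tid <- vapply(mc$Parent, function(p)
      if (length(p)) sub("^transcript:", "", p[[1]]) else NA_character_, "")
  } else {
    stop("annotation has neither transcript_id nor Parent attributes")
  }

  keep <- type %in% c("exon", "CDS", "stop_codon") & !is.na(tid)
  gr <- gr[keep]; type <- type[keep]; tid <- tid[keep]
  catalog <- list()
  for (id in unique(tid[type == "CDS"])) {
    sel <- tid == id
    sub <- gr[sel]; st <- type[sel]
    feat <- function(what) {
      f <- sub[st == what]
      if (length(f) == 0L) return(NULL)
      f <- sort(f)
      data.frame(start0 = GenomicRanges::start(f) - 1L,
                 end0 = GenomicRanges::end(f))
    }
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    strand <- as.character(GenomicRanges::strand(sub))[1]
    exons <- feat("exon")
    if (is.null(exons)) exons <- feat("CDS")  # CDS-only annotations
    model <- tryCatch(
      transcript_model(id, chrom, strand, exons, feat("CDS"),
                       stop_feature = feat("stop_codon"), genome = genome),
      error = function(e) {
        warning("skipping transcript ", id, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(model)) catalog[[id]] <- model
  }
  structure(catalog, class = "transcript_catalog")
}

#' Construct a transcript model
#'
#' Low-level constructor used by [load_annotation()] and the fixture
#' generator. All intervals are 0-based half-open genomic coordinates.
#'
#' @param transcript_id Transcript identifier.
#' @param chrom,strand Chromosome and strand (`"+"` or `"-"`).
#' @param exons,cds Data frames with `start0`/`end0` columns, genomically
#'   sorted, non-overlapping; `cds` must lie within `exons`.
#' @param stop_feature Optional `stop_codon` interval (authoritative when
#'   present).
#' @param genome A `genome_seq` for sequence checks.
#' @return A `transcript_model` object. Errors (caught and converted to
#'   skip-warnings by the loader) signal transcripts with no designable
#'   C-terminal site.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons, cds,
                             stop_feature = NULL, genome) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons), is.data.frame(cds))
  exons <- exons[order(exons$start0), , drop = FALSE]
  cds <- cds[order(cds$start0), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$end0[-nrow(exons)] > exons$start0[-1]))
    stop("overlapping exons")
  clen <- chrom_length(genome, chrom)
  if (any(exons$start0 < 0) || any(exons$end0 > clen))
    stop("exon outside chromosome ", chrom)
  for (i in seq_len(nrow(cds))) {
    if (!any(cds$start0[i] >= exons$start0 & cds$end0[i] <= exons$end0))
      stop("CDS interval not contained in an exon")
  }

  # per-base map of the spliced transcript, in transcript orientation
  gpos <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons$start0[i], exons$end0[i] - 1L)), use.names = FALSE)
  if (strand == "-") gpos <- rev(gpos)
  n <- length(gpos)
  seq_plus <- paste0(vapply(seq_len(nrow(exons)), function(i)
    genome_slice(genome, chrom, exons$start0[i], exons$end0[i]), ""),
    collapse = "")
  tx_seq <- if (strand == "+") seq_plus else revcomp(seq_plus)

  in_cds <- rep(FALSE, n)
  for (i in seq_len(nrow(cds)))
    in_cds[gpos >= cds$start0[i] & gpos < cds$end0[i]] <- TRUE
  idx <- which(in_cds)
  if (length(idx) == 0L) stop("no CDS bases")
  if (any(diff(idx) != 1L)) stop("CDS not contiguous in transcript coordinates")
  cds_start_tx <- idx[1] - 1L          # 0-based
  cds_end_tx <- idx[length(idx)]       # half-open

  tx_codon <- function(start_tx) {
    if (start_tx < 0 || start_tx + 3L > n) return(NA_character_)
    substr0(tx_seq, start_tx, start_tx + 3L)
  }

  if (!is.null(stop_feature)) {
    if (sum(stop_feature$end0 - stop_feature$start0) != 3L)
      stop("stop_codon feature is not 3 bases")
    if (nrow(stop_feature) > 1L)
      stop("stop codon split across a splice junction")
    hit <- which(gpos == stop_feature$start0[1])
    if (length(hit) != 1L) stop("stop_codon feature outside exons")
    stop_tx <- if (strand == "+") hit - 1L else hit - 3L
    if (!is_stop_codon(tx_codon(stop_tx)))
      stop("stop_codon feature sequence ", tx_codon(stop_tx), " is not a stop")
    # Ensembl GTF excludes the stop from CDS; fold it into the coding span
    cds_end_tx <- max(cds_end_tx, stop_tx + 3L)
    if (stop_tx + 3L != cds_end_tx) stop("stop_codon not at the CDS 3' end")
  } else {
    if (is_stop_codon(tx_codon(cds_end_tx - 3L))) {
      stop_tx <- cds_end_tx - 3L
    } else if (is_stop_codon(tx_codon(cds_end_tx))) {
      stop_tx <- cds_end_tx
      cds_end_tx <- cds_end_tx + 3L
    } else {
      stop("no stop codon at or after the CDS 3' end")
    }
  }
  if ((cds_end_tx - cds_start_tx) %% 3L != 0L)
    stop("CDS length ", cds_end_tx - cds_start_tx, " not divisible by 3")
  if (n - cds_end_tx < 1L)
    stop("no 3'UTR downstream of the stop codon")

  structure(list(
    transcript_id = transcript_id, chrom = chrom, strand = strand,
    exons = exons, cds = cds, tx_seq = tx_seq, gpos = gpos,
    cds_start_tx = cds_start_tx, cds_end_tx = cds_end_tx,
    stop_tx = stop_tx,
    stop_codon = c(start0 = min(gpos[(stop_tx + 1L):(stop_tx + 3L)]),
                   end0 = max(gpos[(stop_tx + 1L):(stop_tx + 3L)]) + 1L)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model ", x$transcript_id, " (", x$chrom, x$strand, "): ",
      length(x$gpos), " nt spliced, CDS ", x$cds_end_tx - x$cds_start_tx,
      " nt (incl. stop), 3'UTR ", length(x$gpos) - x$cds_end_tx, " nt\n",
      sep = "")
  invisible(x)
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat("transcript_catalog with", length(x), "transcript(s)\n")
  invisible(x)
}
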