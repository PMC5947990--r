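#' Extract the stop-codon-centred design window for a transcript
#'
#' Returns the spliced, transcript-orientation (coding-strand) sequence of a
#' window centred on the stop codon: `window_nt/2` bases before the first
#' stop base and the remainder from the stop onwards. The window is truncated
#' (not FLANK-padded) where the transcript ends; a "short UTR" warning is
#' emitted when the 3' side is truncated. Each base carries a CDS / UTR3 /
#' FLANK label (the stop codon itself counts as CDS; exonic bases 5' of the
#' CDS are FLANK) and its genomic coordinate, so designs round-trip exactly
#' to the genome. A warning is emitted when the window spans a splice
#' junction (genomic and window coordinates then diverge).
#'
#' @param transcript_id Transcript to design against.
#' @param catalog A `transcript_catalog` from [load_annotation()].
#' @param genome A `genome_seq` (retained for provenance; the catalogue
#'   already stores spliced sequence extracted from it).
#' @param window_nt Even window width in nt, default 200, minimum 46 (room
#'   for one 23-nt Cas9 site either side of the stop).
#' @return A `design_region` object.
#' @export
extract_design_region <- function(transcript_id, catalog, genome,
                                  window_nt = 200L) {
  if (window_nt < 46L || window_nt %% 2L != 0L)
    stop("window_nt must be an even integer >= 46, got ", window_nt)
  model <- catalog[[transcript_id]]
  if (is.null(model)) stop("unknown transcript id: ", transcript_id)

  n <- nchar(model$tx_seq)
  half <- window_nt %/% 2L
  before <- min(half, model$stop_tx)
  after <- min(window_nt - half, n - model$stop_tx)
  if (n - model$stop_tx < window_nt - half)
    warning("short UTR: only ", n - model$stop_tx - 3L,
            " nt of 3'UTR available for transcript ", transcript_id,
            call. = FALSE)
  if (model$stop_tx < half)
    warning("short upstream sequence for transcript ", transcript_id,
            call. = FALSE)

  from <- model$stop_tx - before      # 0-based transcript start of window
  to <- model$stop_tx + after         # half-open
  idx <- (from + 1L):to               # 1-based into tx vectors
  sequence <- substr0(model$tx_seq, from, to)

  tx0 <- from:(to - 1L)
  labels <- ifelse(tx0 < model$cds_start_tx, "FLANK",
                   ifelse(tx0 < model$cds_end_tx, "CDS", "UTR3"))
  gpos <- model$gpos[idx]
  step <- if (model$strand == "+") 1L else -1L
  if (length(gpos) > 1L && any(diff(gpos) != step))
    warning("design window for ", transcript_id, " spans a splice junction; ",
            "genomic and window coordinates diverge", call. = FALSE)

  new_design_region(transcript_id = transcript_id, sequence = sequence,
                    stop_offset = before, labels = labels,
                    chrom = model$chrom, strand = model$strand, gpos = gpos)
}

#' Build a design region directly from a sequence
#'
#' Annotation-free entry point: supply the coding-strand sequence around a
#' stop codon and the 0-based offset of the stop codon's first base. All
#' bases before the stop are labelled CDS and all bases after it UTR3 (use
#' `cds_start` if the supplied sequence extends 5' of the CDS).
#'
#' @param sequence Coding-strand nucleotide string.
#' @param stop_offset 0-based offset of the stop codon's first base.
#' @param transcript_id Label for outputs.
#' @param cds_start 0-based offset where the CDS begins (earlier bases are
#'   labelled FLANK).
#' @return A `design_region` object.
#' @export
design_region_from_sequence <- function(sequence, stop_offset,
                                        transcript_id = "query",
                                        cds_start = 0L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  pos0 <- 0:(n - 1L)
  labels <- ifelse(pos0 < cds_start, "FLANK",
                   ifelse(pos0 < stop_offset + 3L, "CDS", "UTR3"))
  new_design_region(transcript_id = transcript_id, sequence = sequence,
                    stop_offset = stop_offset, labels = labels,
                    chrom = NA_character_, strand = "+",
                    gpos = pos0)
}

new_design_region <- function(transcript_id, sequence, stop_offset, labels,
                              chrom, strand, gpos) {
  n <- nchar(sequence)
  stopifnot(length(labels) == n, length(gpos) == n,
            stop_offset >= 0, stop_offset + 3L <= n)
  codon <- substr0(sequence, stop_offset, stop_offset + 3L)
  if (!is_stop_codon(codon))
    stop("sequence at stop_offset ", stop_offset, " is ", codon,
         ", not a stop codon")
  structure(list(transcript_id = transcript_id, sequence = sequence,
                 stop_offset = as.integer(stop_offset), labels = labels,
                 chrom = chrom, strand = strand, gpos = as.integer(gpos)),
            class = "design_region")
}

#' @export
print.design_region <- function(x, ...) {
  cat("design_region for ", x$transcript_id, ": ", nchar(x$sequence),
      " nt, stop codon at offset ", x$stop_offset, " (",
      substr0(x$sequence, x$stop_offset, x$stop_offset + 3L), "), ",
      sum(x$labels == "UTR3"), " nt 3'UTR\n", sep = "")
  invisible(x)
}
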