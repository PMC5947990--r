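CRRNA_REPEAT_16 <- "GUUUUAGAGCUAUGCU"
# representative SpCas9 tracrRNA constant (67 nt); ordering metadata only
TRACRRNA_67 <- "AGCAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGGCACCGAGUCGGUGCUUU"

#' Design configuration
#'
#' Collects the tunable parameters of the design policy with the defaults
#' used throughout: guides cutting 8-15 nt into the 3'UTR are preferred, in
#' batch mode no guide may cut more than 30 nt from the stop codon, the top
#' two guides are reported, donors are capped at 200 nt with at least 30 nt
#' homology arms, off-targets are searched up to 3 mismatches against NGG
#' and NAG PAMs, and donor PAMs are rewritten NGG->NGC (NGT optional).
#' `specificity_floor` (default 50 on the 0-100 aggregate-specificity scale)
#' is a hard filter below which guides are discarded.
#'
#' @param preferred_window Length-2 integer vector: preferred cut-to-stop
#'   distance band, inclusive.
#' @param batch_max_distance Maximum cut-to-stop distance in batch mode (nt).
#' @param top_k Number of guides to report per target.
#' @param window_nt Design-window width passed to [extract_design_region()].
#' @param ssodn_cap Maximum donor length (nt), tag included.
#' @param min_arm Minimum homology-arm length (nt).
#' @param offtarget_max_mm Off-target search mismatch budget.
#' @param offtarget_pams PAM classes tolerated at off-target sites.
#' @param pam_block_policy `"NGC"` or `"NGT"`: replacement PAM for donor
#'   blocking edits in the 3'UTR.
#' @param specificity_floor Minimum aggregate specificity score (0-100).
#' @param emit_strand `"PAM"` (guide strand, default) or `"nonPAM"` for the
#'   emitted donor oligo.
#' @param always_block Force a blocking edit even when the tag insertion
#'   itself disrupts the protospacer/PAM register.
#' @param crrna_repeat 16-nt crRNA repeat appended to the 20-nt target
#'   sequence in ordering oligos.
#' @return A `design_config` list.
#' @export
design_config <- function(preferred_window = c(8L, 15L),
                          batch_max_distance = 30L,
                          top_k = 2L,
                          window_nt = 200L,
                          ssodn_cap = 200L,
                          min_arm = 30L,
                          offtarget_max_mm = 3L,
                          offtarget_pams = c("NGG", "NAG"),
                          pam_block_policy = c("NGC", "NGT"),
                          specificity_floor = 50,
                          emit_strand = c("PAM", "nonPAM"),
                          always_block = FALSE,
                          crrna_repeat = CRRNA_REPEAT_16) {
  pam_block_policy <- match.arg(pam_block_policy)
  emit_strand <- match.arg(emit_strand)
  stopifnot(length(preferred_window) == 2L,
            preferred_window[1] <= preferred_window[2],
            preferred_window[1] >= 0L,
            preferred_window[2] <= batch_max_distance,
            top_k >= 1L, nchar(crrna_repeat) == 16L)
  structure(list(preferred_window = as.integer(preferred_window),
                 batch_max_distance = as.integer(batch_max_distance),
                 top_k = as.integer(top_k), window_nt = as.integer(window_nt),
                 ssodn_cap = as.integer(ssodn_cap),
                 min_arm = as.integer(min_arm),
                 offtarget_max_mm = as.integer(offtarget_max_mm),
                 offtarget_pams = offtarget_pams,
                 pam_block_policy = pam_block_policy,
                 specificity_floor = specificity_floor,
                 emit_strand = emit_strand, always_block = always_block,
                 crrna_repeat = crrna_repeat),
            class = "design_config")
}

#' Enumerate SpCas9 candidate sites in a design region
#'
#' Scans every 23-nt window on both strands for the N20-NGG pattern. Each
#' hit becomes one candidate row; windows containing N are excluded. The
#' blunt SpCas9 cut falls 3 nt 5' of the PAM (between protospacer positions
#' 17 and 18); `cut_offset` is the 0-based index of the first region base 3'
#' of the cut bond in plus-strand region coordinates, and `cut_to_stop` is
#' `cut_offset - (stop_offset + 3)` (0 = the cut bond abuts the last stop
#' base; positive = downstream in the 3'UTR).
#'
#' @param region A `design_region`.
#' @return A data frame of guide candidates ordered by `region_offset` then
#'   strand, with columns protospacer, pam, strand, region_offset,
#'   cut_offset, cut_to_stop, in_utr3 (cut base annotated UTR3), and
#'   placeholder score columns.
#' @export
enumerate_guides <- function(region) {
  seq <- region$sequence
  n <- nchar(seq)
  if (n < 23L) stop("region shorter than 23 nt")
  rows <- list()
  for (s in 0:(n - 23L)) {
    win <- substr0(seq, s, s + 23L)
    if (grepl("N", win, fixed = TRUE)) next
    # plus strand: protospacer [s, s+20), PAM [s+20, s+23)
    if (substr(win, 22L, 23L) == "GG") {
      rows[[length(rows) + 1L]] <- list(
        protospacer = substr(win, 1L, 20L), pam = substr(win, 21L, 23L),
        strand = "+", region_offset = s, cut_offset = s + 17L)
    }
    # minus strand: PAM footprint [s, s+3) reads CCN on plus
    if (substr(win, 1L, 2L) == "CC") {
      rc <- revcomp(win)
      rows[[length(rows) + 1L]] <- list(
        protospacer = substr(rc, 1L, 20L), pam = substr(rc, 21L, 23L),
        strand = "-", region_offset = s + 3L, cut_offset = s + 6L)
    }
  }
  if (length(rows) == 0L) return(empty_guide_table())
  g <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  g <- g[order(g$region_offset, g$strand), , drop = FALSE]
  g$cut_to_stop <- g$cut_offset - (region$stop_offset + 3L)
  g$in_utr3 <- g$cut_to_stop >= 0L &
    region$labels[g$cut_offset + 1L] == "UTR3"
  g$ontarget <- NA_real_
  g$specificity <- NA_real_
  g$mm0 <- g$mm1 <- g$mm2 <- g$mm3 <- NA_integer_
  rownames(g) <- NULL
  g
}

empty_guide_table <- function() {
  data.frame(protospacer = character(), pam = character(),
             strand = character(), region_offset = integer(),
             cut_offset = integer(), cut_to_stop = integer(),
             in_utr3 = logical(), ontarget = numeric(),
             specificity = numeric(), mm0 = integer(), mm1 = integer(),
             mm2 = integer(), mm3 = integer(), stringsAsFactors = FALSE)
}

#' Signed cut-to-stop distance of a candidate
#'
#' @param candidate One row of the table from [enumerate_guides()].
#' @param region The `design_region` the candidate came from.
#' @return `cut_offset - (stop_offset + 3)`: nt between the last stop-codon
#'   base and the blunt cut bond (0 = abutting, positive = 3'UTR side,
#'   negative = inside/upstream of the stop).
#' @export
cut_to_stop_distance <- function(candidate, region) {
  as.integer(candidate$cut_offset) - (region$stop_offset + 3L)
}

#' Rank and select scored guide candidates
#'
#' Applies the design policy: hard filters first (cut bond in the 3'UTR,
#' aggregate specificity at or above the floor, and in batch mode a
#' cut-to-stop distance of at most `batch_max_distance`), then a tiered
#' order - candidates cutting inside the preferred 8-15 nt band precede all
#' others; within a tier higher on-target score wins, ties broken by smaller
#' cut-to-stop distance then protospacer lexicographic order. The first
#' `top_k` survivors are returned; a structured "no guide" warning is
#' emitted when none survive.
#'
#' Candidates with `NA` specificity (no genome available for the off-target
#' search) pass the specificity filter; the gap is recorded in the output.
#'
#' @param candidates Scored guide table ([enumerate_guides()] +
#'   [score_guides()]).
#' @param config A `design_config`.
#' @param batch_mode Apply the batch distance cap?
#' @return The selected rows, ranked, with a `rank` column.
#' @export
rank_guides <- function(candidates, config = design_config(),
                        batch_mode = FALSE) {
  g <- candidates
  keep <- g$in_utr3 &
    (is.na(g$specificity) | g$specificity >= config$specificity_floor)
  if (batch_mode) keep <- keep & g$cut_to_stop <= config$batch_max_distance
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) {
    warning(structure(class = c("knocktag_no_guide", "warning", "condition"),
                      list(message = "no guide survives the design filters",
                           call = sys.call())))
    out <- g
    out$rank <- integer()
    return(out)
  }
  in_window <- g$cut_to_stop >= config$preferred_window[1] &
    g$cut_to_stop <= config$preferred_window[2]
  ord <- order(!in_window,              # preferred band first
               -g$ontarget,             # then efficiency
               g$cut_to_stop,           # then proximity
               g$protospacer)           # deterministic tie-break
  g <- g[ord, , drop = FALSE]
  g <- head(g, config$top_k)
  g$rank <- seq_len(nrow(g))
  rownames(g) <- NULL
  g
}

#' Assemble the 36-mer crRNA ordering oligo
#'
#' The synthetic crRNA is the 20-nt gene-specific target sequence
#' (transliterated to RNA) followed by the 16-nt repeat that base-pairs with
#' the tracrRNA.
#'
#' @param protospacer 20-nt DNA protospacer.
#' @param repeat_16nt 16-nt RNA repeat.
#' @return A 36-nt RNA string.
#' @export
build_crrna_oligo <- function(protospacer, repeat_16nt = CRRNA_REPEAT_16) {
  if (is.list(protospacer) || is.data.frame(protospacer))
    protospacer <- protospacer$protospacer
  if (nchar(protospacer) != 20L)
    stop("protospacer must be 20 nt, got ", nchar(protospacer))
  if (nchar(repeat_16nt) != 16L)
    stop("repeat must be 16 nt, got ", nchar(repeat_16nt))
  paste0(chartr("T", "U", protospacer), repeat_16nt)
}

#' The tracrRNA ordering constant
#'
#' A representative 67-nt SpCas9 tracrRNA sequence, reported as ordering
#' metadata alongside each design (commercial suppliers ship their own
#' chemically modified variant of the same length).
#'
#' @return A 67-nt RNA string.
#' @export
tracrrna_constant <- function() TRACRRNA_67
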