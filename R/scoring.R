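BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(outer(BASES, BASES, paste0))

# Hsu et al. 2013 per-position single-mismatch weights, position 1 =
# PAM-distal ... position 20 = PAM-proximal
HSU_WEIGHTS <- c(0.000, 0.000, 0.014, 0.000, 0.000,
                 0.395, 0.317, 0.000, 0.389, 0.079,
                 0.445, 0.508, 0.613, 0.851, 0.732,
                 0.828, 0.615, 0.804, 0.685, 0.583)

#' Constants of the MIT specificity model
#'
#' The 20 per-position mismatch weights (published Hsu et al. 2013
#' constants; position 20 is PAM-proximal) and the parameters of the
#' single-hit score: the mean-pairwise-distance denominator (19), the
#' distance-term multiplier (4) and the single-mismatch distance convention
#' (d-bar = 19, i.e. distance term = 1).
#'
#' @param weights Numeric length-20 vector of weights in [0, 1].
#' @return A `mit_constants` list.
#' @export
mit_constants <- function(weights = HSU_WEIGHTS) {
  stopifnot(length(weights) == 20L, all(weights >= 0 & weights <= 1))
  structure(list(W = weights, d_max = 19, d_mult = 4, d_single = 19),
            class = "mit_constants")
}

#' Extract the 30-nt scoring context of a candidate
#'
#' 4 nt upstream + 20-nt protospacer + 3-nt PAM + 3 nt downstream, on the
#' protospacer strand. Returns `NA` when the region does not extend far
#' enough or the context contains N.
#'
#' @param candidate One guide-table row.
#' @param region The `design_region`.
#' @return A 30-nt string, or `NA_character_`.
#' @export
context30 <- function(candidate, region) {
  n <- nchar(region$sequence)
  if (candidate$strand == "+") {
    p <- candidate$region_offset
    if (p - 4L < 0L || p + 26L > n) return(NA_character_)
    ctx <- substr0(region$sequence, p - 4L, p + 26L)
  } else {
    s <- candidate$region_offset - 3L   # PAM footprint start on plus strand
    if (s - 3L < 0L || s + 27L > n) return(NA_character_)
    ctx <- revcomp(substr0(region$sequence, s - 3L, s + 27L))
  }
  if (grepl("[^ACGT]", ctx)) return(NA_character_)
  ctx
}

#' Rule Set 2 feature vector of a 30-nt context
#'
#' Deterministic featurization of the published on-target efficiency
#' scheme: position-specific single-nucleotide indicators (30 x 4),
#' position-specific adjacent dinucleotide indicators (29 x 16),
#' position-independent mono- and dinucleotide counts, the protospacer GC
#' count with low/high-GC indicators, and the 16 NGGN PAM-variant
#' indicators (PAM N crossed with the first downstream base). Feature names
#' are stable across calls; an externally trained linear model over these
#' names can be plugged into [ontarget_score()].
#'
#' @param ctx 30-nt context (see [context30()]); 0-based positions 25-26
#'   must be "GG".
#' @return Named numeric vector of 623 features.
#' @export
ruleset2_features <- function(ctx) {
  if (!is.character(ctx) || length(ctx) != 1L || nchar(ctx) != 30L)
    stop("context must be a single 30-nt string")
  if (grepl("[^ACGT]", ctx)) stop("non-ACGT character in context")
  cc <- chars(ctx)
  if (!(cc[26] == "G" && cc[27] == "G"))
    stop("context positions 25-26 (0-based) must be GG, got ",
         cc[26], cc[27])

  order1 <- setNames(numeric(120),
                     paste0("pos", rep(sprintf("%02d", 1:30), each = 4), "_",
                            rep(BASES, 30)))
  order1[paste0("pos", sprintf("%02d", 1:30), "_", cc)] <- 1

  di <- paste0(cc[1:29], cc[2:30])
  order2 <- setNames(numeric(29 * 16),
                     paste0("di_pos", rep(sprintf("%02d", 1:29), each = 16),
                            "_", rep(DINUCS, 29)))
  order2[paste0("di_pos", sprintf("%02d", 1:29), "_", di)] <- 1

  mono_ct <- setNames(vapply(BASES, function(b) sum(cc == b), 1),
                      paste0("count_", BASES))
  di_ct <- setNames(vapply(DINUCS, function(d) sum(di == d), 1),
                    paste0("count_", DINUCS))

  proto <- cc[5:24]
  gc <- sum(proto %in% c("G", "C"))
  gc_block <- c(gc_count = gc, gc_low = as.numeric(gc < 10),
                gc_high = as.numeric(gc > 10))

  nggn <- setNames(numeric(16), paste0("NGGN_", DINUCS))
  nggn[paste0("NGGN_", cc[25], cc[28])] <- 1

  c(order1, order2, mono_ct, di_ct, gc_block, nggn)
}

#' On-target efficiency score of a candidate
#'
#' With a configured model (a linear model over [ruleset2_features()] names,
#' see [ontarget_model()]), returns its prediction clipped to [0, 1].
#' Without one, returns a documented deterministic fallback:
#' `0.5 * gc_term + 0.5 * run_term`, where `gc_term = max(0, 1 - |GC20 -
#' 10| / 10)` (GC20 = protospacer G+C count) and `run_term` is 1 when the
#' protospacer has no homonucleotide run of 5 or more, else 0. Returns `NA`
#' (unscorable) when the 30-nt context cannot be extracted.
#'
#' @param candidate Guide-table row.
#' @param region `design_region`.
#' @param model Optional `ontarget_model`.
#' @return Score in [0, 1], or `NA`.
#' @export
ontarget_score <- function(candidate, region, model = NULL) {
  ctx <- context30(candidate, region)
  if (is.na(ctx)) return(NA_real_)
  if (!is.null(model)) {
    feats <- ruleset2_features(ctx)
    missing <- setdiff(names(model$weights), names(feats))
    if (length(missing) > 0L)
      stop("model references unknown features: ",
           paste(head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...")
    pred <- model$intercept +
      sum(model$weights * feats[names(model$weights)])
    return(min(1, max(0, pred)))
  }
  proto <- substr(ctx, 5L, 24L)
  gc20 <- nchar(gsub("[^GC]", "", proto))
  gc_term <- max(0, 1 - abs(gc20 - 10) / 10)
  run_term <- as.numeric(!grepl("A{5}|C{5}|G{5}|T{5}", proto))
  0.5 * gc_term + 0.5 * run_term
}

#' Load a linear on-target model from a weights table
#'
#' Expects a tab-separated file with columns `feature` and `weight`; a row
#' with feature `(Intercept)` supplies the intercept.
#'
#' @param path TSV file path.
#' @return An `ontarget_model` list with `weights` and `intercept`.
#' @export
ontarget_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "weight") %in% names(tab)))
  int <- tab$weight[tab$feature == "(Intercept)"]
  w <- tab[tab$feature != "(Intercept)", ]
  structure(list(weights = setNames(w$weight, w$feature),
                 intercept = if (length(int)) int[1] else 0),
            class = "ontarget_model")
}

#' Precompute the off-target search index of a genome
#'
#' Concatenates all chromosomes (separated by N runs longer than the
#' mismatch budget can bridge) so each protospacer needs only two pattern
#' searches over the whole genome; hits spanning a separator are discarded
#' when mapped back.
#'
#' @param genome A `genome_seq`.
#' @return An `offtarget_index`.
#' @export
offtarget_index <- function(genome) {
  sep <- strrep("N", 25L)
  lens <- vapply(genome$chromosomes, nchar, 1L)
  starts0 <- cumsum(c(0L, head(lens + 25L, -1L)))  # chrom start in concat
  names(starts0) <- names(lens)
  concat <- paste(unlist(genome$chromosomes), collapse = sep)
  structure(list(subject = Biostrings::DNAString(concat),
                 starts0 = starts0, lens = lens),
            class = "offtarget_index")
}

#' Find genomic off-target sites of a protospacer
#'
#' Exhaustively reports every 20-nt window, on either strand of every
#' chromosome, within `max_mm` mismatches of the protospacer and flanked by
#' an NGG or NAG PAM. The on-target locus itself (an exact match at
#' `self`) is returned flagged `self = TRUE` and is excluded from aggregate
#' specificity scoring; when `self` is not supplied the first exact NGG
#' match is taken as the on-target locus.
#'
#' @param protospacer 20-nt string (or a guide-table row).
#' @param genome A `genome_seq`.
#' @param max_mm Mismatch budget (default 3).
#' @param pams Tolerated PAM classes.
#' @param self Optional list/row with `chrom`, `strand`, `start0` (0-based
#'   plus-strand start of the 20-nt protospacer footprint) of the intended
#'   target.
#' @param index Optional precomputed [offtarget_index()].
#' @param constants `mit_constants` used to score each hit.
#' @return Data frame: chrom, strand, start0, pam, pam_class, m,
#'   mismatch_positions (comma string, 1 = PAM-distal), dbar, score
#'   (MIT single-hit), self.
#' @export
find_offtargets <- function(protospacer, genome, max_mm = 3L,
                            pams = c("NGG", "NAG"), self = NULL,
                            index = NULL, constants = mit_constants()) {
  if (is.list(protospacer) || is.data.frame(protospacer))
    protospacer <- protospacer$protospacer
  stopifnot(nchar(protospacer) == 20L)
  if (is.null(index)) index <- offtarget_index(genome)
  pam2 <- c(NGG = "GG", NAG = "AG")[pams]

  scan_strand <- function(pattern, strand) {
    mt <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   index$subject, max.mismatch = max_mm,
                                   with.indels = FALSE)
    st0 <- BiocGenerics::start(mt) - 1L   # concat 0-based footprint start
    out <- list()
    for (st in st0) {
      ci <- findInterval(st, index$starts0)
      chrom <- names(index$starts0)[ci]
      pos0 <- st - index$starts0[[ci]]    # chromosome-local
      if (pos0 < 0L || pos0 + 20L > index$lens[[ci]]) next  # spans separator
      chrom_seq <- genome$chromosomes[[chrom]]
      if (strand == "+") {
        if (pos0 + 23L > index$lens[[ci]]) next
        pam <- substr0(chrom_seq, pos0 + 20L, pos0 + 23L)
        site <- substr0(chrom_seq, pos0, pos0 + 20L)
      } else {
        if (pos0 - 3L < 0L) next
        pam <- revcomp(substr0(chrom_seq, pos0 - 3L, pos0))
        site <- revcomp(substr0(chrom_seq, pos0, pos0 + 20L))
      }
      cls <- names(pam2)[match(substr(pam, 2L, 3L), pam2)]
      if (is.na(cls)) next
      mm <- which(chars(site) != chars(protospacer))
      if (length(mm) > max_mm) next     # N-containing windows re-checked
      out[[length(out) + 1L]] <- list(
        chrom = chrom, strand = strand, start0 = pos0, pam = pam,
        pam_class = cls, m = length(mm),
        mismatch_positions = paste(mm, collapse = ","),
        dbar = mean_pairwise_distance(mm, constants))
    }
    out
  }

  rows <- c(scan_strand(protospacer, "+"),
            scan_strand(revcomp(protospacer), "-"))
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      start0 = integer(), pam = character(),
                      pam_class = character(), m = integer(),
                      mismatch_positions = character(), dbar = numeric(),
                      score = numeric(), self = logical(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  hits <- hits[order(hits$chrom, hits$start0, hits$strand), , drop = FALSE]
  hits$score <- vapply(seq_len(nrow(hits)), function(i)
    mit_single_hit(parse_positions(hits$mismatch_positions[i]), constants),
    1)
  hits$self <- FALSE
  if (!is.null(self)) {
    hits$self <- hits$chrom == self$chrom & hits$strand == self$strand &
      hits$start0 == self$start0 & hits$m == 0L
  } else {
    cand <- which(hits$m == 0L & hits$pam_class == "NGG")
    if (length(cand) > 0L) hits$self[cand[1]] <- TRUE
  }
  rownames(hits) <- NULL
  hits
}

parse_positions <- function(x) {
  if (is.na(x) || x == "") integer() else as.integer(strsplit(x, ",")[[1]])
}

mean_pairwise_distance <- function(positions, constants = mit_constants()) {
  m <- length(positions)
  if (m < 2L) return(constants$d_single)
  mean(abs(outer(positions, positions, "-"))[lower.tri(diag(m))])
}

#' MIT single-hit score
#'
#' Perfect matches score 100 by convention. For m >= 1 mismatches at
#' protospacer positions p (1 = PAM-distal, 20 = PAM-proximal):
#' `100 * prod(1 - W[p]) * 1 / (((19 - dbar) / 19) * 4 + 1) * 1 / m^2`,
#' where `dbar` is the mean pairwise distance between mismatch positions
#' (taken as 19 when m = 1, so the distance term is 1).
#'
#' @param hit Ascending integer vector of mismatch positions in 1..20, or a
#'   row from [find_offtargets()].
#' @param constants A `mit_constants`.
#' @return Score in [0, 100].
#' @export
mit_single_hit <- function(hit, constants = mit_constants()) {
  positions <- if (is.data.frame(hit) || is.list(hit)) {
    parse_positions(hit$mismatch_positions)
  } else as.integer(hit)
  m <- length(positions)
  if (m == 0L) return(100)
  if (any(positions < 1L | positions > 20L))
    stop("mismatch position outside 1..20")
  dbar <- mean_pairwise_distance(positions, constants)
  dterm <- 1 / (((constants$d_max - dbar) / constants$d_max) *
                  constants$d_mult + 1)
  100 * prod(1 - constants$W[positions]) * dterm * (1 / m^2)
}

#' Aggregate MIT specificity score
#'
#' `100 * 100 / (100 + sum(single-hit scores))` over all off-target hits
#' excluding the on-target locus; 100 when there are no off-targets (higher
#' = more specific).
#'
#' @param hits Data frame from [find_offtargets()] (rows with
#'   `self = TRUE` are dropped), or a numeric vector of single-hit scores.
#' @return Score in [0, 100].
#' @export
mit_aggregate <- function(hits) {
  scores <- if (is.data.frame(hits)) hits$score[!hits$self] else hits
  100 * 100 / (100 + sum(scores))
}

#' Score a guide candidate table
#'
#' Fills `ontarget` (model or fallback), and when a genome is available the
#' off-target-derived columns: `specificity` (aggregate MIT score excluding
#' the on-target locus) and `mm0`..`mm3` (non-self hit counts by mismatch
#' count). Candidates whose 30-nt context cannot be extracted are dropped
#' with a warning.
#'
#' @param candidates Guide table from [enumerate_guides()].
#' @param region The `design_region`.
#' @param genome Optional `genome_seq` for the off-target search (without
#'   it, specificity stays `NA`).
#' @param model Optional `ontarget_model`.
#' @param config A `design_config`.
#' @param index Optional precomputed [offtarget_index()].
#' @return The scored candidate table.
#' @export
score_guides <- function(candidates, region, genome = NULL, model = NULL,
                         config = design_config(), index = NULL) {
  g <- candidates
  if (nrow(g) == 0L) return(g)
  g$ontarget <- vapply(seq_len(nrow(g)), function(i)
    ontarget_score(g[i, ], region, model), 1)
  if (anyNA(g$ontarget)) {
    warning(sum(is.na(g$ontarget)),
            " candidate(s) dropped: 30-nt scoring context not extractable",
            call. = FALSE)
    g <- g[!is.na(g$ontarget), , drop = FALSE]
  }
  if (!is.null(genome) && nrow(g) > 0L) {
    if (is.null(index)) index <- offtarget_index(genome)
    for (i in seq_len(nrow(g))) {
      self <- guide_genomic_locus(g[i, ], region)
      hits <- find_offtargets(g$protospacer[i], genome,
                              max_mm = config$offtarget_max_mm,
                              pams = config$offtarget_pams, self = self,
                              index = index)
      ns <- hits[!hits$self, , drop = FALSE]
      g$specificity[i] <- mit_aggregate(hits)
      for (k in 0:3) g[[paste0("mm", k)]][i] <- sum(ns$m == k)
    }
  }
  rownames(g) <- NULL
  g
}

# genomic locus of a candidate's 20-nt protospacer footprint (plus-strand
# start), for self-identification in the off-target scan; NULL for direct
# sequence input with no genomic anchor
guide_genomic_locus <- function(candidate, region) {
  if (is.na(region$chrom)) return(NULL)
  idx <- (candidate$region_offset + 1L):(candidate$region_offset + 20L)
  gp <- region$gpos[idx]
  step <- if (region$strand == "+") 1L else -1L
  if (any(diff(gp) != step)) return(NULL)  # footprint spans splice junction
  list(chrom = region$chrom,
       strand = if (region$strand == candidate$strand) "+" else "-",
       start0 = min(gp))
}
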