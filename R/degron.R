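# Average residue masses (Da) and Kyte-Doolittle hydropathies used by the
# PEST-find score. X gets a generic residue mass and neutral hydropathy.
AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 110.0000
)

KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -0.3, V =  4.2, X =  0.0
)

# PEST-find score of one inter-flank stretch (character vector of residues).
# score = 0.55 * DEPST mass percent (corrected by one equivalent each of P,
# D|E, S|T) - 0.5 * mass-weighted hydrophobicity index, where hydropathy is
# mapped to hv = 10*KD + 45 so it spans 0 (Arg) to 90 (Ile). On this scale a
# long poly-DEPST stretch scores about +43 and poly-Ile -45.
pest_score <- function(aa) {
  mass <- AA_MASS[aa]
  total <- sum(mass)
  is_depst <- aa %in% c("D", "E", "P", "S", "T")
  depst_mass <- sum(mass[is_depst])
  corr <- AA_MASS[["P"]]
  de <- intersect(c("D", "E"), aa)
  st <- intersect(c("S", "T"), aa)
  corr <- corr + min(AA_MASS[de]) + min(AA_MASS[st])
  depst_pct <- 100 * (depst_mass - corr) / total
  hv <- 10 * KYTE_DOOLITTLE[aa] + 45
  hydind <- sum(mass * hv) / total
  unname(0.55 * depst_pct - 0.5 * hydind)
}

#' Scan a protein for PEST regions
#'
#' PEST regions -- stretches rich in Pro, Glu/Asp and Ser/Thr flanked by
#' positively charged residues -- are associated with rapid proteolysis.
#' Candidates are the maximal stretches between consecutive K/R/H residues
#' (or sequence ends) that are at least `min_window` residues long and
#' contain at least one P, one of D/E, and one of S/T. Each candidate is
#' scored with the PEST-find formula: 0.55 times the mass percent of
#' D/E/P/S/T (corrected by one equivalent each of P, D or E, and S or T)
#' minus 0.5 times the mass-weighted hydrophobicity index (Kyte-Doolittle
#' hydropathy mapped to `10*KD + 45`). Scores above `threshold` (default +5)
#' are flagged significant ("potential" PEST regions).
#'
#' @param record A [protein_record()].
#' @param min_window Minimum stretch length between charged flanks
#'   (default 10).
#' @param threshold Significance cutoff on the score (default 5, strict).
#' @return A data.frame of class `pest_candidates` with columns `start`,
#'   `end`, `length`, `score`, `significant`, `sequence`, sorted by score
#'   descending (ties by start ascending). Coordinates are 1-based inclusive
#'   and cover the inter-flank stretch only.
#' @export
pest_scan <- function(record, min_window = 10L, threshold = 5) {
  aa <- residues(record)
  n <- length(aa)
  is_flank <- aa %in% c("K", "R", "H")
  runs <- rle(!is_flank)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_window
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                    score = numeric(0), significant = logical(0),
                    sequence = character(0), stringsAsFactors = FALSE)
  for (i in which(keep)) {
    stretch <- aa[starts[i]:ends[i]]
    if (!any(stretch == "P")) next
    if (!any(stretch %in% c("D", "E"))) next
    if (!any(stretch %in% c("S", "T"))) next
    sc <- pest_score(stretch)
    out <- rbind(out, data.frame(
      start = starts[i], end = ends[i], length = length(stretch),
      score = sc, significant = sc > threshold,
      sequence = paste(stretch, collapse = ""), stringsAsFactors = FALSE))
  }
  out <- out[order(-out$score, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pest_candidates", "data.frame"))
}

# Shared motif scanner: overlapping matches of a fixed-width pattern,
# restricted to `scan_region` if given; coordinates stay on the parent.
scan_motif <- function(record, pattern, width, motif_type, scan_region = NULL) {
  seq <- record$sequence
  offset <- 0L
  if (!is.null(scan_region)) {
    validate_region(scan_region, record)
    seq <- substr(seq, scan_region$start, scan_region$end)
    offset <- scan_region$start - 1L
  }
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  starts <- if (m[1L] == -1L) integer(0) else as.integer(m)
  starts <- starts[starts + width - 1L <= nchar(seq)]
  matched <- if (length(starts) == 0L) character(0) else {
    substring(record$sequence, starts + offset, starts + offset + width - 1L)
  }
  hits <- data.frame(
    protein_id = rep(record$id, length(starts)),
    motif_type = rep(motif_type, length(starts)),
    start = starts + offset,
    end = starts + offset + width - 1L,
    matched_sequence = matched,
    stringsAsFactors = FALSE)
  structure(hits, class = c("degron_hits", "data.frame"))
}

#' Scan for D-box degrons (RxxL)
#'
#' The destruction box recognized by the anaphase-promoting complex (APC/C)
#' is the four-residue pattern R-x-x-L. All (possibly overlapping) matches
#' are reported with 1-based coordinates; `x` matches any of the 20 standard
#' residues but never `X`.
#'
#' @param record A [protein_record()].
#' @param scan_region Optional [region()] restricting the scan (coordinates
#'   in the output remain relative to the full sequence).
#' @return A `degron_hits` data.frame: `protein_id`, `motif_type`, `start`,
#'   `end`, `matched_sequence`.
#' @export
dbox_scan <- function(record, scan_region = NULL) {
  scan_motif(record, "R[ACDEFGHIKLMNPQRSTVWY]{2}L", 4L, "D_box", scan_region)
}

#' Scan for KEN-box degrons (literal KEN)
#'
#' @inheritParams dbox_scan
#' @return A `degron_hits` data.frame.
#' @export
kenbox_scan <- function(record, scan_region = NULL) {
  scan_motif(record, "KEN", 3L, "KEN_box", scan_region)
}

#' Write degron / PEST hits to TSV
#'
#' @param hits A `degron_hits` or `pest_candidates` data.frame.
#' @param path Output path.
#' @param protein_id Used for `pest_candidates`, which carry no id column.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path, protein_id = "") {
  if (inherits(hits, "pest_candidates")) {
    hits <- data.frame(protein_id = protein_id, motif_type = "PEST",
                       start = hits$start, end = hits$end,
                       matched_sequence = hits$sequence, score = hits$score,
                       stringsAsFactors = FALSE)
  } else {
    hits$score <- NA_real_
  }
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
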