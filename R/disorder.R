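# Per-residue disorder propensities (TOP-IDP-style composition scale):
# positive values are disorder-promoting, negative values order-promoting.
# X is neutral (0) and additionally pinned to score 0.5 after smoothing so
# unknown residues can never create or extend a disordered segment under the
# strict > 0.5 rule.
DISORDER_PROPENSITY <- c(
  W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
  L = -0.326, V = -0.121, C = -0.020, N =  0.007, T =  0.059,
  A =  0.060, G =  0.166, R =  0.180, D =  0.192, H =  0.303,
  Q =  0.318, S =  0.341, K =  0.586, E =  0.736, P =  0.987,
  X =  0.000
)

# Sliding mean with truncated windows at the sequence ends.
running_mean <- function(x, half_width) {
  n <- length(x)
  if (half_width <= 0L || n == 1L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_width, 1L)
  hi <- pmin(seq_len(n) + half_width, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Score per-residue disorder
#'
#' The bundled `"propensity"` scorer estimates disorder from local amino-acid
#' composition: each residue's disorder propensity (a TOP-IDP-style scale in
#' which P, E, K, S, Q, G promote disorder and W, F, Y, I, L, V promote
#' order) is averaged over a sequence window, smoothed a second time, and
#' mapped through a logistic function to \[0, 1\]. Scores above 0.5 indicate
#' a residue more likely to lie in a disordered region. `X` residues always
#' receive exactly 0.5. The scorer is deterministic: identical sequences give
#' bit-identical profiles.
#'
#' Per-residue profiles produced by any external predictor (e.g. IUPred2A)
#' can be used instead via [read_disorder_profile()]; all downstream
#' operations consume the same `disorder_profile` container.
#'
#' @param record A [protein_record()].
#' @param scorer Scorer id; only `"propensity"` is bundled.
#' @param window Half-width of the first composition window, in residues.
#' @param smooth Half-width of the second smoothing pass.
#' @param steepness Slope of the logistic map from mean propensity to score.
#' @return A `disorder_profile`: list with `protein_id`, `scores` (one per
#'   residue, in \[0,1\]), `scorer_id`, `scorer_params`.
#' @export
score_disorder <- function(record, scorer = "propensity",
                           window = 10L, smooth = 5L, steepness = 4) {
  stopifnot(inherits(record, "protein_record"))
  if (!identical(scorer, "propensity")) {
    stop("score_disorder: unknown scorer id '", scorer,
         "' (use read_disorder_profile() for external profiles)", call. = FALSE)
  }
  aa <- residues(record)
  p <- unname(DISORDER_PROPENSITY[aa])
  m <- running_mean(running_mean(p, as.integer(window)), as.integer(smooth))
  scores <- 1 / (1 + exp(-steepness * m))
  scores[aa == "X"] <- 0.5
  disorder_profile(record$id, scores, "propensity",
                   list(window = window, smooth = smooth, steepness = steepness))
}

#' Construct a disorder profile container
#' @param protein_id Identifier of the scored protein.
#' @param scores Numeric vector of per-residue scores in \[0,1\].
#' @param scorer_id Name of the scorer that produced the profile.
#' @param scorer_params Named list of scorer parameters.
#' @return An object of class `disorder_profile`.
#' @export
disorder_profile <- function(protein_id, scores, scorer_id = "external",
                             scorer_params = list()) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L || any(!is.finite(scores)) ||
      any(scores < 0) || any(scores > 1)) {
    stop("disorder_profile: scores must be finite values in [0, 1]",
         call. = FALSE)
  }
  structure(list(protein_id = protein_id, scores = scores,
                 scorer_id = scorer_id, scorer_params = scorer_params),
            class = "disorder_profile")
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat(sprintf("<disorder_profile> %s: %d residues, scorer=%s, %.1f%% > 0.5\n",
              x$protein_id, length(x$scores), x$scorer_id,
              100 * mean(x$scores > 0.5)))
  invisible(x)
}

#' Read an external per-residue disorder profile (TSV)
#'
#' Expects columns `position` (1-based, contiguous from 1) and `score`; an
#' optional `residue` column is checked against `record` when supplied.
#'
#' @param path TSV path.
#' @param record Optional [protein_record()]; the profile length must match.
#' @param scorer_id Label stored in the profile (default `"external"`).
#' @return A `disorder_profile`.
#' @export
read_disorder_profile <- function(path, record = NULL, scorer_id = "external") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("position", "score") %in% names(df))) {
    stop("read_disorder_profile: need columns 'position' and 'score'",
         call. = FALSE)
  }
  df <- df[order(df$position), ]
  if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
    stop("read_disorder_profile: positions must be contiguous from 1",
         call. = FALSE)
  }
  id <- if (!is.null(record)) record$id else "external"
  if (!is.null(record) && nrow(df) != record_length(record)) {
    stop(sprintf(
      "read_disorder_profile: profile length %d does not match sequence length %d",
      nrow(df), record_length(record)), call. = FALSE)
  }
  disorder_profile(id, df$score, scorer_id)
}

#' Write a disorder profile to TSV
#' @param profile A `disorder_profile`.
#' @param path Output path.
#' @param record Optional record supplying the `residue` column.
#' @return Invisibly, `path`.
#' @export
write_disorder_profile <- function(profile, path, record = NULL) {
  df <- data.frame(position = seq_along(profile$scores),
                   residue = if (!is.null(record)) residues(record) else NA,
                   score = profile$scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of residues above the disorder threshold
#'
#' Counts residues with score strictly greater than `threshold` (a residue
#' scoring exactly at the threshold does not qualify), optionally within a
#' [region()].
#'
#' @param profile A `disorder_profile`.
#' @param threshold Disorder cutoff (default 0.5).
#' @param region Optional `region` restricting the computation.
#' @return Fraction in \[0, 1\].
#' @export
fraction_disordered <- function(profile, threshold = 0.5, region = NULL) {
  s <- profile$scores
  if (!is.null(region)) {
    validate_region(region, length(s))
    s <- s[region$start:region$end]
  }
  mean(s > threshold)
}

#' Find maximal long disordered segments
#'
#' Returns every maximal run of consecutive residues with score strictly
#' above `threshold` whose length is at least `min_length`. Long disordered
#' stretches matter because a terminal segment of roughly 30 residues is
#' enough for a ubiquitinated substrate to engage the proteasome channel;
#' the default `min_length = 31` implements ">30 residues" strictly.
#'
#' @param profile A `disorder_profile`.
#' @param threshold Disorder cutoff (default 0.5, strict).
#' @param min_length Minimum segment length in residues (default 31).
#' @return A data.frame of class `idr_segments` with columns `start`, `end`,
#'   `length`, `mean_score`, `side` (NA until classified), sorted by `start`.
#' @export
find_long_idrs <- function(profile, threshold = 0.5, min_length = 31L) {
  stopifnot(min_length >= 1L)
  above <- profile$scores > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  seg <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  seg$mean_score <- vapply(seq_len(nrow(seg)), function(i) {
    mean(profile$scores[seg$start[i]:seg$end[i]])
  }, numeric(1))
  seg$side <- rep(NA_character_, nrow(seg))
  structure(seg[order(seg$start), , drop = FALSE],
            class = c("idr_segments", "data.frame"))
}

#' Classify segments relative to an N/C split position
#'
#' A segment is `N` if it ends at or before `split_position`, `C` if it
#' starts after it, and `overlapping` if it spans the junction. The counts
#' always sum to the number of segments.
#'
#' @param segments An `idr_segments` data.frame.
#' @param split_position Last residue of the N-terminal part (e.g. 1403 for
#'   the SETD2-N / SETD2-C split 1403|1404).
#' @return List with `segments` (side column filled) and `counts`, a named
#'   integer vector `c(N=, C=, overlapping=)`.
#' @export
classify_segments <- function(segments, split_position) {
  split_position <- as.integer(split_position)
  side <- ifelse(segments$end <= split_position, "N",
                 ifelse(segments$start > split_position, "C", "overlapping"))
  segments$side <- side
  counts <- c(N = sum(side == "N"), C = sum(side == "C"),
              overlapping = sum(side == "overlapping"))
  list(segments = segments, counts = counts)
}

#' Summarize a disorder profile
#'
#' Aggregates the overall disordered fraction, the long-IDR segment table,
#' the N/C segment partition, and regional disordered fractions for the two
#' parts of the split (when `split_position` is given).
#'
#' @inheritParams find_long_idrs
#' @param split_position Optional N/C junction residue.
#' @return An object of class `disorder_summary`.
#' @export
summarize_disorder <- function(profile, threshold = 0.5, min_length = 31L,
                               split_position = NULL) {
  n_total <- length(profile$scores)
  n_dis <- sum(profile$scores > threshold)
  segments <- find_long_idrs(profile, threshold, min_length)
  counts <- NULL
  regional <- NULL
  if (!is.null(split_position)) {
    cl <- classify_segments(segments, split_position)
    segments <- cl$segments
    counts <- cl$counts
    rN <- region(1L, split_position)
    rC <- region(split_position + 1L, n_total)
    regional <- data.frame(
      region = c(sprintf("1-%d", split_position),
                 sprintf("%d-%d", split_position + 1L, n_total)),
      start = c(1L, split_position + 1L),
      end = c(split_position, n_total),
      fraction = c(fraction_disordered(profile, threshold, rN),
                   fraction_disordered(profile, threshold, rC)))
  }
  structure(list(protein_id = profile$protein_id,
                 threshold = threshold, min_length = as.integer(min_length),
                 fraction_disordered = n_dis / n_total,
                 n_disordered_residues = n_dis, n_total_residues = n_total,
                 segments = segments, segment_counts = counts,
                 regional_fractions = regional,
                 split_position = if (is.null(split_position)) NA_integer_
                                  else as.integer(split_position)),
            class = "disorder_summary")
}

#' @export
print.disorder_summary <- function(x, ...) {
  cat(sprintf("<disorder_summary> %s\n", x$protein_id))
  cat(sprintf("  disordered: %d / %d residues (%.2f%%), threshold > %g\n",
              x$n_disordered_residues, x$n_total_residues,
              100 * x$fraction_disordered, x$threshold))
  cat(sprintf("  long IDR segments (>= %d aa): %d\n",
              x$min_length, nrow(x$segments)))
  if (!is.null(x$segment_counts)) {
    cat(sprintf("  split %d|%d: N=%d, C=%d, overlapping=%d\n",
                x$split_position, x$split_position + 1L,
                x$segment_counts["N"], x$segment_counts["C"],
                x$segment_counts["overlapping"]))
    for (i in seq_len(nrow(x$regional_fractions))) {
      cat(sprintf("  region %s: %.2f%% disordered\n",
                  x$regional_fractions$region[i],
                  100 * x$regional_fractions$fraction[i]))
    }
  }
  invisible(x)
}

#' Write long-IDR segments to a BED-like TSV (1-based inclusive coordinates)
#' @param segments An `idr_segments` data.frame.
#' @param path Output path.
#' @param protein_id Identifier written in the first column.
#' @return Invisibly, `path`.
#' @export
write_segments_tsv <- function(segments, path, protein_id = "") {
  out <- data.frame(protein_id = rep(protein_id, nrow(segments)),
                    as.data.frame(segments))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a disorder summary to JSON
#' @param summary A `disorder_summary`.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON (e.g. run config).
#' @return Invisibly, `path`.
#' @export
write_summary_json <- function(summary, path, extra = NULL) {
  x <- unclass(summary)
  x$fraction_disordered_pct <- round(100 * x$fraction_disordered, 2)
  x$fraction_disordered <- round(x$fraction_disordered, 4)
  if (!is.null(extra)) x <- c(x, list(metadata = extra))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}
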