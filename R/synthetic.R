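# Default residue frequencies for the two composition modes. Disordered
# blocks are enriched in disorder-promoting residues (P, E, S, K, Q, G --
# high net charge, low hydrophobicity); ordered blocks in order-promoting
# ones (W, F, Y, I, L, V plus hydrophobic/neutral fill). Frequencies are
# configurable; only the dichotomy matters for the emulated contrast.
DISORDERED_FREQS <- c(
  P = 0.14, E = 0.14, S = 0.13, K = 0.11, Q = 0.09, G = 0.09,
  A = 0.06, D = 0.06, R = 0.06, T = 0.05, N = 0.03, H = 0.02,
  M = 0.005, C = 0.005, V = 0.01, L = 0.01, I = 0.005, F = 0.005,
  Y = 0.005, W = 0.005
)

ORDERED_FREQS <- c(
  I = 0.11, L = 0.12, V = 0.11, F = 0.09, W = 0.05, Y = 0.07,
  M = 0.05, C = 0.05, A = 0.08, T = 0.07, N = 0.05, H = 0.04,
  G = 0.05, S = 0.03, D = 0.02, E = 0.02, Q = 0.02, R = 0.02,
  K = 0.02, P = 0.01
)

#' Generate a synthetic protein sequence with planted disorder architecture
#'
#' Samples an ordered background and overwrites the requested blocks with
#' residues drawn from a disorder-promoting (or ordered) composition,
#' emulating the compositional contrast that drives composition-based
#' disorder predictors. Deterministic given `(params, seed)`.
#'
#' @param length Total sequence length (residues).
#' @param blocks List of `list(region = region(...), mode = "disordered"`
#'   or `"ordered")`; blocks must lie within the sequence and not overlap.
#' @param seed Integer seed.
#' @param id Record id.
#' @param disordered_freqs,ordered_freqs Named residue frequency vectors.
#' @return List with `record` (a [protein_record()]) and `truth` (scenario
#'   parameters incl. block coordinates and the seed).
#' @export
gen_sequence <- function(length, blocks = list(), seed = 1L,
                         id = "synthetic",
                         disordered_freqs = DISORDERED_FREQS,
                         ordered_freqs = ORDERED_FREQS) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  covered <- integer(0)
  for (b in blocks) {
    validate_region(b$region, length)
    span <- b$region$start:b$region$end
    if (any(span %in% covered)) {
      stop("gen_sequence: blocks must not overlap", call. = FALSE)
    }
    covered <- c(covered, span)
  }
  aa <- with_local_seed(seed, {
    bg <- sample(names(ordered_freqs), length, replace = TRUE,
                 prob = ordered_freqs)
    for (b in blocks) {
      span <- b$region$start:b$region$end
      freqs <- if (identical(b$mode, "disordered")) disordered_freqs
               else ordered_freqs
      bg[span] <- sample(names(freqs), length(span), replace = TRUE,
                         prob = freqs)
    }
    bg
  })
  record <- protein_record(id, paste(aa, collapse = ""))
  truth <- list(scenario = "gen_sequence", seed = seed, length = length,
                blocks = lapply(blocks, function(b) {
                  list(start = b$region$start, end = b$region$end,
                       mode = b$mode)
                }))
  list(record = record, truth = truth)
}

# Closed-form FRAP model evaluated on post-bleach times.
frap_model_curve <- function(t, params) {
  if (is.null(params$tau_fast)) {
    params$plateau - (params$plateau - params$f0) * exp(-t / params$tau)
  } else {
    params$plateau - params$amp_fast * exp(-t / params$tau_fast) -
      params$amp_slow * exp(-t / params$tau_slow)
  }
}

#' Generate a synthetic FRAP trace
#'
#' Emulates a typical acquisition: a prebleach plateau at 1.0 (~0.7 s), an
#' instantaneous bleach, and recovery sampled every `frame_interval` seconds
#' for `duration` seconds, following a single-exponential (full-FRAP) or
#' double-exponential (half-FRAP) model with additive Gaussian noise.
#'
#' @param params For mode `"full"`: `list(tau =, plateau =, f0 =)`. For mode
#'   `"half"`: `list(tau_fast =, tau_slow =, amp_fast =, amp_slow =,
#'   plateau =)`.
#' @param mode `"full"` or `"half"`.
#' @param noise_sd Additive Gaussian noise SD (0 for a noiseless trace).
#' @param frame_interval Seconds per frame (50-200 ms typical).
#' @param duration Post-bleach duration (s).
#' @param prebleach Prebleach duration (s).
#' @param seed Integer seed.
#' @return List with `trace` (a [frap_trace()]) and `truth`.
#' @export
gen_frap_trace <- function(params, mode = c("full", "half"), noise_sd = 0,
                           frame_interval = 0.1, duration = 10,
                           prebleach = 0.7, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(frame_interval > 0, frame_interval < duration, noise_sd >= 0)
  if (mode == "full") {
    stopifnot(params$tau > 0, params$plateau >= 0, params$f0 >= 0)
  } else {
    stopifnot(params$tau_fast > 0, params$tau_slow > 0,
              params$amp_fast >= 0, params$amp_slow >= 0)
  }
  n_pre <- max(3L, floor(prebleach / frame_interval))
  t_pre <- -rev(seq_len(n_pre)) * frame_interval
  t_post <- seq(0, duration, by = frame_interval)
  model_params <- if (mode == "full") {
    list(tau = params$tau, plateau = params$plateau, f0 = params$f0)
  } else {
    params
  }
  clean <- c(rep(1, n_pre), frap_model_curve(t_post, model_params))
  noisy <- with_local_seed(seed, {
    pmax(clean + stats::rnorm(length(clean), sd = noise_sd), 0)
  })
  trace <- frap_trace(times = c(t_pre, t_post), intensities = noisy,
                      bleach_index = n_pre + 1L, mode = mode,
                      frame_interval = frame_interval)
  list(trace = trace,
       truth = list(scenario = "gen_frap_trace", seed = seed, mode = mode,
                    params = params, noise_sd = noise_sd,
                    frame_interval = frame_interval, duration = duration,
                    clean = clean))
}

#' Generate a synthetic punctum image stack
#'
#' A 2-D Gaussian punctum on a dim background; inside the (rectangular
#' bleach) ROI the punctum amplitude follows the supplied single-exponential
#' FRAP recovery after the bleach frame, with Gaussian pixel noise.
#'
#' @param dim_hw Image height/width, e.g. `c(48, 48)`.
#' @param center Punctum center `c(row, col)` in pixels.
#' @param sigma Gaussian punctum width (pixels).
#' @param frap_params `list(tau =, plateau =, f0 =)` for the bleached-region
#'   recovery (normalized amplitude units).
#' @param frame_interval Seconds per frame.
#' @param duration Post-bleach duration (s).
#' @param prebleach Prebleach duration (s).
#' @param noise_sd Pixel noise SD.
#' @param seed Integer seed.
#' @return List with `stack` (a `punctum_stack` with `roi`) and `truth`.
#' @export
gen_punctum_stack <- function(dim_hw = c(48L, 48L), center = c(24, 24),
                              sigma = 6, frap_params = list(tau = 1,
                                                            plateau = 0.9,
                                                            f0 = 0),
                              frame_interval = 0.1, duration = 10,
                              prebleach = 0.7, noise_sd = 0, seed = 1L) {
  h <- dim_hw[1L]; w <- dim_hw[2L]
  if (center[1L] < 1 || center[1L] > h || center[2L] < 1 || center[2L] > w) {
    stop("gen_punctum_stack: punctum center outside frame", call. = FALSE)
  }
  n_pre <- max(3L, floor(prebleach / frame_interval))
  t_post <- seq(0, duration, by = frame_interval)
  nt <- n_pre + length(t_post)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  punctum <- exp(-((rows - center[1L])^2 + (cols - center[2L])^2) /
                   (2 * sigma^2))
  amp <- c(rep(1, n_pre), frap_model_curve(t_post, frap_params))
  half <- round(2 * sigma)
  roi <- list(x = max(1L, as.integer(round(center[2L] - half))),
              y = max(1L, as.integer(round(center[1L] - half))),
              width = min(w, 2L * half + 1L), height = min(h, 2L * half + 1L))
  mask <- matrix(FALSE, h, w)
  mask[roi$y:(roi$y + roi$height - 1L), roi$x:(roi$x + roi$width - 1L)] <- TRUE
  frames <- with_local_seed(seed, {
    arr <- array(0, dim = c(h, w, nt))
    for (k in seq_len(nt)) {
      img <- 0.05 + punctum
      img[mask] <- 0.05 + punctum[mask] * amp[k]
      if (noise_sd > 0) img <- pmax(img + stats::rnorm(h * w, sd = noise_sd), 0)
      arr[, , k] <- img
    }
    arr
  })
  stack <- list(frames = frames, frame_interval = frame_interval,
                bleach_frame = n_pre + 1L, roi = roi)
  list(stack = stack,
       truth = list(scenario = "gen_punctum_stack", seed = seed,
                    frap_params = frap_params, noise_sd = noise_sd,
                    center = center, sigma = sigma, amp = amp))
}

#' Generate a synthetic bait/mock spectral-count table
#'
#' Emulates an affinity-purification duplicate design: skewed
#' negative-binomial background counts, a planted enriched protein set whose
#' bait-run counts are multiplied by `effect_size`, a stated fraction of
#' peptides shared between protein pairs, and lengths over a realistic
#' range.
#'
#' @param n_proteins Number of proteins.
#' @param n_bait_runs,n_mock_runs Runs per condition (duplicates typical).
#' @param enriched_fraction Fraction of proteins planted as enriched.
#' @param effect_size Multiplier on bait counts for the planted set (1 =
#'   null).
#' @param shared_fraction Fraction of peptides shared between two proteins.
#' @param mean_count Negative-binomial mean per peptide per run.
#' @param dispersion Negative-binomial size parameter.
#' @param peptides_per_protein Range (min, max) of peptides per protein.
#' @param seed Integer seed.
#' @return List with `table` (a [count_table()]) and `truth` (incl. the
#'   planted enriched ids).
#' @export
gen_count_table <- function(n_proteins = 200L, n_bait_runs = 2L,
                            n_mock_runs = 2L, enriched_fraction = 0.1,
                            effect_size = 4, shared_fraction = 0.1,
                            mean_count = 4, dispersion = 2,
                            peptides_per_protein = c(2L, 8L), seed = 1L) {
  stopifnot(enriched_fraction >= 0, enriched_fraction <= 1,
            shared_fraction >= 0, shared_fraction < 1, effect_size > 0)
  with_local_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n_proteins))
    lens <- round(stats::runif(n_proteins, 100, 2000))
    n_enriched <- round(enriched_fraction * n_proteins)
    enriched <- sort(sample(ids, n_enriched))
    npep <- sample(peptides_per_protein[1L]:peptides_per_protein[2L],
                   n_proteins, replace = TRUE)
    pep_owner <- rep(seq_len(n_proteins), npep)
    n_pep <- length(pep_owner)
    pep_ids <- sprintf("pep%05d", seq_len(n_pep))
    pep_proteins <- lapply(pep_owner, function(i) ids[i])
    shared_idx <- sample(n_pep, round(shared_fraction * n_pep))
    for (p in shared_idx) {
      other <- sample(setdiff(seq_len(n_proteins), pep_owner[p]), 1L)
      pep_proteins[[p]] <- sort(c(pep_proteins[[p]], ids[other]))
    }
    run_ids <- c(sprintf("bait_%d", seq_len(n_bait_runs)),
                 sprintf("mock_%d", seq_len(n_mock_runs)))
    conditions <- c(rep("bait", n_bait_runs), rep("mock", n_mock_runs))
    counts <- matrix(stats::rnbinom(n_pep * length(run_ids),
                                    mu = mean_count, size = dispersion),
                     n_pep, length(run_ids))
    is_enriched_pep <- vapply(pep_proteins,
                              function(ps) any(ps %in% enriched), logical(1))
    bait_cols <- which(conditions == "bait")
    counts[is_enriched_pep, bait_cols] <-
      counts[is_enriched_pep, bait_cols] * effect_size
    colnames(counts) <- run_ids
    peptides_df <- data.frame(peptide = pep_ids, stringsAsFactors = FALSE)
    peptides_df$proteins <- pep_proteins
    peptides_df <- cbind(peptides_df, as.data.frame(counts))
    table <- count_table(
      proteins = data.frame(id = ids, length = lens,
                            is_contaminant = FALSE,
                            stringsAsFactors = FALSE),
      runs = data.frame(run_id = run_ids, condition = conditions,
                        replicate = c(seq_len(n_bait_runs),
                                      seq_len(n_mock_runs)),
                        stringsAsFactors = FALSE),
      peptides = peptides_df)
    list(table = table,
         truth = list(scenario = "gen_count_table", seed = seed,
                      enriched = enriched, effect_size = effect_size,
                      shared_fraction = shared_fraction))
  })
}

#' Generate a synthetic target/decoy PSM table
#'
#' Target scores are drawn from a higher-location Gaussian than decoys,
#' emulating a search against real plus shuffled sequences.
#'
#' @param n_targets,n_decoys Number of target / decoy PSMs.
#' @param target_mean,decoy_mean Score distribution locations.
#' @param score_sd Common score SD.
#' @param peptides_per_protein Approximate peptides per (target) protein.
#' @param seed Integer seed.
#' @return List with `psms` (a [psm_table()]) and `truth`.
#' @export
gen_psm_table <- function(n_targets = 200L, n_decoys = 200L,
                          target_mean = 4, decoy_mean = 0, score_sd = 1,
                          peptides_per_protein = 4L, seed = 1L) {
  stopifnot(n_targets >= 1L, n_decoys >= 0L)
  with_local_seed(seed, {
    n <- n_targets + n_decoys
    is_decoy <- c(rep(FALSE, n_targets), rep(TRUE, n_decoys))
    score <- c(stats::rnorm(n_targets, target_mean, score_sd),
               stats::rnorm(n_decoys, decoy_mean, score_sd))
    pep <- sprintf("pep%05d", seq_len(n))
    prot <- c(sprintf("T%04d", ceiling(seq_len(n_targets) /
                                         peptides_per_protein)),
              if (n_decoys > 0)
                sprintf("D%04d", ceiling(seq_len(n_decoys) /
                                           peptides_per_protein)))
    psms <- psm_table(psm_id = sprintf("psm%05d", seq_len(n)),
                      score = score, peptide = pep, proteins = as.list(prot),
                      is_decoy = is_decoy)
    list(psms = psms,
         truth = list(scenario = "gen_psm_table", seed = seed,
                      target_mean = target_mean, decoy_mean = decoy_mean,
                      score_sd = score_sd))
  })
}

#' Generate a synthetic SETD2-scale protein with a planted IDR architecture
#'
#' Convenience scenario used by tests and the acceptance script: a
#' 2564-residue protein with 17 planted long disordered blocks partitioned
#' 11 (N-terminal, within 1-1403) / 5 (C-terminal, within 1404-2564) / 1
#' (spanning the 1403|1404 junction), a DEPST-rich PEST stretch (flanked by
#' lysines) inside 504-1403, a KEN box planted at 2078 and a D box (RxxL) at
#' 2033.
#'
#' @param seed Integer seed.
#' @return List with `record` and `truth` (block coordinates, motif
#'   positions, PEST stretch).
#' @export
gen_idr_architecture <- function(seed = 1L) {
  n_blocks <- function(starts, len) {
    lapply(starts, function(s) list(region = region(s, s + len - 1L),
                                    mode = "disordered"))
  }
  # 11 N-terminal blocks of 80 aa; the 9th (start 980) doubles as the PEST
  # stretch host. 1 junction block 1370-1460. 5 C-terminal blocks of 80 aa,
  # clear of the degron positions 2033/2078.
  n_starts <- c(20L, 140L, 260L, 380L, 500L, 620L, 740L, 860L, 980L, 1100L,
                1220L)
  c_starts <- c(1540L, 1660L, 1780L, 2150L, 2290L)
  blocks <- c(n_blocks(n_starts, 80L),
              list(list(region = region(1370L, 1460L), mode = "disordered")),
              n_blocks(c_starts, 80L))
  gs <- gen_sequence(2564L, blocks, seed = seed, id = "synthetic-SETD2-like")
  aa <- residues(gs$record)
  # PEST stretch: K flanks at 980/1052, DEPST-rich interior 981-1051
  pest_inner <- 981:1051
  aa[980L] <- "K"; aa[1052L] <- "K"
  aa[pest_inner] <- with_local_seed(seed + 1L, {
    sample(c("D", "E", "P", "S", "T"), length(pest_inner), replace = TRUE)
  })
  # degron neighborhood: clear accidental K (KEN starts) and R (RxxL starts)
  # from the ordered background so the planted motifs are unambiguous
  zone <- 1964:2074
  aa[zone][aa[zone] %in% c("K", "R")] <- "A"
  aa[2033:2036] <- c("R", "S", "E", "L")  # D box RxxL at 2033
  aa[2078:2080] <- c("K", "E", "N")       # KEN box at 2078
  record <- protein_record(gs$record$id, paste(aa, collapse = ""))
  truth <- gs$truth
  truth$scenario <- "gen_idr_architecture"
  truth$pest <- list(start = 981L, end = 1051L)
  truth$dbox_start <- 2033L
  truth$kenbox_start <- 2078L
  truth$split_position <- 1403L
  truth$n_segments <- c(N = 11L, C = 5L, overlapping = 1L)
  list(record = record, truth = truth)
}

#' Write generator truth as JSON
#' @param truth A generator truth list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
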