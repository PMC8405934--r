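# Serialize a resolved config into "# key=value" TSV header lines.
config_header <- function(config) {
  flat <- unlist(config[vapply(config, function(x)
    is.atomic(x) && length(x) == 1L, logical(1))])
  c(sprintf("# idrproteo_version=%s",
            as.character(utils::packageVersion("idrproteo"))),
    sprintf("# %s=%s", names(flat), as.character(flat)))
}

write_tsv_with_header <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_stage <- function(quiet, fmt, ...) {
  if (!isTRUE(quiet)) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the disorder/degron profiling analysis
#'
#' Scores (or loads) a per-residue disorder profile, summarizes it
#' (fraction disordered, long-IDR segments, N/C partition), and optionally
#' scans for PEST regions and APC/C degrons. Writes a summary JSON, a
#' segment TSV, and (when degron scanning is on) a hits TSV.
#'
#' @param config Named list: `fasta` (path) or `record`
#'   ([protein_record()]); optional `profile` (external profile TSV, which
#'   bypasses the bundled scorer); `record_index` (default 1); `threshold`
#'   (0.5); `min_length` (31); `split_position` (optional); `scan_degrons`
#'   (default TRUE); `out_dir` (required); `quiet`.
#' @return Invisibly, a list with `summary`, `pest`, `dbox`, `kenbox`, and
#'   output `paths`.
#' @export
run_disorder <- function(config) {
  if (is.null(config$out_dir)) stop("run_disorder: config$out_dir is required",
                                    call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  record <- if (!is.null(config$record)) config$record
            else if (!is.null(config$fasta)) {
              read_fasta(config$fasta)[[config$record_index %||% 1L]]
            } else stop("run_disorder: supply config$fasta or config$record",
                        call. = FALSE)
  threshold <- config$threshold %||% 0.5
  min_length <- config$min_length %||% 31L
  profile <- if (!is.null(config$profile)) {
    read_disorder_profile(config$profile, record)
  } else {
    score_disorder(record)
  }
  log_stage(config$quiet, "disorder: %s, %d residues, scorer=%s",
            record$id, record_length(record), profile$scorer_id)
  summary <- summarize_disorder(profile, threshold, min_length,
                                config$split_position)
  log_stage(config$quiet, "disorder: %.2f%% disordered, %d long segments",
            100 * summary$fraction_disordered, nrow(summary$segments))
  paths <- list(
    summary = file.path(config$out_dir, "disorder_summary.json"),
    segments = file.path(config$out_dir, "idr_segments.tsv"))
  write_summary_json(summary, paths$summary, extra = config[
    vapply(config, function(x) is.atomic(x) && length(x) == 1L, logical(1))])
  write_segments_tsv(summary$segments, paths$segments, record$id)
  pest <- dbox <- kenbox <- NULL
  if (isTRUE(config$scan_degrons %||% TRUE)) {
    pest <- pest_scan(record, config$pest_min_window %||% 10L,
                      config$pest_threshold %||% 5)
    dbox <- dbox_scan(record)
    kenbox <- kenbox_scan(record)
    paths$hits <- file.path(config$out_dir, "degron_hits.tsv")
    hits <- rbind(as.data.frame(dbox), as.data.frame(kenbox))
    hits$score <- NA_real_
    pest_rows <- if (nrow(pest) > 0L) {
      data.frame(protein_id = record$id, motif_type = "PEST",
                 start = pest$start, end = pest$end,
                 matched_sequence = pest$sequence, score = pest$score,
                 stringsAsFactors = FALSE)
    } else NULL
    write_tsv_with_header(rbind(hits, pest_rows), paths$hits, config)
    log_stage(config$quiet, "degron: %d PEST, %d D-box, %d KEN-box hits",
              nrow(pest), nrow(dbox), nrow(kenbox))
  }
  invisible(list(summary = summary, pest = pest, dbox = dbox,
                 kenbox = kenbox, paths = paths))
}

#' Run the two-stage FRAP ensemble analysis
#'
#' For each sample, fits the full-FRAP trace first (single exponential,
#' yielding tau), then fits every half-FRAP trace with the double
#' exponential whose slow component is fixed to that tau -- the two-pass
#' order is enforced -- then classifies material state and summarizes the
#' ensemble.
#'
#' @param config Named list: `samples`, a named list where each element is
#'   `list(full = <frap_trace or CSV path>, half = list of traces/paths)`
#'   (`half` may be empty); optional `solid_cutoff` (20), `liquid_tau_cutoff`
#'   (2), `out_dir`, `quiet`. A sample with half-FRAP traces but no full
#'   trace is a pairing error.
#' @return Invisibly, list with per-sample `fits` (full fit, half fits,
#'   states), `ensemble` summary, and `paths`.
#' @export
run_frap <- function(config) {
  if (is.null(config$samples) || length(config$samples) == 0L) {
    stop("run_frap: config$samples is required", call. = FALSE)
  }
  orphans <- names(config$samples)[vapply(config$samples, function(s)
    is.null(s$full) && length(s$half) > 0L, logical(1))]
  if (length(orphans) > 0L) {
    stop("run_frap: half-FRAP traces without a matching full-FRAP sample: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  load_trace <- function(x) {
    if (inherits(x, "frap_trace")) x else read_trace_csv(x)
  }
  prep <- function(x) align_bleach(normalize_trace(load_trace(x)))
  fits <- lapply(names(config$samples), function(nm) {
    s <- config$samples[[nm]]
    full_fit <- fit_full_frap(prep(s$full))
    log_stage(config$quiet, "frap[%s]: full tau=%.4g s, recovery=%.1f%%",
              nm, full_fit$tau_slow, full_fit$percent_recovery)
    half_fits <- lapply(s$half %||% list(), function(h) {
      fit_half_frap(prep(h), full_tau = full_fit$tau_slow)
    })
    all_fits <- c(list(full_fit), half_fits)
    states <- vapply(all_fits, classify_state,
                     solid_cutoff = config$solid_cutoff %||% 20,
                     liquid_tau_cutoff = config$liquid_tau_cutoff %||% 2,
                     character(1))
    list(sample = nm, full = full_fit, half = half_fits, states = states)
  })
  names(fits) <- names(config$samples)
  flat <- do.call(rbind, lapply(fits, function(f) {
    rows <- c(list(f$full), f$half)
    data.frame(sample = f$sample,
               trace = c("full", sprintf("half_%d", seq_along(f$half))),
               model = vapply(rows, `[[`, character(1), "model"),
               tau_slow = vapply(rows, `[[`, numeric(1), "tau_slow"),
               tau_fast = vapply(rows, `[[`, numeric(1), "tau_fast"),
               percent_recovery = vapply(rows, `[[`, numeric(1),
                                         "percent_recovery"),
               state = f$states, stringsAsFactors = FALSE)
  }))
  rownames(flat) <- NULL
  ensemble <- summarize_ensemble(unlist(lapply(fits, function(f)
    c(list(f$full), f$half)), recursive = FALSE))
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(ensemble = file.path(config$out_dir, "frap_ensemble.tsv"),
                  fits = file.path(config$out_dir, "frap_fits.json"))
    write_tsv_with_header(flat, paths$ensemble,
                          list(solid_cutoff = config$solid_cutoff %||% 20,
                               liquid_tau_cutoff =
                                 config$liquid_tau_cutoff %||% 2))
    jsonlite::write_json(
      list(metadata = list(
             version = as.character(utils::packageVersion("idrproteo")),
             solid_cutoff = config$solid_cutoff %||% 20,
             liquid_tau_cutoff = config$liquid_tau_cutoff %||% 2),
           fits = lapply(fits, function(f) {
             list(sample = f$sample, full = unclass(f$full),
                  half = lapply(f$half, unclass), states = f$states)
           }),
           ensemble = ensemble),
      paths$fits, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(list(fits = fits, table = flat, ensemble = ensemble,
                 paths = paths))
}

#' Run the spectral-count quantification pipeline
#'
#' Stage order is fixed: target-decoy FDR filtering (when PSMs are given;
#' skipped with a logged notice otherwise), parsimony reduction, detection
#' flags, shared-count distribution, dNSAF, and bait-versus-mock enrichment.
#' Writes a dNSAF matrix TSV, a presence matrix TSV (detected x bait-run
#' grid), and an enrichment TSV.
#'
#' @param config Named list: `counts` (a [count_table()]) or
#'   `protein_tsv`/`peptide_tsv` paths plus `runs`; optional `psms`
#'   ([psm_table()] or TSV path), `fdr_target` (0.01), `fdr_levels`
#'   (default all three of spectral/peptide/protein, applied in sequence),
#'   `min_peptides` (2), `length_overrides`, `pseudocount`, `out_dir`,
#'   `quiet`.
#' @return Invisibly, list with `fdr` (per-level reports), `parsimony`
#'   report, `quant`, `enrichment`, `presence`, `paths`.
#' @export
run_quant <- function(config) {
  table <- if (!is.null(config$counts)) config$counts
           else if (!is.null(config$protein_tsv)) {
             read_count_tables(config$protein_tsv, config$peptide_tsv,
                               config$runs)
           } else stop("run_quant: supply config$counts or TSV paths",
                       call. = FALSE)
  fdr_reports <- NULL
  if (!is.null(config$psms)) {
    psms <- if (inherits(config$psms, "psm_table")) config$psms
            else read_psm_tsv(config$psms)
    levels <- config$fdr_levels %||% c("spectral", "peptide", "protein")
    fdr_reports <- list()
    for (lv in levels) {
      flt <- fdr_filter(psms, config$fdr_target %||% 0.01, lv)
      log_stage(config$quiet,
                "quant: FDR filter (%s) retained %d/%d PSMs (achieved %.3g)",
                lv, flt$n_retained, nrow(psms), flt$achieved_fdr)
      psms <- flt$psms
      fdr_reports[[lv]] <- flt[c("threshold", "achieved_fdr", "n_retained",
                                 "estimator")]
    }
    config$filtered_psms <- psms
  } else {
    log_stage(config$quiet, "quant: no PSM table supplied; FDR stage skipped")
  }
  pr <- parsimony_reduce(table)
  log_stage(config$quiet, "quant: parsimony kept %d of %d proteins",
            nrow(pr$table$proteins), nrow(table$proteins))
  table <- pr$table
  detected <- detection_flags(table, config$min_peptides %||% 2L)
  quant <- dnsaf(table, length_overrides = config$length_overrides,
                 zero_unique = config$zero_unique %||% "equal")
  enr <- enrich_vs_mock(quant, pseudocount = config$pseudocount,
                        seed = config$seed %||% 1L)
  bait_runs <- table$runs$run_id[table$runs$condition == "bait"]
  presence <- sapply(bait_runs, function(r) {
    as.integer(quant$detected & quant$distributed[, r] > 0)
  })
  if (is.null(dim(presence))) presence <- matrix(presence, ncol = length(bait_runs))
  dimnames(presence) <- list(rownames(quant$dnsaf), bait_runs)
  log_stage(config$quiet, "quant: %d detected proteins; %d enriched at log2FC>1",
            sum(quant$detected), sum(enr$log2_fc > 1))
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(dnsaf = file.path(config$out_dir, "dnsaf_matrix.tsv"),
                  presence = file.path(config$out_dir, "presence_matrix.tsv"),
                  enrichment = file.path(config$out_dir, "enrichment.tsv"))
    cfg_flat <- config[vapply(config, function(x)
      is.atomic(x) && length(x) == 1L, logical(1))]
    write_tsv_with_header(
      cbind(protein = rownames(quant$dnsaf), as.data.frame(quant$dnsaf)),
      paths$dnsaf, cfg_flat)
    write_tsv_with_header(
      cbind(protein = rownames(presence), as.data.frame(presence)),
      paths$presence, cfg_flat)
    enr_out <- as.data.frame(enr)
    write_tsv_with_header(enr_out, paths$enrichment,
                          c(cfg_flat, list(
                            enrichment_method = attr(enr, "method"),
                            pseudocount = attr(enr, "pseudocount"))))
  }
  invisible(list(fdr = fdr_reports, parsimony = pr$report, quant = quant,
                 enrichment = enr, presence = presence, paths = paths))
}
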