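#' Construct a PSM table
#'
#' Peptide-spectrum matches with search scores and target/decoy labels.
#' Decoy status must be consistent within a protein id (decoy PSMs map only
#' to decoy proteins).
#'
#' @param psm_id Character vector of PSM identifiers.
#' @param score Numeric search scores (higher is better).
#' @param peptide Peptide sequence per PSM.
#' @param proteins List of character vectors (protein ids per PSM) or a
#'   semicolon-joined character vector.
#' @param is_decoy Logical vector.
#' @return A data.frame of class `psm_table` with a `proteins` list-column.
#' @export
psm_table <- function(psm_id, score, peptide, proteins, is_decoy) {
  if (is.character(proteins)) proteins <- strsplit(proteins, ";", fixed = TRUE)
  stopifnot(length(psm_id) == length(score),
            length(peptide) == length(score),
            length(proteins) == length(score),
            length(is_decoy) == length(score))
  if (any(lengths(proteins) == 0L)) {
    stop("psm_table: every PSM must map to at least one protein", call. = FALSE)
  }
  df <- data.frame(psm_id = psm_id, score = as.numeric(score),
                   peptide = peptide, is_decoy = as.logical(is_decoy),
                   stringsAsFactors = FALSE)
  df$proteins <- proteins
  structure(df, class = c("psm_table", "data.frame"))
}

#' Read a PSM table from TSV
#' @param path TSV with columns psm_id, score, peptide, proteins
#'   (semicolon-joined), is_decoy.
#' @return A `psm_table`.
#' @export
read_psm_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  psm_table(df$psm_id, df$score, df$peptide, df$proteins,
            as.logical(df$is_decoy))
}

#' Write a PSM table to TSV
#' @param psms A `psm_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_psm_tsv <- function(psms, path) {
  out <- as.data.frame(psms[, c("psm_id", "score", "peptide", "is_decoy")])
  out$proteins <- vapply(psms$proteins, paste, character(1), collapse = ";")
  utils::write.table(out[, c("psm_id", "score", "peptide", "proteins",
                             "is_decoy")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Best score per entity (peptide or protein) with the entity's decoy label.
entity_scores <- function(psms, level) {
  if (level == "peptide") {
    key <- psms$peptide
    decoy <- psms$is_decoy
    agg <- tapply(psms$score, key, max)
    dec <- tapply(decoy, key, any)
    data.frame(score = as.numeric(agg), is_decoy = as.logical(dec))
  } else { # protein
    expanded <- data.frame(
      protein = unlist(psms$proteins),
      score = rep(psms$score, lengths(psms$proteins)),
      is_decoy = rep(psms$is_decoy, lengths(psms$proteins)),
      stringsAsFactors = FALSE)
    agg <- tapply(expanded$score, expanded$protein, max)
    dec <- tapply(expanded$is_decoy, expanded$protein, any)
    data.frame(score = as.numeric(agg), is_decoy = as.logical(dec))
  }
}

#' Target-decoy FDR filtering
#'
#' Finds the most permissive score threshold (among observed scores) at
#' which the decoy-estimated FDR is at most `target_fdr`, then retains all
#' PSMs scoring at or above it. The FDR estimator is `#decoy / #target`
#' among entities at or above the threshold (DTASelect-style); at the
#' `"peptide"` and `"protein"` levels entities are aggregated by their
#' best-scoring member before counting. If no threshold attains the target,
#' an empty table is returned (no error) with the report showing the best
#' achievable FDR.
#'
#' @param psms A [psm_table()].
#' @param target_fdr Target FDR in (0, 1), e.g. 0.01.
#' @param level `"spectral"`, `"peptide"`, or `"protein"`.
#' @return List with `psms` (filtered `psm_table`), `threshold`,
#'   `achieved_fdr`, `n_retained`, `level`, and `estimator = "decoy/target"`.
#' @export
fdr_filter <- function(psms, target_fdr = 0.01,
                       level = c("spectral", "peptide", "protein")) {
  level <- match.arg(level)
  stopifnot(target_fdr > 0, target_fdr < 1)
  ent <- if (level == "spectral") {
    data.frame(score = psms$score, is_decoy = psms$is_decoy)
  } else {
    entity_scores(psms, level)
  }
  o <- order(ent$score, decreasing = TRUE)
  dec <- cumsum(ent$is_decoy[o])
  tar <- cumsum(!ent$is_decoy[o])
  fdr_at <- ifelse(tar == 0, ifelse(dec == 0, 0, Inf), dec / tar)
  # candidate thresholds: each observed entity score, scanning from strict
  # to permissive; ties share the fate of the lowest-ranked tied entity
  scores_sorted <- ent$score[o]
  # a threshold is valid only at positions where all tied entities included
  valid_idx <- which(fdr_at <= target_fdr &
                       (seq_along(scores_sorted) == length(scores_sorted) |
                          scores_sorted != c(scores_sorted[-1L], NA)))
  if (length(valid_idx) == 0L) {
    empty <- psms[0L, , drop = FALSE]
    return(list(psms = empty, threshold = Inf,
                achieved_fdr = suppressWarnings(min(fdr_at)),
                n_retained = 0L, level = level, estimator = "decoy/target"))
  }
  cut_i <- max(valid_idx)
  threshold <- scores_sorted[cut_i]
  keep <- psms$score >= threshold
  list(psms = psms[keep, , drop = FALSE], threshold = threshold,
       achieved_fdr = fdr_at[cut_i], n_retained = sum(keep),
       level = level, estimator = "decoy/target")
}

#' Construct a spectral-count table
#'
#' Peptide-level spectral counts for a set of runs, with the peptide-to-
#' protein map needed for parsimony, detection flags, and distributed
#' counts.
#'
#' @param proteins data.frame with columns `id`, `length` (residues),
#'   `is_contaminant` (logical; optional, defaults to FALSE).
#' @param runs data.frame with columns `run_id`, `condition` (`"bait"` or
#'   `"mock"`), `replicate`.
#' @param peptides data.frame with columns `peptide`, `proteins` (semicolon-
#'   joined ids or list-column), plus one integer count column per `run_id`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(proteins, runs, peptides) {
  stopifnot(all(c("id", "length") %in% names(proteins)),
            all(c("run_id", "condition") %in% names(runs)))
  if (is.null(proteins$is_contaminant)) proteins$is_contaminant <- FALSE
  if (any(proteins$length <= 0)) {
    stop("count_table: protein lengths must be positive", call. = FALSE)
  }
  if (!all(runs$condition %in% c("bait", "mock"))) {
    stop("count_table: run condition must be 'bait' or 'mock'", call. = FALSE)
  }
  if (is.character(peptides$proteins)) {
    peptides$proteins <- strsplit(peptides$proteins, ";", fixed = TRUE)
  }
  missing_runs <- setdiff(runs$run_id, names(peptides))
  if (length(missing_runs) > 0L) {
    stop("count_table: peptide table lacks count columns for runs: ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  }
  cnt <- as.matrix(peptides[, runs$run_id, drop = FALSE])
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("count_table: counts must be non-negative integers", call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(peptides$proteins)), proteins$id)
  if (length(unknown) > 0L) {
    stop("count_table: peptides map to unknown proteins: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(proteins = proteins, runs = runs,
                 peptides = peptides$peptide,
                 peptide_proteins = peptides$proteins,
                 counts = cnt),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d proteins, %d peptides, %d runs (%d bait, %d mock)\n",
              nrow(x$proteins), length(x$peptides), nrow(x$runs),
              sum(x$runs$condition == "bait"), sum(x$runs$condition == "mock")))
  invisible(x)
}

# Peptide set per protein: peptides with a nonzero count in any run.
protein_peptide_sets <- function(table) {
  observed <- rowSums(table$counts) > 0
  sets <- lapply(table$proteins$id, function(pid) {
    sort(table$peptides[observed &
                          vapply(table$peptide_proteins,
                                 function(ps) pid %in% ps, logical(1))])
  })
  names(sets) <- table$proteins$id
  sets
}

#' Parsimony reduction of a count table
#'
#' Removes proteins whose observed peptide set is a strict subset of another
#' protein's set, and merges proteins with identical peptide sets into one
#' group represented by the lexicographically smallest id (a deterministic
#' stand-in for an arbitrary representative). Counts are re-attributed to
#' the survivors through the peptide map. Proteins with no observed peptides
#' are dropped.
#'
#' @param table A [count_table()].
#' @return List with `table` (reduced `count_table`) and `report`, a
#'   data.frame with columns `protein`, `status`
#'   (`kept` / `removed_subset` / `merged` / `no_peptides`), `representative`.
#' @export
parsimony_reduce <- function(table) {
  sets <- protein_peptide_sets(table)
  ids <- names(sets)
  n <- length(ids)
  status <- rep("kept", n)
  representative <- ids
  status[lengths(sets) == 0L] <- "no_peptides"
  representative[status == "no_peptides"] <- ""
  for (i in seq_len(n)) {
    if (status[i] != "kept") next
    for (j in seq_len(n)) {
      if (i == j || status[j] == "no_peptides") next
      if (length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])) {
        status[i] <- "removed_subset"
        representative[i] <- ""
        break
      }
    }
  }
  # group identical sets among remaining proteins
  keep_idx <- which(status == "kept")
  keys <- vapply(sets[keep_idx], paste, character(1), collapse = "\r")
  for (k in unique(keys)) {
    members <- keep_idx[keys == k]
    if (length(members) > 1L) {
      rep_id <- min(ids[members])
      for (m in members) {
        representative[m] <- rep_id
        if (ids[m] != rep_id) status[m] <- "merged"
      }
    }
  }
  survivors <- ids[status == "kept"]
  new_prot <- table$proteins[table$proteins$id %in% survivors, , drop = FALSE]
  remap <- stats::setNames(representative, ids)
  new_pp <- lapply(table$peptide_proteins, function(ps) {
    mapped <- unique(remap[ps])
    mapped[nzchar(mapped)]
  })
  nonempty <- lengths(new_pp) > 0L
  peptides_df <- data.frame(peptide = table$peptides[nonempty],
                            stringsAsFactors = FALSE)
  peptides_df$proteins <- new_pp[nonempty]
  peptides_df <- cbind(peptides_df,
                       as.data.frame(table$counts[nonempty, , drop = FALSE]))
  reduced <- count_table(new_prot, table$runs, peptides_df)
  list(table = reduced,
       report = data.frame(protein = ids, status = status,
                           representative = representative,
                           stringsAsFactors = FALSE))
}

#' Per-protein detection flags (>= 2 distinct peptides across replicates)
#'
#' A protein counts as detected when, combining all runs, it was observed
#' with at least `min_peptides` distinct peptides. This flag drives the
#' presence matrix (detected-by-bait grid).
#'
#' @param table A [count_table()].
#' @param min_peptides Minimum distinct peptides (default 2).
#' @return Named logical vector over `table$proteins$id`.
#' @export
detection_flags <- function(table, min_peptides = 2L) {
  sets <- protein_peptide_sets(table)
  stats::setNames(lengths(sets) >= min_peptides, names(sets))
}

#' Distribute shared-peptide counts among proteins
#'
#' For each run, each shared peptide's spectral counts are split among its
#' proteins in proportion to the proteins' unique-peptide counts in that
#' run; when none of the sharing proteins has unique evidence the counts are
#' split equally (configurable to `"drop"` them instead). The distributed
#' count of a protein is its unique count plus its allocations, so per-run
#' totals are conserved exactly (under `"equal"`).
#'
#' @param table A [count_table()].
#' @param zero_unique `"equal"` (default) or `"drop"`: how to allocate a
#'   shared peptide when all sharing proteins lack unique counts.
#' @return Numeric matrix (protein x run) of distributed counts.
#' @export
distribute_shared_counts <- function(table, zero_unique = c("equal", "drop")) {
  zero_unique <- match.arg(zero_unique)
  ids <- table$proteins$id
  nruns <- nrow(table$runs)
  shared <- lengths(table$peptide_proteins) > 1L
  prot_index <- stats::setNames(seq_along(ids), ids)
  unique_counts <- matrix(0, length(ids), nruns,
                          dimnames = list(ids, table$runs$run_id))
  for (p in which(!shared)) {
    i <- prot_index[[table$peptide_proteins[[p]][1L]]]
    unique_counts[i, ] <- unique_counts[i, ] + table$counts[p, ]
  }
  dist <- unique_counts
  for (p in which(shared)) {
    members <- prot_index[table$peptide_proteins[[p]]]
    for (r in seq_len(nruns)) {
      c_pr <- table$counts[p, r]
      if (c_pr == 0) next
      u <- unique_counts[members, r]
      if (sum(u) > 0) {
        dist[members, r] <- dist[members, r] + c_pr * u / sum(u)
      } else if (zero_unique == "equal") {
        dist[members, r] <- dist[members, r] + c_pr / length(members)
      }
    }
  }
  dist
}

#' Distributed NSAF quantification
#'
#' Computes, per run, the spectral abundance factor
#' `SAF_i = distributed_count_i / L_i` and normalizes it across proteins:
#' `dNSAF_i = SAF_i / sum_j SAF_j`, so each run's dNSAF column sums to 1.
#' Length normalization matters because longer proteins yield more peptides;
#' deletion-mutant baits should be quantified with their construct lengths,
#' supplied via `length_overrides` (e.g. a 601-residue bait fragment rather
#' than the 2564-residue full-length protein). Contaminants are excluded
#' from the denominator (and the output) by default.
#'
#' @param table A [count_table()].
#' @param length_overrides Named numeric vector, id -> length in residues.
#' @param include_contaminants Keep contaminant rows in the normalization.
#' @param zero_unique Passed to [distribute_shared_counts()].
#' @return A `quant_result`: list with `dnsaf` (protein x run matrix),
#'   `distributed` counts, `lengths`, `detected`, `n_peptides`, `runs`.
#' @export
dnsaf <- function(table, length_overrides = NULL,
                  include_contaminants = FALSE,
                  zero_unique = c("equal", "drop")) {
  dist <- distribute_shared_counts(table, match.arg(zero_unique))
  lens <- stats::setNames(as.numeric(table$proteins$length), table$proteins$id)
  if (!is.null(length_overrides)) {
    bad <- setdiff(names(length_overrides), names(lens))
    if (length(bad) > 0L) {
      stop("dnsaf: length_overrides for unknown proteins: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(length_overrides <= 0)) {
      stop("dnsaf: overridden lengths must be positive", call. = FALSE)
    }
    lens[names(length_overrides)] <- length_overrides
  }
  keep <- if (include_contaminants) rep(TRUE, nrow(table$proteins))
          else !table$proteins$is_contaminant
  dist_k <- dist[keep, , drop = FALSE]
  saf <- dist_k / lens[keep]
  totals <- colSums(saf)
  dn <- saf
  for (r in seq_along(totals)) {
    if (totals[r] > 0) {
      dn[, r] <- saf[, r] / totals[r]
    } else {
      dn[, r] <- 0
      warning("dnsaf: run '", table$runs$run_id[r],
              "' has zero total counts; dNSAF column set to 0")
    }
  }
  sets <- protein_peptide_sets(table)
  structure(list(dnsaf = dn, distributed = dist_k,
                 lengths = lens[keep],
                 detected = detection_flags(table)[keep],
                 n_peptides = lengths(sets)[keep],
                 runs = table$runs),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %d proteins x %d runs; %d detected (>=2 peptides)\n",
              nrow(x$dnsaf), ncol(x$dnsaf), sum(x$detected)))
  invisible(x)
}

#' Bait-versus-mock enrichment (pseudocount log-ratio + permutation test)
#'
#' A deliberately simple enrichment statistic (not QPROT's Bayesian model):
#' `log2((mean bait dNSAF + eps) / (mean mock dNSAF + eps))` with a
#' condition-label permutation p-value. With 10 or fewer runs every distinct
#' bait/mock label assignment is enumerated; otherwise `n_perm` assignments
#' are sampled with `seed`. The default pseudocount is half the smallest
#' nonzero dNSAF in the dataset (scale-free).
#'
#' @param quant A `quant_result` from [dnsaf()].
#' @param pseudocount Positive stabilizer `eps`; default as described.
#' @param n_perm Number of sampled permutations when exhaustive enumeration
#'   is infeasible.
#' @param seed Seed for sampled permutations.
#' @return data.frame of class `enrichment_result`: `protein`, `log2_fc`,
#'   `p_value`, `mean_bait`, `mean_mock`, plus attribute
#'   `method = "pseudocount log2 ratio + label permutation (non-QPROT)"`.
#' @export
enrich_vs_mock <- function(quant, pseudocount = NULL, n_perm = 1000L,
                           seed = 1L) {
  cond <- quant$runs$condition
  if (!any(cond == "bait") || !any(cond == "mock")) {
    stop("enrich_vs_mock: need at least one bait and one mock run",
         call. = FALSE)
  }
  dn <- quant$dnsaf
  if (is.null(pseudocount)) {
    nz <- dn[dn > 0]
    pseudocount <- if (length(nz) > 0L) min(nz) / 2 else 1e-6
  }
  stopifnot(pseudocount > 0)
  stat <- function(is_bait) {
    log2((rowMeans(dn[, is_bait, drop = FALSE]) + pseudocount) /
           (rowMeans(dn[, !is_bait, drop = FALSE]) + pseudocount))
  }
  obs_bait <- cond == "bait"
  obs <- stat(obs_bait)
  nruns <- length(cond)
  nb <- sum(obs_bait)
  if (nruns <= 10L) {
    assignments <- utils::combn(nruns, nb, simplify = FALSE)
  } else {
    assignments <- with_local_seed(seed, {
      lapply(seq_len(n_perm), function(i) sample.int(nruns, nb))
    })
  }
  exceed <- rep(0L, nrow(dn))
  for (a in assignments) {
    is_bait <- seq_len(nruns) %in% a
    exceed <- exceed + (abs(stat(is_bait)) >= abs(obs) - 1e-12)
  }
  p <- exceed / length(assignments)
  res <- data.frame(protein = rownames(dn), log2_fc = unname(obs),
                    p_value = unname(p),
                    mean_bait = unname(rowMeans(dn[, obs_bait, drop = FALSE])),
                    mean_mock = unname(rowMeans(dn[, !obs_bait, drop = FALSE])),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$log2_fc), ]
  rownames(res) <- NULL
  structure(res,
            method = "pseudocount log2 ratio + label permutation (non-QPROT)",
            pseudocount = pseudocount,
            class = c("enrichment_result", "data.frame"))
}

#' Read a count-table TSV pair
#'
#' @param protein_path TSV: `id`, `length`, optional `is_contaminant`.
#' @param peptide_path TSV: `peptide`, `proteins` (semicolon-joined), one
#'   count column per run.
#' @param runs data.frame with `run_id`, `condition`, `replicate`; if NULL,
#'   every count column is treated as a bait run.
#' @return A [count_table()].
#' @export
read_count_tables <- function(protein_path, peptide_path, runs = NULL) {
  prot <- utils::read.table(protein_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "#")
  pep <- utils::read.table(peptide_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(runs)) {
    run_cols <- setdiff(names(pep), c("peptide", "proteins"))
    runs <- data.frame(run_id = run_cols, condition = "bait",
                       replicate = seq_along(run_cols),
                       stringsAsFactors = FALSE)
  }
  count_table(prot, runs, pep)
}
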