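# Small hand-built count table used across several tests:
# A: unique p1 (6 counts) + shared p2 with B (10 counts)
# B: shares p2 only; C, D share p3 (8 counts) with no unique evidence
small_table <- function() {
  peptides <- data.frame(peptide = c("p1", "p2", "p3"),
                         stringsAsFactors = FALSE)
  peptides$proteins <- list("A", c("A", "B"), c("C", "D"))
  peptides$run1 <- c(6L, 10L, 8L)
  count_table(
    proteins = data.frame(id = c("A", "B", "C", "D"),
                          length = c(100, 200, 400, 400),
                          is_contaminant = FALSE, stringsAsFactors = FALSE),
    runs = data.frame(run_id = "run1", condition = "bait", replicate = 1,
                      stringsAsFactors = FALSE),
    peptides = peptides)
}

test_that("FDR filter handles decoy-free and decoy-only extremes", {
  all_target <- psm_table(sprintf("s%d", 1:5), c(5, 4, 3, 2, 1),
                          sprintf("pep%d", 1:5), as.list(sprintf("P%d", 1:5)),
                          rep(FALSE, 5))
  res <- fdr_filter(all_target, 0.01, "spectral")
  expect_equal(res$n_retained, 5L)
  expect_equal(res$achieved_fdr, 0)
  all_decoy <- psm_table(sprintf("s%d", 1:5), c(5, 4, 3, 2, 1),
                         sprintf("pep%d", 1:5), as.list(sprintf("D%d", 1:5)),
                         rep(TRUE, 5))
  res2 <- fdr_filter(all_decoy, 0.01, "spectral")
  expect_equal(res2$n_retained, 0L)
  expect_equal(nrow(res2$psms), 0L)
})

test_that("FDR threshold equals exhaustive search and achieved FDR <= target", {
  set.seed(14)
  for (i in 1:40) {
    n <- 200
    g <- gen_psm_table(n_targets = n / 2, n_decoys = n / 2, target_mean = 3,
                       decoy_mean = 0, seed = i)
    res <- fdr_filter(g$psms, 0.05, "spectral")
    exp_thr <- brute_fdr_threshold(g$psms$score, g$psms$is_decoy, 0.05)
    expect_equal(res$threshold, exp_thr)
    expect_lte(res$achieved_fdr, 0.05)
    # retained set is exactly scores >= threshold
    expect_equal(res$n_retained, sum(g$psms$score >= exp_thr))
  }
})

test_that("peptide/protein level FDR aggregates by best-scoring member", {
  psms <- psm_table(sprintf("s%d", 1:6),
                    c(10, 9, 1, 8, 7, 6.5),
                    c("pepA", "pepA", "pepA", "pepB", "pepD1", "pepD2"),
                    list("T1", "T1", "T1", "T2", "D1", "D2"),
                    c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # at peptide level: entities pepA(10), pepB(8), pepD1(7), pepD2(6.5)
  res <- fdr_filter(psms, 0.4, "peptide")
  # thresholds: >=10 -> 0/1; >=8 -> 0/2; >=7 -> 1/2 = 0.5 > 0.4
  expect_equal(res$threshold, 8)
  res_p <- fdr_filter(psms, 0.6, "protein")
  # protein entities: T1(10), T2(8), D1(7), D2(6.5); >=7: 1/2 <= 0.6
  expect_equal(res_p$threshold, 7)
  expect_equal(res_p$achieved_fdr, 0.5)
})

test_that("parsimony removes strict subsets and merges identical sets", {
  peptides <- data.frame(peptide = c("p1", "p2"), stringsAsFactors = FALSE)
  peptides$proteins <- list(c("A", "B"), "A")
  peptides$r1 <- c(3L, 2L)
  tb <- count_table(
    proteins = data.frame(id = c("A", "B"), length = c(100, 100),
                          stringsAsFactors = FALSE),
    runs = data.frame(run_id = "r1", condition = "bait", replicate = 1),
    peptides = peptides)
  pr <- parsimony_reduce(tb)
  expect_equal(pr$table$proteins$id, "A")  # B {p1} is a strict subset of A {p1,p2}
  expect_equal(pr$report$status[pr$report$protein == "B"], "removed_subset")

  # identical sets merge to the lexicographically smallest id
  peptides2 <- data.frame(peptide = c("p1", "p2"), stringsAsFactors = FALSE)
  peptides2$proteins <- list(c("Z", "M"), c("Z", "M"))
  peptides2$r1 <- c(3L, 2L)
  tb2 <- count_table(
    proteins = data.frame(id = c("Z", "M"), length = c(100, 100),
                          stringsAsFactors = FALSE),
    runs = data.frame(run_id = "r1", condition = "bait", replicate = 1),
    peptides = peptides2)
  pr2 <- parsimony_reduce(tb2)
  expect_equal(pr2$table$proteins$id, "M")
  expect_equal(pr2$report$representative, c("M", "M"))
})

test_that("parsimony equals exhaustive subset analysis on random instances", {
  set.seed(31)
  for (i in 1:120) {
    np <- sample(2:8, 1)
    npep <- sample(2:10, 1)
    ids <- sprintf("P%02d", seq_len(np))
    peps <- sprintf("q%02d", seq_len(npep))
    owner <- lapply(seq_len(npep), function(j) {
      sort(sample(ids, sample(1:min(3, np), 1)))
    })
    pdf <- data.frame(peptide = peps, stringsAsFactors = FALSE)
    pdf$proteins <- owner
    pdf$r1 <- sample(1:5, npep, replace = TRUE)
    tb <- count_table(
      proteins = data.frame(id = ids, length = 100, stringsAsFactors = FALSE),
      runs = data.frame(run_id = "r1", condition = "bait", replicate = 1),
      peptides = pdf)
    got <- sort(parsimony_reduce(tb)$table$proteins$id)
    sets <- lapply(ids, function(p) {
      sort(peps[vapply(owner, function(o) p %in% o, logical(1))])
    })
    names(sets) <- ids
    expect_equal(got, sort(brute_parsimony_survivors(sets)), info = i)
  }
})

test_that("parsimony is idempotent, keeps unique-peptide proteins, and preserves detection", {
  set.seed(77)
  for (i in 1:20) {
    g <- gen_count_table(n_proteins = 20, shared_fraction = 0.4, seed = i)
    pr <- parsimony_reduce(g$table)
    pr2 <- parsimony_reduce(pr$table)
    expect_equal(sort(pr2$table$proteins$id), sort(pr$table$proteins$id))
    # a protein with a unique observed peptide is never removed as a subset
    unique_owners <- unique(unlist(
      g$table$peptide_proteins[lengths(g$table$peptide_proteins) == 1L &
                                 rowSums(g$table$counts) > 0]))
    removed <- pr$report$protein[pr$report$status == "removed_subset"]
    expect_length(intersect(unique_owners, removed), 0L)
    # detection flags agree for survivors computed before/after reduction
    before <- detection_flags(g$table)
    after <- detection_flags(pr$table)
    expect_equal(unname(after), unname(before[names(after)]))
  }
})

test_that("detection requires >= 2 distinct peptides across all replicates", {
  peptides <- data.frame(peptide = c("p1", "p2", "p3"),
                         stringsAsFactors = FALSE)
  peptides$proteins <- list("A", "A", "B")
  peptides$rep1 <- c(2L, 0L, 1L)
  peptides$rep2 <- c(0L, 1L, 0L)
  tb <- count_table(
    proteins = data.frame(id = c("A", "B"), length = c(100, 100),
                          stringsAsFactors = FALSE),
    runs = data.frame(run_id = c("rep1", "rep2"), condition = "bait",
                      replicate = 1:2),
    peptides = peptides)
  fl <- detection_flags(tb)
  expect_true(fl[["A"]])   # p1 in rep1 plus p2 in rep2: union counts
  expect_false(fl[["B"]])  # single peptide only
  expect_true(detection_flags(tb, min_peptides = 1L)[["B"]])
})

test_that("shared counts distribute proportionally to unique evidence", {
  dist <- distribute_shared_counts(small_table())
  expect_equal(dist["A", "run1"], 16)   # 6 unique + all 10 shared (B has none)
  expect_equal(dist["B", "run1"], 0)
  expect_equal(dist["C", "run1"], 4)    # equal share of 8
  expect_equal(dist["D", "run1"], 4)
  # conservation: distributed totals equal raw totals
  expect_equal(sum(dist), 24)
  # drop mode discards the zero-unique shared peptide
  dist2 <- distribute_shared_counts(small_table(), zero_unique = "drop")
  expect_equal(sum(dist2), 16)
  expect_equal(dist2["C", "run1"], 0)
})

test_that("3:1 unique evidence splits a shared peptide 7.5 / 2.5", {
  peptides <- data.frame(peptide = c("u1", "u2", "sh"),
                         stringsAsFactors = FALSE)
  peptides$proteins <- list("A", "B", c("A", "B"))
  peptides$r1 <- c(3L, 1L, 10L)
  tb <- count_table(
    proteins = data.frame(id = c("A", "B"), length = c(100, 100),
                          stringsAsFactors = FALSE),
    runs = data.frame(run_id = "r1", condition = "bait", replicate = 1),
    peptides = peptides)
  dist <- distribute_shared_counts(tb)
  expect_equal(dist["A", "r1"], 3 + 7.5)
  expect_equal(dist["B", "r1"], 1 + 2.5)
})

test_that("dNSAF normalizes per run, weights by length, and handles edge cases", {
  # single protein
  pdf <- data.frame(peptide = "p1", stringsAsFactors = FALSE)
  pdf$proteins <- list("A"); pdf$r1 <- 5L
  one <- count_table(
    proteins = data.frame(id = "A", length = 300, stringsAsFactors = FALSE),
    runs = data.frame(run_id = "r1", condition = "bait", replicate = 1),
    peptides = pdf)
  expect_equal(unname(dnsaf(one)$dnsaf[, "r1"]), 1)

  # equal counts, lengths L and L/2 -> dNSAF 1/3 and 2/3
  pdf2 <- data.frame(peptide = c("p1", "p2"), stringsAsFactors = FALSE)
  pdf2$proteins <- list("A", "B"); pdf2$r1 <- c(4L, 4L)
  two <- count_table(
    proteins = data.frame(id = c("A", "B"), length = c(400, 200),
                          stringsAsFactors = FALSE),
    runs = data.frame(run_id = "r1", condition = "bait", replicate = 1),
    peptides = pdf2)
  q <- dnsaf(two)
  expect_equal(unname(q$dnsaf[, "r1"]), c(1 / 3, 2 / 3), tolerance = 1e-12)

  # length overrides emulate deletion-mutant bait lengths
  q2 <- dnsaf(two, length_overrides = c(A = 200))
  expect_equal(unname(q2$dnsaf[, "r1"]), c(0.5, 0.5), tolerance = 1e-12)
  expect_error(dnsaf(two, length_overrides = c(ZZ = 100)), "unknown")

  # scaling all counts leaves dNSAF unchanged
  pdf3 <- pdf2; pdf3$r1 <- pdf2$r1 * 10L
  two10 <- count_table(two$proteins,
                       data.frame(run_id = "r1", condition = "bait",
                                  replicate = 1),
                       pdf3)
  expect_equal(dnsaf(two10)$dnsaf, q$dnsaf, tolerance = 1e-12)

  # zero-count run warns and yields a zero column
  pdf4 <- pdf2; pdf4$r1 <- c(0L, 0L)
  zero <- count_table(two$proteins,
                      data.frame(run_id = "r1", condition = "bait",
                                 replicate = 1), pdf4)
  expect_warning(qz <- dnsaf(zero), "zero total")
  expect_equal(unname(qz$dnsaf[, "r1"]), c(0, 0))
})

test_that("hand-worked shared-count example matches to 1e-12", {
  q <- dnsaf(small_table())
  # distributed: A=16, B=0, C=4, D=4; SAF = c(16/100, 0, 4/400, 4/400)
  saf <- c(16 / 100, 0, 4 / 400, 4 / 400)
  expect_equal(unname(q$dnsaf[, "run1"]), saf / sum(saf), tolerance = 1e-12)
  expect_equal(sum(q$dnsaf[, "run1"]), 1, tolerance = 1e-12)
})

test_that("contaminants are excluded from the dNSAF denominator by default", {
  pdf <- data.frame(peptide = c("p1", "p2"), stringsAsFactors = FALSE)
  pdf$proteins <- list("A", "KRT1"); pdf$r1 <- c(4L, 4L)
  tb <- count_table(
    proteins = data.frame(id = c("A", "KRT1"), length = c(100, 100),
                          is_contaminant = c(FALSE, TRUE),
                          stringsAsFactors = FALSE),
    runs = data.frame(run_id = "r1", condition = "bait", replicate = 1),
    peptides = pdf)
  expect_equal(unname(dnsaf(tb)$dnsaf[, "r1"]), 1)
  expect_equal(unname(dnsaf(tb, include_contaminants = TRUE)$dnsaf[, "r1"]),
               c(0.5, 0.5))
})

test_that("enrichment is symmetric under identical profiles and signed correctly", {
  g <- gen_count_table(n_proteins = 30, enriched_fraction = 0, seed = 5)
  q <- dnsaf(g$table)
  # make bait and mock literally identical: copy mock columns over bait
  q$dnsaf[, 1:2] <- q$dnsaf[, 3:4]
  enr <- enrich_vs_mock(q)
  expect_true(all(abs(enr$log2_fc) < 1e-12))
  # a protein present only in bait has positive log2 FC bounded by pseudocount
  q2 <- dnsaf(g$table)
  q2$dnsaf["P0001", ] <- c(0.2, 0.2, 0, 0)
  enr2 <- enrich_vs_mock(q2, pseudocount = 0.01)
  row <- enr2[enr2$protein == "P0001", ]
  expect_gt(row$log2_fc, 0)
  expect_lte(row$log2_fc, log2((0.2 + 0.01) / 0.01))
  expect_error(enrich_vs_mock(dnsaf(count_table(
    proteins = data.frame(id = "A", length = 100, stringsAsFactors = FALSE),
    runs = data.frame(run_id = "r1", condition = "bait", replicate = 1),
    peptides = {
      d <- data.frame(peptide = "p1", stringsAsFactors = FALSE)
      d$proteins <- list("A"); d$r1 <- 1L; d
    }))), "mock")
})

test_that("PSM TSV round trip", {
  g <- gen_psm_table(n_targets = 20, n_decoys = 20, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_psm_tsv(g$psms, tmp)
  back <- read_psm_tsv(tmp)
  expect_equal(back$score, g$psms$score, tolerance = 1e-9)
  expect_equal(back$is_decoy, g$psms$is_decoy)
  expect_equal(back$proteins, g$psms$proteins)
})
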