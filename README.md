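# idrproteo

Tools for studying how intrinsically disordered regions (IDRs) govern
protein turnover and phase separation. Written for groups combining
sequence bioinformatics, live-cell FRAP imaging, and
affinity-purification mass spectrometry around a single substrate — the
motivating case is the 2564-residue human H3K36 methyltransferase SETD2,
whose IDR-rich N-terminal region drives its proteasomal degradation while
its C-terminal region forms liquid-like nuclear condensates.

The package covers four analyses end to end:

1. **Disorder profiling** — per-residue disorder scores (bundled
   composition-propensity scorer, or any external predictor's profile via
   TSV), the fraction of residues above the 0.5 cutoff, maximal long-IDR
   segmentation (strictly >30 residues by default), and the N/C regional
   partition of segments around a junction such as SETD2's 1403|1404
   split.
2. **Degron scanning** — PEST regions scored with the classical PEST-find
   formula (0.55 × corrected DEPST mass percent − 0.5 × mass-weighted
   Kyte–Doolittle hydrophobicity index, significance at >5), plus APC/C
   degrons: the destruction box `RxxL` and the `KEN` box.
3. **FRAP curve fitting** — full-FRAP traces fit with a single
   exponential `F(t) = plateau − (plateau − F0)·exp(−t/τ)`; half-FRAP
   traces with a double exponential whose *slow component is fixed
   exactly* to the paired full-FRAP τ (the two-stage constrained fit),
   separating internal punctum mixing (τ_fast) from nucleoplasmic
   exchange (τ_slow); liquid/gel/solid classification from percent
   recovery and τ.
4. **Spectral-count quantification** — target-decoy FDR filtering at the
   spectral/peptide/protein level, parsimony reduction, ≥2-peptide
   detection flags, distributed NSAF (`dNSAF`) with shared-peptide counts
   split by unique evidence and lengths overridable for deletion-mutant
   baits, and a labelled pseudocount log2-ratio + permutation enrichment
   versus mock controls.

Seeded generators (`gen_sequence()`, `gen_idr_architecture()`,
`gen_frap_trace()`, `gen_punctum_stack()`, `gen_count_table()`,
`gen_psm_table()`) emulate every input type with planted ground truth, so
the whole pipeline is testable offline. See the methods vignette
(`vignettes/idr-proteostasis-methods.Rmd`) for the models, parameter
defaults, and known limitations.

## Worked example

A synthetic SETD2-scale protein with a planted architecture — 17 long
disordered blocks (11 N-terminal, 5 C-terminal, 1 spanning the junction),
a PEST stretch inside 504–1403, a D box at 2033 and a KEN box at 2078 —
read back out by the sequence stages:

```r
library(idrproteo)

g <- gen_idr_architecture(seed = 1)
prof <- score_disorder(g$record)
summarize_disorder(prof, split_position = 1403)
#> <disorder_summary> synthetic-SETD2-like
#>   disordered: 1554 / 2564 residues (60.61%), threshold > 0.5
#>   long IDR segments (>= 31 aa): 17
#>   split 1403|1404: N=11, C=5, overlapping=1
#>   region 1-1403: 72.20% disordered
#>   region 1404-2564: 46.60% disordered
```

All 17 planted segments are recovered with the planted 11/5/1 partition,
and the N-terminal side is the more disordered, as constructed. The
degron scans find the planted motifs at their exact coordinates:

```r
head(pest_scan(g$record), 1)   # top candidate = the planted PEST stretch
#>   start  end length    score significant
#> 1   981 1051     71 41.40880        TRUE
kenbox_scan(g$record, region(1964, 2564))
#>             protein_id motif_type start  end matched_sequence
#> 1 synthetic-SETD2-like    KEN_box  2078 2080              KEN
```

The two-stage FRAP analysis: the full-FRAP τ is fit first, then every
half-FRAP trace is fit with the slow component fixed to it (note the
identical `tau_slow`), and both puncta classify as liquid:

```r
full <- gen_frap_trace(list(tau = 1.2, plateau = 0.9, f0 = 0.05), "full",
                       noise_sd = 0.02, seed = 2)$trace
half <- gen_frap_trace(list(tau_fast = 0.3, tau_slow = 1.2, amp_fast = 0.35,
                            amp_slow = 0.3, plateau = 0.92), "half",
                       noise_sd = 0.02, seed = 3)$trace
res <- run_frap(list(samples = list(FL = list(full = full, half = list(half))),
                     quiet = TRUE))
res$table
#>   sample  trace                  model tau_slow  tau_fast percent_recovery  state
#> 1     FL   full             single_exp 1.199003        NA         86.16694 liquid
#> 2     FL half_1 double_exp_constrained 1.199003 0.2979149         88.70429 liquid
```

The fitted τ (1.199 s vs the generating 1.2 s) and τ_fast (0.298 s vs
0.3 s) recover the planted values; percent recovery near 87% with a
sub-second τ gives the quick-recovery, liquid-droplet signature.

AP-MS quantification on a simulated 2-bait/2-mock design with 10 planted
enriched proteins at effect size 4:

```r
gq <- gen_count_table(n_proteins = 100, enriched_fraction = 0.1,
                      effect_size = 4, seed = 4)
rq <- run_quant(list(counts = gq$table, quiet = TRUE))
head(rq$enrichment, 3)
#>   protein  log2_fc   p_value   mean_bait   mean_mock
#> 1   P0068 2.684212 0.3333333 0.045678325 0.007042413
#> 2   P0052 2.575213 0.3333333 0.007517639 0.001197857
#> 3   P0097 2.133209 0.3333333 0.022115288 0.004982202
sum(gq$truth$enriched %in% rq$enrichment$protein[1:10])
#> [1] 8
```

Eight of the ten planted proteins rank in the top ten by log2 fold
change. (With 2+2 runs the permutation p-value floor is 1/6 ≈ 0.33, so at
this design size the ranking, not the p-value, carries the signal.)

A thin command-line front end over the same functions lives at
`inst/scripts/idrproteo-cli.R` (subcommands `disorder`, `quant`, `frap`,
`simulate`).

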