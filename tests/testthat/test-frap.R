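make_trace <- function(y, dt = 0.1, bleach = 4L, mode = "full") {
  frap_trace(times = (seq_along(y) - 1) * dt, intensities = y,
             bleach_index = bleach, mode = mode)
}

test_that("normalize_trace maps min/max to 0/1 and is idempotent", {
  tr <- make_trace(c(2, 4, 6, 1, 3, 5, 6, 6, 6, 6, 6, 6, 6, 6))
  nt <- normalize_trace(tr)
  expect_equal(min(nt$intensities), 0)
  expect_equal(max(nt$intensities), 1)
  expect_equal(normalize_trace(make_trace(c(2, 4, 6, 1, 1, 1, 1, 1, 1, 1,
                                            1, 1, 1, 1)))$intensities[1:3],
               c(0.2, 0.6, 1))
  expect_equal(normalize_trace(nt)$intensities, nt$intensities)
  expect_error(normalize_trace(make_trace(rep(3, 14))), "degenerate")
})

test_that("align_bleach zeroes the first post-bleach frame, times only", {
  tr <- make_trace(c(1, 1, 1, 1, 0.1, 0.3, 0.5, 0.6, 0.7, 0.7, 0.7, 0.7,
                     0.72, 0.72), bleach = 5L)
  al <- align_bleach(tr)
  expect_equal(al$times[5], 0)
  expect_equal(al$intensities, tr$intensities)
  # two traces with different bleach frames share the post-bleach grid
  tr2 <- make_trace(c(1, 1, 1, 0.1, 0.3, 0.5, 0.6, 0.7, 0.7, 0.7, 0.7, 0.72,
                      0.72, 0.73), bleach = 4L)
  both <- align_bleach(list(tr, tr2))
  g1 <- both[[1]]$times[both[[1]]$bleach_index:14]
  g2 <- both[[2]]$times[both[[2]]$bleach_index:13]
  expect_equal(g1[1:10], g2[1:10])
  tr$bleach_index <- NULL
  expect_error(align_bleach(tr), "bleach_index")
})

test_that("noiseless single-exponential fits recover generating parameters exactly", {
  for (tau in c(0.3, 1, 4)) {
    g <- gen_frap_trace(list(tau = tau, plateau = 0.9, f0 = 0), "full",
                        noise_sd = 0)
    f <- fit_full_frap(align_bleach(normalize_trace(g$trace)))
    expect_equal(f$tau_slow, tau, tolerance = 1e-6)
    expect_equal(f$plateau, 0.9, tolerance = 1e-6)
    expect_equal(f$percent_recovery, 90, tolerance = 1e-4)
    expect_true(f$converged)
  }
  # non-recovering trace: percent recovery ~ 0 (solid-aggregate signature)
  g0 <- gen_frap_trace(list(tau = 1, plateau = 0.021, f0 = 0.02), "full",
                       noise_sd = 0)
  f0 <- fit_full_frap(align_bleach(g0$trace))
  expect_lt(f0$percent_recovery, 1)
})

test_that("noiseless constrained double-exponential round trip is exact", {
  g <- gen_frap_trace(list(tau_fast = 0.2, tau_slow = 2, amp_fast = 0.3,
                           amp_slow = 0.4, plateau = 0.95), "half",
                      noise_sd = 0)
  f <- fit_half_frap(align_bleach(g$trace), full_tau = 2)
  expect_equal(f$tau_fast, 0.2, tolerance = 1e-6)
  expect_equal(f$amp_fast, 0.3, tolerance = 1e-6)
  expect_equal(f$amp_slow, 0.4, tolerance = 1e-6)
  expect_identical(f$tau_slow, 2)  # bit-exact: the constraint is structural
  expect_equal(f$model, "double_exp_constrained")
  expect_error(fit_half_frap(align_bleach(g$trace), full_tau = -1),
               "full_tau")
})

test_that("amp_fast = 0 traces reduce to the single-exponential limit", {
  g <- gen_frap_trace(list(tau_fast = 0.3, tau_slow = 2, amp_fast = 0,
                           amp_slow = 0.6, plateau = 0.9), "half",
                      noise_sd = 0)
  f <- fit_half_frap(align_bleach(g$trace), full_tau = 2)
  expect_lt(f$amp_fast, 1e-6)
  expect_equal(f$amp_slow, 0.6, tolerance = 1e-6)
})

test_that("constrained fit has >= residual norm but lower tau_fast variance", {
  truth <- list(tau_fast = 0.5, tau_slow = 10, amp_fast = 0.4,
                amp_slow = 0.35, plateau = 0.95)
  tfc <- tfu <- numeric(30)
  for (i in 1:30) {
    g <- gen_frap_trace(truth, "half", noise_sd = 0.05,
                        frame_interval = 0.05, seed = 400 + i)
    tr <- align_bleach(g$trace)
    fc <- fit_half_frap(tr, full_tau = truth$tau_slow)
    fu <- fit_half_frap(tr, full_tau = NULL)
    expect_gte(fc$residual_norm, fu$residual_norm - 1e-8)
    tfc[i] <- fc$tau_fast; tfu[i] <- fu$tau_fast
  }
  expect_lte(var(tfc), var(tfu))
})

test_that("material-state classification follows the documented rule", {
  mk <- function(pr, tf = NA_real_, ts = 1) {
    structure(list(model = "m", tau_slow = ts, tau_fast = tf,
                   percent_recovery = pr, converged = TRUE),
              class = "frap_fit")
  }
  expect_equal(classify_state(mk(2)), "solid")
  expect_equal(classify_state(mk(90, ts = 0.5)), "liquid")
  expect_equal(classify_state(mk(90, ts = 5)), "gel")
  # double-exponential fits classify on tau_fast
  expect_equal(classify_state(mk(60, tf = 0.4, ts = 8)), "liquid")
  # boundaries: recovery exactly at the solid cutoff is NOT solid (strict <);
  # tau exactly at the liquid cutoff IS liquid (non-strict <=)
  expect_equal(classify_state(mk(20, ts = 5)), "gel")
  expect_equal(classify_state(mk(50, ts = 2)), "liquid")
  un <- mk(50); un$converged <- FALSE
  expect_error(classify_state(un), "unconverged")
})

test_that("ensemble summaries average fit parameters and drop failures", {
  mk <- function(tau, pr, conv = TRUE) {
    structure(list(model = "m", tau_slow = tau, tau_fast = NA_real_,
                   percent_recovery = pr, converged = conv),
              class = "frap_fit")
  }
  same <- summarize_ensemble(list(mk(1, 50), mk(1, 50)))
  expect_equal(same$tau_slow_sd, 0)
  two <- summarize_ensemble(list(mk(1, 40), mk(3, 60), mk(99, 99, FALSE)))
  expect_equal(two$tau_slow_mean, 2)
  expect_equal(two$percent_recovery_mean, 50)
  expect_equal(two$n, 2L)
  expect_equal(two$n_excluded, 1L)
  expect_error(summarize_ensemble(list(mk(1, 1, FALSE))), "no converged")
})

test_that("ROI trace extraction averages the ROI and validates geometry", {
  uniform <- list(frames = array(7, dim = c(8, 8, 15)), frame_interval = 0.1,
                  bleach_frame = 4L,
                  roi = list(x = 2L, y = 3L, width = 4L, height = 3L))
  tr <- extract_roi_trace(uniform)
  expect_equal(tr$intensities, rep(7, 15))
  expect_equal(tr$times, (0:14) * 0.1)
  bad <- uniform; bad$roi$x <- 7L
  expect_error(extract_roi_trace(bad), "bounds")
  empty_mask <- uniform; empty_mask$roi <- matrix(FALSE, 8, 8)
  expect_error(extract_roi_trace(empty_mask), "empty")
  # noiseless synthetic stack reproduces the generating recovery in the ROI
  gs <- gen_punctum_stack(frap_params = list(tau = 1, plateau = 0.8, f0 = 0.1),
                          noise_sd = 0, seed = 5)
  tr2 <- extract_roi_trace(gs$stack)
  f <- fit_full_frap(align_bleach(normalize_trace(tr2)))
  expect_equal(f$tau_slow, 1, tolerance = 0.02)
})

test_that("trace CSV round trip preserves data and metadata", {
  g <- gen_frap_trace(list(tau = 1, plateau = 0.9, f0 = 0), "full",
                      noise_sd = 0.02, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(g$trace, tmp)
  back <- read_trace_csv(tmp)
  expect_equal(back$intensities, g$trace$intensities, tolerance = 1e-6)
  expect_equal(back$bleach_index, g$trace$bleach_index)
  expect_equal(back$mode, "full")
})
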