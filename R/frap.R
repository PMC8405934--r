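#' Construct a FRAP trace
#'
#' A fluorescence-recovery trace: strictly increasing times (seconds),
#' non-negative intensities, and the index of the first post-bleach frame.
#' Typical acquisitions collect ~0.7 s of prebleach frames and record
#' recovery every 50-200 ms for ~10 s.
#'
#' @param times Numeric vector of frame times (s), strictly increasing.
#' @param intensities Numeric vector, same length, non-negative.
#' @param bleach_index Index of the first post-bleach frame.
#' @param mode `"full"` (whole punctum bleached; probes exchange with the
#'   nucleoplasm) or `"half"` (half the punctum bleached; probes internal
#'   mixing as well).
#' @param frame_interval Acquisition interval (s); inferred from `times` if
#'   omitted.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, intensities, bleach_index,
                       mode = c("full", "half"), frame_interval = NULL) {
  mode <- match.arg(mode)
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  stopifnot(length(times) == length(intensities), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("frap_trace: times must be strictly increasing",
                                  call. = FALSE)
  if (any(intensities < 0)) stop("frap_trace: intensities must be non-negative",
                                 call. = FALSE)
  bleach_index <- as.integer(bleach_index)
  if (is.na(bleach_index) || bleach_index < 1L || bleach_index > length(times)) {
    stop("frap_trace: bleach_index out of range", call. = FALSE)
  }
  if (is.null(frame_interval)) frame_interval <- stats::median(diff(times))
  structure(list(times = times, intensities = intensities,
                 bleach_index = bleach_index, mode = mode,
                 frame_interval = frame_interval),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %s, %d frames (%d post-bleach), dt=%.3g s\n",
              x$mode, length(x$times), length(x$times) - x$bleach_index + 1L,
              x$frame_interval))
  invisible(x)
}

#' Min-max normalize a trace
#'
#' Maps intensities affinely so the curve minimum becomes 0 and the maximum
#' becomes 1 ("normalized to the min and max of the curve"); times are
#' unchanged. Idempotent on already-normalized traces.
#'
#' @param trace A [frap_trace()].
#' @return A normalized `frap_trace`.
#' @export
normalize_trace <- function(trace) {
  rng <- range(trace$intensities)
  if (diff(rng) <= 0) {
    stop("normalize_trace: degenerate (flat) trace cannot be normalized",
         call. = FALSE)
  }
  trace$intensities <- (trace$intensities - rng[1L]) / diff(rng)
  trace
}

#' Align traces so the bleach point sits at t = 0
#'
#' Shifts each trace's time axis so that its first post-bleach frame is at
#' time zero; intensities are untouched.
#'
#' @param traces A `frap_trace` or list of them.
#' @return A list of aligned `frap_trace`s (a single trace in, single out).
#' @export
align_bleach <- function(traces) {
  single <- inherits(traces, "frap_trace")
  if (single) traces <- list(traces)
  out <- lapply(traces, function(tr) {
    if (is.null(tr$bleach_index)) {
      stop("align_bleach: trace has no bleach_index", call. = FALSE)
    }
    tr$times <- tr$times - tr$times[tr$bleach_index]
    tr
  })
  if (single) out[[1L]] else out
}

# Deterministic multi-start grid for tau initialization: the time to
# half-recovery, scaled by fixed factors. Avoids RNG in a deterministic fit.
tau_starts <- function(t_post, y_post) {
  y0 <- y_post[1L]
  plateau <- stats::median(y_post[max(1L, length(y_post) - 4L):length(y_post)])
  half <- y0 + 0.5 * (plateau - y0)
  idx <- which(y_post >= half)
  t_half <- if (length(idx) > 0L && plateau > y0) max(t_post[idx[1L]], t_post[2L])
            else max(t_post) / 4
  base <- t_half / log(2)
  unique(pmax(base * c(1, 0.25, 0.5, 2, 4), 1e-4))
}

post_bleach <- function(trace) {
  i <- trace$bleach_index:length(trace$times)
  list(t = trace$times[i] - trace$times[trace$bleach_index],
       y = trace$intensities[i])
}

# Bounded Levenberg-Marquardt least squares (minpack.lm::nls.lm) over a
# deterministic list of starting points; returns the best converged fit.
fit_nls <- function(resid_fn, start_list, lower, upper) {
  best <- NULL
  for (st in start_list) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out) || !(out$info %in% 1:3)) next
    rss <- sum(out$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = out$par, rss = rss)
  }
  best
}

#' Fit a full-FRAP trace with a single exponential
#'
#' Full-FRAP recovery is modeled as
#' `F(t) = plateau - (plateau - F0) * exp(-t / tau)` over the post-bleach
#' frames, where `F0` is the fitted bleach depth and `tau` the recovery time
#' constant (the "diffusion time" of protein entering the bleached punctum
#' from the nucleoplasm). Percent recovery is
#' `100 * (plateau - F0) / (1 - F0)`, i.e. recovery relative to the
#' normalized prebleach level. Bounded Levenberg-Marquardt least squares
#' with a deterministic multi-start grid on `tau`.
#'
#' @param trace A normalized, bleach-aligned [frap_trace()] (mode `"full"`).
#' @return A `frap_fit` with elements `model`, `tau_slow`, `tau_fast` (NA),
#'   `amp_fast` (NA), `amp_slow`, `plateau`, `f0`, `percent_recovery`,
#'   `residual_norm`, `converged`.
#' @export
fit_full_frap <- function(trace) {
  pb <- post_bleach(trace)
  if (length(pb$t) < 10L) stop("fit_full_frap: need >= 10 post-bleach frames",
                               call. = FALSE)
  if (diff(range(trace$intensities)) <= 0) {
    stop("fit_full_frap: degenerate (flat) trace", call. = FALSE)
  }
  resid_fn <- function(p) {
    p[["plateau"]] - (p[["plateau"]] - p[["f0"]]) * exp(-pb$t / p[["tau"]]) -
      pb$y
  }
  starts <- lapply(tau_starts(pb$t, pb$y), function(tau0) {
    c(plateau = max(pb$y), f0 = pb$y[1L], tau = tau0)
  })
  best <- fit_nls(resid_fn, starts,
                  lower = c(plateau = 0, f0 = 0, tau = 1e-6),
                  upper = c(plateau = 2, f0 = 2, tau = Inf))
  if (is.null(best)) {
    stop("fit_full_frap: optimizer failed to converge from all starts",
         call. = FALSE)
  }
  p <- as.list(best$par)
  pr <- if (p$f0 >= 1) 0 else 100 * (p$plateau - p$f0) / (1 - p$f0)
  structure(list(model = "single_exp", tau_slow = p$tau, tau_fast = NA_real_,
                 amp_fast = NA_real_, amp_slow = p$plateau - p$f0,
                 plateau = p$plateau, f0 = p$f0, percent_recovery = pr,
                 residual_norm = sqrt(best$rss), converged = TRUE),
            class = "frap_fit")
}

#' Fit a half-FRAP trace with a constrained double exponential
#'
#' Half-FRAP recovery mixes two processes: fast internal turnover within the
#' punctum and slow addition of protein from the nucleoplasm. The model is
#' `F(t) = plateau - amp_fast * exp(-t / tau_fast) - amp_slow * exp(-t / tau_slow)`.
#' In the two-stage procedure the slow time constant is fixed exactly to the
#' single-exponential tau obtained from the matching full-FRAP sample
#' (`full_tau`), so only `tau_fast` (bounded to `(0, full_tau]`), the two
#' non-negative amplitudes, and the plateau are free. Passing
#' `full_tau = NULL` fits the unconstrained double exponential (both taus
#' free), which is useful for comparing the stability of the two estimators.
#'
#' @param trace A normalized, bleach-aligned [frap_trace()] (mode `"half"`).
#' @param full_tau Slow time constant from the paired full-FRAP fit (s), or
#'   `NULL` for an unconstrained fit.
#' @return A `frap_fit`; for the constrained model `tau_slow` is bit-equal
#'   to `full_tau`.
#' @export
fit_half_frap <- function(trace, full_tau) {
  constrained <- !is.null(full_tau)
  if (constrained && (!is.numeric(full_tau) || full_tau <= 0)) {
    stop("fit_half_frap: full_tau must be > 0", call. = FALSE)
  }
  pb <- post_bleach(trace)
  if (length(pb$t) < 10L) stop("fit_half_frap: need >= 10 post-bleach frames",
                               call. = FALSE)
  depth <- max(pb$y) - pb$y[1L]
  if (constrained) {
    resid_fn <- function(p) {
      p[["plateau"]] - p[["amp_fast"]] * exp(-pb$t / p[["tau_fast"]]) -
        p[["amp_slow"]] * exp(-pb$t / full_tau) - pb$y
    }
    starts <- lapply(tau_starts(pb$t, pb$y), function(tau0) {
      c(plateau = max(pb$y), amp_fast = depth / 2, amp_slow = depth / 2,
        tau_fast = min(tau0, full_tau * 0.99))
    })
    best <- fit_nls(
      resid_fn, starts,
      lower = c(plateau = 0, amp_fast = 0, amp_slow = 0, tau_fast = 1e-6),
      upper = c(plateau = 2, amp_fast = 2, amp_slow = 2, tau_fast = full_tau))
  } else {
    resid_fn <- function(p) {
      p[["plateau"]] - p[["amp_fast"]] * exp(-pb$t / p[["tau_fast"]]) -
        p[["amp_slow"]] * exp(-pb$t / p[["tau_slow"]]) - pb$y
    }
    starts <- lapply(tau_starts(pb$t, pb$y), function(tau0) {
      c(plateau = max(pb$y), amp_fast = depth / 2, amp_slow = depth / 2,
        tau_fast = tau0 / 4, tau_slow = tau0 * 4)
    })
    best <- fit_nls(
      resid_fn, starts,
      lower = c(plateau = 0, amp_fast = 0, amp_slow = 0,
                tau_fast = 1e-6, tau_slow = 1e-6),
      upper = c(plateau = 2, amp_fast = 2, amp_slow = 2,
                tau_fast = Inf, tau_slow = Inf))
  }
  if (is.null(best)) {
    stop("fit_half_frap: optimizer failed to converge from all starts",
         call. = FALSE)
  }
  p <- as.list(best$par)
  tau_slow <- if (constrained) full_tau else p$tau_slow
  f0 <- p$plateau - p$amp_fast - p$amp_slow
  pr <- if (f0 >= 1) 0 else 100 * (p$plateau - f0) / (1 - f0)
  structure(list(model = if (constrained) "double_exp_constrained"
                         else "double_exp",
                 tau_slow = tau_slow, tau_fast = p$tau_fast,
                 amp_fast = p$amp_fast, amp_slow = p$amp_slow,
                 plateau = p$plateau, f0 = f0, percent_recovery = pr,
                 residual_norm = sqrt(best$rss), converged = TRUE),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> %s: tau_slow=%.4g s%s, plateau=%.3g, recovery=%.1f%%\n",
              x$model, x$tau_slow,
              if (!is.na(x$tau_fast)) sprintf(", tau_fast=%.4g s", x$tau_fast)
              else "",
              x$plateau, x$percent_recovery))
  invisible(x)
}

#' Classify punctum material state from a FRAP fit
#'
#' Liquid-like droplets recover fluorescence quickly, gel-like droplets
#' recover slowly, and solid aggregates show essentially no recovery. The
#' rule (with documented default cutoffs, both configurable): `solid` if
#' `percent_recovery < solid_cutoff` (default 20%); otherwise `liquid` if
#' the characteristic tau (`tau_fast` for double-exponential fits, `tau_slow`
#' for single) is `<= liquid_tau_cutoff` (default 2 s, i.e. twice a typical
#' ~1 s cytoplasmic-control tau); otherwise `gel`. Boundary values: recovery
#' exactly at `solid_cutoff` is not solid (strict `<`); tau exactly at
#' `liquid_tau_cutoff` is liquid (non-strict `<=`).
#'
#' @param result A converged `frap_fit`.
#' @param solid_cutoff Percent recovery below which the punctum is solid.
#' @param liquid_tau_cutoff Tau (s) at or below which recovery counts as fast.
#' @return One of `"liquid"`, `"gel"`, `"solid"`.
#' @export
classify_state <- function(result, solid_cutoff = 20, liquid_tau_cutoff = 2) {
  if (!isTRUE(result$converged)) {
    stop("classify_state: refusing to classify an unconverged fit",
         call. = FALSE)
  }
  if (result$percent_recovery < solid_cutoff) return("solid")
  tau <- if (!is.na(result$tau_fast)) result$tau_fast else result$tau_slow
  if (tau <= liquid_tau_cutoff) "liquid" else "gel"
}

#' Summarize an ensemble of FRAP fits
#'
#' Averages fitted parameters across cells (fits), as in per-curve fitting
#' followed by parameter averaging. Unconverged fits are excluded and
#' counted.
#'
#' @param results List of `frap_fit` objects.
#' @return List with `n`, `n_excluded`, and mean/SD of `tau_slow`,
#'   `tau_fast`, `percent_recovery`.
#' @export
summarize_ensemble <- function(results) {
  ok <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  if (!any(ok)) stop("summarize_ensemble: no converged fits", call. = FALSE)
  get <- function(f) vapply(results[ok], function(r) r[[f]], numeric(1))
  taus <- get("tau_slow"); tf <- get("tau_fast"); pr <- get("percent_recovery")
  list(n = sum(ok), n_excluded = sum(!ok),
       tau_slow_mean = mean(taus), tau_slow_sd = stats::sd(taus),
       tau_fast_mean = mean(tf, na.rm = TRUE),
       tau_fast_sd = stats::sd(tf[!is.na(tf)]),
       percent_recovery_mean = mean(pr), percent_recovery_sd = stats::sd(pr))
}

#' Extract a mean-intensity ROI trace from a punctum image stack
#'
#' @param stack A `punctum_stack`: list with `frames` (h x w x t numeric
#'   array), `frame_interval` (s), `bleach_frame`, and `roi` -- either a
#'   list `(x, y, width, height)` in pixel coordinates (1-based) or a
#'   logical h x w mask.
#' @param mode Trace mode recorded on the output (default `"full"`).
#' @return A [frap_trace()] whose intensity at each frame is the mean over
#'   the ROI pixels.
#' @export
extract_roi_trace <- function(stack, mode = c("full", "half")) {
  mode <- match.arg(mode)
  frames <- stack$frames
  stopifnot(length(dim(frames)) == 3L)
  h <- dim(frames)[1L]; w <- dim(frames)[2L]; nt <- dim(frames)[3L]
  roi <- stack$roi
  if (is.matrix(roi)) {
    if (!identical(dim(roi), c(h, w)) || !any(roi)) {
      stop("extract_roi_trace: ROI mask empty or wrong shape", call. = FALSE)
    }
    mask <- roi
  } else {
    if (roi$x < 1L || roi$y < 1L || roi$x + roi$width - 1L > w ||
        roi$y + roi$height - 1L > h || roi$width < 1L || roi$height < 1L) {
      stop("extract_roi_trace: ROI outside image bounds", call. = FALSE)
    }
    mask <- matrix(FALSE, h, w)
    mask[roi$y:(roi$y + roi$height - 1L), roi$x:(roi$x + roi$width - 1L)] <- TRUE
  }
  intensity <- vapply(seq_len(nt), function(k) mean(frames[, , k][mask]),
                      numeric(1))
  frap_trace(times = (seq_len(nt) - 1L) * stack$frame_interval,
             intensities = intensity, bleach_index = stack$bleach_frame,
             mode = mode, frame_interval = stack$frame_interval)
}

#' Read a multi-page TIFF as a punctum stack
#'
#' Frames are assumed registered (no drift correction is performed); a
#' simple frame-to-frame correlation check warns when apparent drift is
#' large.
#'
#' @param path Multi-page TIFF path.
#' @param roi ROI descriptor (list `x, y, width, height` or logical mask).
#' @param frame_interval Seconds per frame.
#' @param bleach_frame Index of the first post-bleach frame.
#' @return A `punctum_stack` list.
#' @export
read_punctum_stack_tiff <- function(path, roi, frame_interval, bleach_frame) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("read_punctum_stack_tiff requires the 'tiff' package", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- simplify2array(pages)
  stack <- list(frames = frames, frame_interval = frame_interval,
                bleach_frame = bleach_frame, roi = roi)
  cors <- vapply(seq_len(dim(frames)[3L] - 1L), function(k) {
    suppressWarnings(stats::cor(as.vector(frames[, , k]),
                                as.vector(frames[, , k + 1L])))
  }, numeric(1))
  if (any(!is.na(cors) & cors < 0.2)) {
    warning("read_punctum_stack_tiff: low frame-to-frame correlation; ",
            "stack may be unregistered or drifting")
  }
  stack
}

#' Read a FRAP trace CSV
#'
#' Expects columns `time_s`, `intensity` and metadata header lines of the
#' form `# mode=full`, `# bleach_index=8`, `# interval_s=0.1`.
#'
#' @param path CSV path.
#' @return A [frap_trace()].
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  stopifnot(all(c("time_s", "intensity") %in% names(df)))
  frap_trace(df$time_s, df$intensity,
             bleach_index = as.integer(meta$bleach_index %||% 1L),
             mode = meta$mode %||% "full",
             frame_interval = if (!is.null(meta$interval_s))
               as.numeric(meta$interval_s) else NULL)
}

#' Write a FRAP trace CSV (with metadata header)
#' @param trace A [frap_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mode=%s", trace$mode),
               sprintf("# bleach_index=%d", trace$bleach_index),
               sprintf("# interval_s=%g", trace$frame_interval)), con)
  utils::write.csv(data.frame(time_s = trace$times,
                              intensity = trace$intensities),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
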