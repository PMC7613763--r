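# Study-level statistics: pulse-train arithmetic, electroporation yield,
# repeat summaries, percent changes and the Mann-Whitney U test used for
# drug-vs-baseline comparisons.

#' Total duration of a biphasic pulse train
#'
#' Each pulse cycle is two phases plus one interpulse interval:
#' `n_pulses * (2 * phase_us + ipi_ms)`. This per-pulse-period convention
#' reproduces the reference protocol exactly (25,000 pulses x (2 x 200 us +
#' 1 ms) = 35 s).
#'
#' @param protocol [poration_protocol], or a pulse count if the remaining
#'   arguments are given.
#' @param phase_us,ipi_ms timing (ignored when a protocol is passed).
#' @return duration in seconds.
#' @export
train_duration_s <- function(protocol, phase_us = NULL, ipi_ms = NULL) {
  if (inherits(protocol, "poration_protocol")) {
    n <- protocol$n_pulses
    phase_us <- protocol$phase_us
    ipi_ms <- protocol$ipi_ms
  } else {
    n <- protocol
    stopifnot(!is.null(phase_us), !is.null(ipi_ms))
  }
  n * (2 * phase_us * 1e-6 + ipi_ms * 1e-3)
}

#' Geometric electrode area
#'
#' Returns the geometric area; for the 5.5 x 9.3 um rectangle this is
#' 51.15 um2 while vendor datasheets print 50.7 um2 (presumably rounded
#' corners) - the printed value, when known, belongs in metadata, not here.
#'
#' @param shape `"circle"` or `"rectangle"`.
#' @param diameter_um circle diameter.
#' @param width_um,height_um rectangle sides.
#' @return area in um2.
#' @export
electrode_area_um2 <- function(shape = c("circle", "rectangle"),
                               diameter_um = NULL, width_um = NULL,
                               height_um = NULL) {
  shape <- match.arg(shape)
  if (shape == "circle") {
    if (is.null(diameter_um) || diameter_um <= 0)
      stop("electrode_area_um2: diameter_um must be > 0")
    pi * diameter_um^2 / 4
  } else {
    if (is.null(width_um) || is.null(height_um) || width_um <= 0 || height_um <= 0)
      stop("electrode_area_um2: width_um and height_um must be > 0")
    width_um * height_um
  }
}

#' Percent change
#'
#' `100 * (post - pre) / pre`. Note the asymmetry: exchanging pre and post
#' flips the sign but not the magnitude (a drop from 96.9 to 62.2 is -35.8%,
#' the reverse is +55.8%).
#'
#' @param pre,post numeric vectors (recycled).
#' @return percent change.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("percent_change: pre must be nonzero")
  100 * (post - pre) / pre
}

# exact null counts of the Mann-Whitney U statistic: number of ways to choose
# n of n+m ranks summing (after offset) to each U in 0..n*m. Classic DP over
# the Gaussian-binomial recurrence.
.mwu_counts <- function(n, m) {
  counts <- vector("list", m + 1L)
  for (j in 0:m) counts[[j + 1L]] <- 1   # n = 0 row: U = 0 only
  for (i in seq_len(n)) {
    prev <- counts
    for (j in 0:m) {
      c_len <- i * j + 1L
      cur <- numeric(c_len)
      # f(i, j, u) = f(i-1, j, u - j) + f(i, j-1, u)
      a <- prev[[j + 1L]]
      cur[(j + 1L):min(c_len, j + length(a))] <- a[seq_len(min(c_len - j, length(a)))]
      if (j > 0) {
        b <- counts[[j]]
        cur[seq_along(b)] <- cur[seq_along(b)] + b
      }
      counts[[j + 1L]] <- cur
    }
  }
  counts[[m + 1L]]
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum with midranks for ties. The p-value is exact (by enumeration of
#' the null distribution of U) when `min(n, m) <= 8` and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. The exact two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric samples.
#' @return list with `u` (U statistic of `x`), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n <- length(x)
  m <- length(y)
  if (n == 0 || m == 0) stop("mann_whitney_u: both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && min(n, m) <= 8 && n * m <= 10000) {
    cnt <- .mwu_counts(n, m)
    tot <- sum(cnt)
    lo <- sum(cnt[seq_len(round(u) + 1L)]) / tot          # P(U <= u)
    hi <- sum(cnt[(round(u) + 1L):length(cnt)]) / tot     # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    N <- n + m
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - n * m / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal_approx"
  }
  list(u = u, p_value = p, method = method)
}

#' Electroporation yield
#'
#' Percentage of pulsed electrodes whose representative waveform is
#' intracellular-like with AP amplitude above the threshold. Invariant to
#' electrode ordering and to extra feature rows for electrodes that received
#' no pulses.
#'
#' @param features feature table (schema of [write_feature_table]).
#' @param events poration-event data.frame (defines which electrodes
#'   received pulses; success is irrelevant here).
#' @param amp_threshold_mv amplitude criterion, mV (default 1).
#' @return data.frame with one row per `repeat_idx` present in `features`:
#'   `repeat_idx`, `n_stimulated`, `n_intracellular`, `yield_pct`.
#' @export
poration_yield <- function(features, events, amp_threshold_mv = 1) {
  stim <- unique(events$electrode_id)
  if (length(stim) == 0) stop("poration_yield: no stimulated electrodes")
  reps <- sort(unique(features$repeat_idx))
  out <- lapply(reps, function(r) {
    f <- features[features$repeat_idx == r & features$electrode_id %in% stim, ]
    hit <- f$label == "intracellular_like" &
      !is.na(f$ap_amplitude_mv) & f$ap_amplitude_mv > amp_threshold_mv
    data.frame(repeat_idx = r, n_stimulated = length(stim),
               n_intracellular = sum(hit),
               yield_pct = 100 * sum(hit) / length(stim))
  })
  do.call(rbind, out)
}

#' Per-repeat medians and IQRs of AP parameters
#'
#' @param features feature table covering one or more repeats.
#' @return data.frame with one row per repeat: n, median/IQR of APD90,
#'   depolarization time, AP amplitude and FP amplitude. Repeats with no
#'   intracellular-like rows yield NA summaries.
#' @export
repeat_summary <- function(features) {
  reps <- sort(unique(features$repeat_idx))
  med_iqr <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) c(NA_real_, NA_real_)
    else c(stats::median(v), stats::IQR(v))
  }
  out <- lapply(reps, function(r) {
    f <- features[features$repeat_idx == r & features$label == "intracellular_like", ]
    a <- med_iqr(f$apd90_ms)
    d <- med_iqr(f$tdep_ms)
    m <- med_iqr(f$ap_amplitude_mv)
    fp <- med_iqr(features$fp_amplitude_uv[features$repeat_idx == r])
    data.frame(repeat_idx = r, n = nrow(f),
               apd90_median = a[1], apd90_iqr = a[2],
               tdep_median = d[1], tdep_iqr = d[2],
               amp_median = m[1], amp_iqr = m[2],
               fp_median = fp[1], fp_iqr = fp[2])
  })
  do.call(rbind, out)
}

#' Drug-response report
#'
#' Per-electrode percent changes are computed against the last baseline
#' (ctrl3); the Mann-Whitney U test compares the postdose and ctrl3 feature
#' distributions across electrodes. A ctrl1-vs-ctrl3 comparison is reported
#' as a baseline-stability check. Electrodes without a valid measurement in
#' both phases of a comparison are dropped (and listed).
#'
#' @param baselines list of 3 feature tables (ctrl1, ctrl2, ctrl3).
#' @param postdose feature table after drug administration.
#' @param feature_names columns to compare (default APD90 and
#'   depolarization time).
#' @param alpha significance level (default 0.05).
#' @return list with `comparisons` (data.frame: feature_name, comparison,
#'   n_pre, n_post, mean_pct_change, sd_pct_change, u_statistic, p_value,
#'   significant), `changes` (per-electrode percent changes vs ctrl3) and
#'   `dropped` (electrode ids without matched measurements).
#' @export
drug_report <- function(baselines, postdose,
                        feature_names = c("apd90_ms", "tdep_ms"),
                        alpha = 0.05) {
  stopifnot(length(baselines) == 3)
  ctrl1 <- baselines[[1]]
  ctrl3 <- baselines[[3]]
  valid <- function(tab, f)
    tab[tab$label == "intracellular_like" & !is.na(tab[[f]]),
        c("electrode_id", f)]
  comp_rows <- list()
  changes <- list()
  dropped <- integer(0)
  for (f in feature_names) {
    for (cmp in c("postdose_vs_ctrl3", "ctrl1_vs_ctrl3")) {
      pre <- valid(ctrl3, f)
      post <- valid(if (cmp == "postdose_vs_ctrl3") postdose else ctrl1, f)
      ids <- intersect(pre$electrode_id, post$electrode_id)
      dropped <- union(dropped, setdiff(union(pre$electrode_id,
                                              post$electrode_id), ids))
      a <- pre[[f]][match(ids, pre$electrode_id)]
      b <- post[[f]][match(ids, post$electrode_id)]
      pc <- percent_change(a, b)
      mw <- mann_whitney_u(b, a)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        feature_name = f, comparison = cmp, n_pre = length(a),
        n_post = length(b), mean_pct_change = mean(pc),
        sd_pct_change = stats::sd(pc), u_statistic = mw$u,
        p_value = mw$p_value, significant = mw$p_value < alpha)
      if (cmp == "postdose_vs_ctrl3")
        changes[[f]] <- data.frame(electrode_id = ids, feature_name = f,
                                   pre = a, post = b, pct_change = pc)
    }
  }
  list(comparisons = do.call(rbind, comp_rows),
       changes = do.call(rbind, changes),
       dropped = sort(dropped))
}
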