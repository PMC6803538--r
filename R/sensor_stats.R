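#' Grand average by condition
#'
#' Arithmetic mean over trials within each condition.
#'
#' @param epochs An `epoch_set`.
#' @return conditions x channels x time array (condition names on dim 1),
#'   with attributes `times_s` and `rate_hz`.
#' @export
grand_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  conds <- levels(epochs$labels)
  counts <- table(epochs$labels)
  if (any(counts == 0))
    stop("no trials for condition(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  d <- dim(epochs$data)
  out <- array(0, c(length(conds), d[2], d[3]),
               dimnames = list(conds, epochs$channel_names, NULL))
  for (i in seq_along(conds)) {
    sel <- epochs$labels == conds[i]
    out[i, , ] <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  }
  attr(out, "times_s") <- epoch_times(epochs)
  attr(out, "rate_hz") <- epochs$rate_hz
  out
}

#' Channelwise one-way ANOVA across conditions
#'
#' For every channel, the per-trial mean amplitude over `window_s` is
#' compared across conditions with a one-way ANOVA, followed by pairwise
#' post hoc t-tests (pooled SD) with Bonferroni correction
#' (`p_corr = min(1, m * p_raw)`, `m` = number of pairs).  Significance is
#' flagged per channel at `alpha` on the uncorrected-across-channels ANOVA
#' p-value (per-channel testing convention; the ERP analysis uses
#' `alpha = 0.001`, the hemoglobin analysis `0.05`).
#'
#' @param epochs An `epoch_set` (>= 2 trials per condition).
#' @param window_s Analysis window (s), e.g. `c(0.35, 0.40)` for the evoked
#'   component or `c(0, 3.5)` for the HbO observation period.
#' @param alpha Per-channel significance level (default 0.001).
#' @return data.frame of class `channel_stats` with per-channel `F`, `p`,
#'   `df1`, `df2`, `significant`; pairwise Bonferroni-corrected p-values in
#'   attribute `"posthoc"` (channels x pairs matrix).
#' @export
channel_anova <- function(epochs, window_s, alpha = 0.001) {
  stopifnot(inherits(epochs, "epoch_set"))
  counts <- table(epochs$labels)
  if (any(counts < 2)) stop("need >= 2 trials per condition")
  wm <- window_mean(epochs, window_s)
  g <- epochs$labels
  conds <- levels(g)
  pairs <- utils::combn(conds, 2)
  m <- ncol(pairs)
  nch <- ncol(wm)
  res <- data.frame(channel = seq_len(nch), F = NA_real_, p = NA_real_,
                    df1 = length(conds) - 1L,
                    df2 = length(g) - length(conds),
                    significant = FALSE)
  post <- matrix(NA_real_, nch, m,
                 dimnames = list(NULL, apply(pairs, 2, paste, collapse = "-")))
  for (ch in seq_len(nch)) {
    y <- wm[, ch]
    if (max(tapply(y, g, stats::var)) < 1e-24)
      stop("degenerate input: zero within-group variance on channel ", ch)
    a <- stats::anova(stats::lm(y ~ g))
    res$F[ch] <- a$`F value`[1]
    res$p[ch] <- a$`Pr(>F)`[1]
    pt <- stats::pairwise.t.test(y, g, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    praw <- vapply(seq_len(m), function(j) {
      a1 <- pairs[1, j]; a2 <- pairs[2, j]
      if (!is.na(pt[a2, a1])) pt[a2, a1] else pt[a1, a2]
    }, numeric(1))
    post[ch, ] <- pmin(1, m * praw)
  }
  res$significant <- res$p < alpha
  attr(res, "posthoc") <- post
  attr(res, "alpha") <- alpha
  class(res) <- c("channel_stats", "data.frame")
  res
}

#' Paired observation-vs-baseline t-tests of the HbO signal over time
#'
#' For each channel and each probe time (default 1..5 s post-onset), the
#' trial-wise mean over `[t - halfwidth, t + halfwidth]` is compared with
#' the trial-wise mean over the baseline block by a paired t-test.
#'
#' @param epochs An HbO `epoch_set` (>= 2 trials).
#' @param times_s Probe times (s; default `1:5`).
#' @param halfwidth_s Half-width of the observation window (default 0.5 s).
#' @param baseline_window_s Baseline block (default `c(-6.5, -0.5)`).
#' @param alpha Significance level (default 0.05).
#' @return data.frame of class `block_ttest` with columns `channel`,
#'   `time_s`, `t`, `p`, `df`, `significant`.
#' @export
hbo_block_ttest <- function(epochs, times_s = 1:5, halfwidth_s = 0.5,
                            baseline_window_s = c(-6.5, -0.5), alpha = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1] < 2L) stop("need >= 2 trials for a paired t-test")
  base <- window_mean(epochs, baseline_window_s)
  out <- do.call(rbind, lapply(times_s, function(tt) {
    obs <- window_mean(epochs, c(tt - halfwidth_s, tt + halfwidth_s))
    res <- lapply(seq_len(ncol(obs)), function(ch) {
      tst <- stats::t.test(obs[, ch], base[, ch], paired = TRUE)
      data.frame(channel = ch, time_s = tt,
                 t = unname(tst$statistic), p = tst$p.value,
                 df = unname(tst$parameter))
    })
    do.call(rbind, res)
  }))
  out$significant <- out$p < alpha
  class(out) <- c("block_ttest", "data.frame")
  out
}
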