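#' One-way random-effects single-measure intraclass correlation, ICC(1,1)
#'
#' `ICC(1,1) = (MSB - MSW) / (MSB + (k - 1) MSW)` from the one-way ANOVA mean
#' squares of an n-subject by k-rater table, with the exact F-quantile 95%
#' confidence interval on (n - 1) and n(k - 1) degrees of freedom (Searle).
#' Negative estimates are reported as computed, not truncated.
#'
#' @param table numeric n x k matrix (subjects x raters), no missing cells.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `msb`, `msw`, `n`, `k`.
#' @export
icc_oneway_single <- function(table, conf = 0.95) {
  x <- as.matrix(table)
  if (any(is.na(x))) stop("ratings table must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(x)
  rowm <- rowMeans(x)
  ssb <- k * sum((rowm - grand)^2)
  ssw <- sum((x - rowm)^2)
  if (ssb + ssw < 1e-300) stop("degenerate ratings: zero total variance")
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf
  if (msw > 0) {
    fobs <- msb / msw
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci_low <- (fl - 1) / (fl + k - 1)
    ci_high <- (fu - 1) / (fu + k - 1)
  } else {
    ci_low <- ci_high <- 1
  }
  list(icc = icc, ci_low = ci_low, ci_high = ci_high,
       msb = msb, msw = msw, n = n, k = k)
}

#' Mean absolute difference and its standard deviation
#'
#' `mad = mean(|x - y|)`; `sd` is the sample (n - 1) standard deviation of the
#' absolute differences — the "MAD (SD)" agreement summary. Set
#' `sd_of = "signed"` for the SD of signed differences instead.
#'
#' @param x,y paired measurement vectors of equal length >= 2.
#' @param sd_of "absolute" (default) or "signed" differences.
#' @return list with `mad` and `sd`.
#' @export
mad_sd <- function(x, y, sd_of = c("absolute", "signed")) {
  sd_of <- match.arg(sd_of)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  list(mad = mean(abs(d)),
       sd = if (sd_of == "absolute") stats::sd(abs(d)) else stats::sd(d))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`, bias = mean(d), 95% limits of agreement
#' `bias +/- 1.96 sd(d)` (sample SD). Per-pair means and differences are
#' returned for plotting.
#'
#' @param x,y paired measurement vectors of equal length >= 3.
#' @return object of class `bland_altman`: list with `bias`, `loa_low`,
#'   `loa_high`, `sd`, and a `data` data.frame (mean, diff).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  s <- stats::sd(d)
  bias <- mean(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd = s,
                 data = data.frame(mean = (x + y) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, 95%% limits of agreement [%.4f, %.4f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, nrow(x$data)))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' Scatter of pairwise differences against pairwise means with bias and
#' limit-of-agreement lines.
#'
#' @param x a `bland_altman` object.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, main = "Bland-Altman", ...) {
  graphics::plot(x$data$mean, x$data$diff, pch = 19,
                 xlab = "Mean of observers", ylab = "Difference (obs1 - obs2)",
                 main = main, ...)
  graphics::abline(h = x$bias, col = "blue", lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  invisible(x)
}

#' Cicchetti interpretation of an ICC
#'
#' Bands: poor < 0.40 <= fair < 0.60 <= good < 0.75 <= excellent. The
#' reliability verdict accepts "good" or "excellent" (ICC > 0.60).
#'
#' @param icc finite ICC estimate.
#' @return list with `category` and logical `reliable`.
#' @export
cicchetti_category <- function(icc) {
  if (!is.finite(icc)) stop("ICC must be finite")
  category <- if (icc < 0.40) "poor" else if (icc < 0.60) "fair"
              else if (icc < 0.75) "good" else "excellent"
  list(category = category, reliable = category %in% c("good", "excellent"))
}

#' Sample size for a one-sample correlation study
#'
#' Fisher-z formula for testing H0: rho = 0 against Ha: rho = `rho_alt` with
#' two raters: `n = ceil(((z_{1-alpha/2} + z_{power}) / atanh(rho_alt))^2 + 3)`.
#' With `rho_alt = 0.6`, `alpha = 0.05`, `power = 0.8` this gives n = 20.
#'
#' @param rho_alt alternative correlation (0 < rho_alt < 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return required number of subjects (integer).
#' @export
sample_size_one_correlation <- function(rho_alt = 0.6, alpha = 0.05, power = 0.8) {
  if (rho_alt <= 0 || rho_alt >= 1) stop("rho_alt must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(rho_alt)
  as.integer(ceiling(z^2 + 3))
}

#' Two-observer reliability study over morphometric reports
#'
#' Pairs the two observers' measurement tables by subject, structure, region
#' and metric, and emits one reliability row per structure x region x metric
#' cell: ICC(1,1) with 95% CI, MAD (SD), Bland-Altman bias and limits of
#' agreement, and the Cicchetti category.
#'
#' @param reports_obs1,reports_obs2 data.frames with columns `subject`,
#'   `structure`, `region`, `metric`, `value` (one row per measurement), e.g.
#'   stacked [assess_tmj()] reports.
#' @return data.frame with one row per metric cell (class
#'   `reliability_report`).
#' @export
reliability_study <- function(reports_obs1, reports_obs2) {
  key <- function(d) paste(d$subject, d$structure, d$region, d$metric, sep = "|")
  k1 <- key(reports_obs1); k2 <- key(reports_obs2)
  miss <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(miss))
    stop(sprintf("unmatched observer keys: %s", paste(utils::head(miss, 10), collapse = "; ")))
  m <- match(k1, k2)
  d <- data.frame(subject = reports_obs1$subject,
                  structure = reports_obs1$structure,
                  region = reports_obs1$region,
                  metric = reports_obs1$metric,
                  v1 = reports_obs1$value, v2 = reports_obs2$value[m],
                  stringsAsFactors = FALSE)
  d <- d[!is.na(d$v1) & !is.na(d$v2), ]
  cells <- unique(d[, c("structure", "region", "metric")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- d$structure == cells$structure[i] & d$region == cells$region[i] &
      d$metric == cells$metric[i]
    dd <- d[sel, ]
    if (nrow(dd) < 2) return(NULL)
    icc <- tryCatch(icc_oneway_single(cbind(dd$v1, dd$v2)),
                    error = function(e) NULL)
    if (is.null(icc)) return(NULL)
    ms <- mad_sd(dd$v1, dd$v2)
    ba <- bland_altman(dd$v1, dd$v2)
    cc <- cicchetti_category(icc$icc)
    data.frame(structure = cells$structure[i], region = cells$region[i],
               metric = cells$metric[i], n = nrow(dd),
               icc = icc$icc, ci_low = icc$ci_low, ci_high = icc$ci_high,
               mad = ms$mad, sd = ms$sd,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               category = cc$category, reliable = cc$reliable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("reliability study needs at least 2 matched subjects per cell (ICC undefined for n = 1)")
  class(out) <- c("reliability_report", class(out))
  out
}
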