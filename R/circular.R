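# Circular statistics: summaries, Watson's one- and two-sample tests,
# circular histograms and angular Q-Q quantile matching.  Angles are
# radians wrapped to (-pi, pi]; angular space is non-Euclidean, so all
# summaries go through the resultant vector.

#' Circular mean, SD and resultant length
#'
#' Mean direction is the angle of the summed unit phasors; the mean
#' resultant length Rbar is their average magnitude; the circular SD is
#' `sqrt(-2 * log(Rbar))`.
#'
#' @param angles numeric vector of angles, radians (wrapped internally).
#' @return an object of class `circ_summary` with `mean` (radians in
#'   (-pi, pi]), `sd` (radians), `rbar` in `[0, 1]` and `n`.
#' @export
circ_summary <- function(angles) {
  angles <- wrap_angle(as.numeric(angles))
  n <- length(angles)
  if (n < 1L) abort("need at least one angle")
  z <- sum(exp(1i * angles)) / n
  rbar <- Mod(z)
  if (rbar < 1e-12) abort("mean direction undefined (resultant length ~ 0)")
  structure(list(mean = wrap_angle(Arg(z)), sd = sqrt(-2 * log(rbar)),
                 rbar = rbar, n = n),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("circular mean %.3f +/- %.3f rad (Rbar = %.3f, n = %d)\n",
              x$mean, x$sd, x$rbar, x$n))
  invisible(x)
}

# internal: second trigonometric moment about the mean direction
rho2_about_mean <- function(angles, mu) mean(cos(2 * (angles - mu)))

#' Watson's large-sample one-sample test of mean direction
#'
#' Nonparametric large-sample test that the population mean direction
#' equals `mu0`: the wrapped deviation of the sample mean direction from
#' `mu0` is standardised by the circular dispersion
#' `delta = (1 - rho2) / (2 * Rbar^2)` and referred to the standard
#' normal (two-sided).
#'
#' @param angles circular sample, radians; at least 25 values (the
#'   large-sample regime).
#' @param mu0 hypothesised mean direction, radians.
#' @return an object of class `watson_test` with `statistic` (z),
#'   `p_value` (floored at 1e-16), `dispersion`, `n`, `mu0`.
#' @export
watson_one_sample <- function(angles, mu0 = 0) {
  angles <- wrap_angle(as.numeric(angles))
  n <- length(angles)
  if (n < 25L) abort("n < 25: the large-sample test does not apply; bootstrap instead")
  s <- circ_summary(angles)
  rho2 <- rho2_about_mean(angles, s$mean)
  disp <- (1 - rho2) / (2 * s$rbar^2)
  if (!is.finite(disp) || disp <= 0) abort("degenerate circular dispersion")
  z <- wrap_angle(s$mean - mu0) / sqrt(disp / n)
  p <- max(2 * stats::pnorm(-abs(z)), 1e-16)
  structure(list(statistic = z, p_value = p, dispersion = disp, n = n,
                 mu0 = mu0, mean = s$mean,
                 method = "Watson large-sample one-sample test of mean direction"),
            class = "watson_test")
}

# internal: Watson U2 statistic for two samples on pooled ranks.
# `sorted_groups` is the group indicator (TRUE = sample a) ordered by the
# pooled sorted values.  `block` groups tied pooled values: the empirical
# CDF difference is evaluated once per tied block (weighted by its size),
# so identical samples give exactly U2 = 0.
watson_u2_stat <- function(sorted_groups, n_a, n_b, block_ends = NULL,
                           block_sizes = NULL) {
  nn <- n_a + n_b
  d <- cumsum(sorted_groups) / n_a - cumsum(!sorted_groups) / n_b
  if (!is.null(block_ends)) {
    d <- d[block_ends]
    w <- block_sizes
  } else w <- rep(1, nn)
  (n_a * n_b / nn^2) * (sum(w * d^2) - sum(w * d)^2 / nn)
}

# internal: asymptotic tail probability of Watson's U2
watson_u2_p_asymptotic <- function(u2) {
  k <- 1:10
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
  min(max(p, 1e-16), 1)
}

#' Watson's two-sample U-squared test
#'
#' Tests whether two circular samples are drawn from a common
#' distribution using Watson's U2 on the pooled ranks.  The p-value is
#' obtained by random permutation of the group labels (seeded), with the
#' asymptotic value reported alongside.
#'
#' @param a,b circular samples, radians; at least 8 values each.
#' @param n_permutations number of label permutations (default 1e4).
#' @param seed RNG seed for the permutations.
#' @return an object of class `watson_test` with `statistic` (U2),
#'   `p_value` (permutation), `p_asymptotic`, `n_a`, `n_b`, and a
#'   `tie_warning` flag set when more than 25% of the pooled values tie
#'   (rank statistic degraded).
#' @export
watson_two_sample <- function(a, b, n_permutations = 1e4, seed = 1L) {
  a <- wrap_angle(as.numeric(a)); b <- wrap_angle(as.numeric(b))
  n_a <- length(a); n_b <- length(b)
  if (n_a < 8L || n_b < 8L) abort("each sample must contain at least 8 angles")
  pooled <- c(a, b)
  ties <- 1 - length(unique(pooled)) / length(pooled)
  ord <- order(pooled)
  grp <- c(rep(TRUE, n_a), rep(FALSE, n_b))[ord]
  sorted <- pooled[ord]
  ends <- which(c(sorted[-1] != sorted[-length(sorted)], TRUE))
  sizes <- diff(c(0L, ends))
  u2 <- watson_u2_stat(grp, n_a, n_b, ends, sizes)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i)
      watson_u2_stat(sample(grp), n_a, n_b, ends, sizes) >= u2, logical(1)))
  })
  p_perm <- (exceed + 1) / (n_permutations + 1)
  structure(list(statistic = u2, p_value = p_perm,
                 p_asymptotic = watson_u2_p_asymptotic(u2),
                 n_a = n_a, n_b = n_b, n_permutations = n_permutations,
                 tie_warning = ties > 0.25,
                 method = "Watson two-sample U2 test (permutation p)"),
            class = "watson_test")
}

#' @export
print.watson_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f, p %s\n", x$statistic,
              format.pval(x$p_value, digits = 3)))
  if (!is.null(x$tie_warning) && isTRUE(x$tie_warning))
    cat("  warning: > 25% ties in the pooled sample\n")
  invisible(x)
}

#' Circular histogram
#'
#' Counts angles in equal-width bins partitioning (-pi, pi]; counts are
#' conserved.  `plot()` draws the rose diagram.
#'
#' @param angles circular sample, radians.
#' @param n_bins number of bins (default 36).
#' @return an object of class `circ_hist`: `counts`, `breaks`, `mids`,
#'   `n`.
#' @export
circ_hist <- function(angles, n_bins = 36L) {
  angles <- wrap_angle(as.numeric(angles))
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  # half-open (lo, hi] bins matching the wrap convention
  idx <- findInterval(angles, breaks, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx == 0L] <- 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = counts, breaks = breaks,
                 mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                 n = length(angles)),
            class = "circ_hist")
}

#' @export
plot.circ_hist <- function(x, col = "orange", ...) {
  r <- sqrt(x$counts / max(x$counts, 1))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE, fg = "grey70")
  for (i in seq_along(x$counts)) {
    if (x$counts[i] == 0) next
    th <- seq(x$breaks[i], x$breaks[i + 1], length.out = 8)
    graphics::polygon(c(0, r[i] * cos(th)), c(0, r[i] * sin(th)),
                      col = col, border = "grey30")
  }
  graphics::text(c(1.08, 0, -1.08, 0), c(0, 1.08, 0, -1.08),
                 c("0", expression(pi / 2), expression(pi), expression(-pi / 2)))
  invisible(x)
}

#' Angular Q-Q quantile matching of two circular samples
#'
#' Centres each sample on its own circular mean (raw angular quantiles
#' depend on an arbitrary cut point), wraps, sorts, and matches quantiles
#' at probabilities k/(m+1), k = 1..m, m = min(n_a, n_b), by linear
#' interpolation.  Samples from the same shape of distribution fall on
#' the identity line regardless of a rotation between them.
#'
#' @param a,b circular samples, radians; at least 5 values each.
#' @return an object of class `angular_qq`: `quantiles` (m x 2 matrix),
#'   `max_abs_deviation` and `mean_abs_deviation` from the identity line.
#' @export
angular_qq <- function(a, b) {
  a <- wrap_angle(as.numeric(a)); b <- wrap_angle(as.numeric(b))
  if (length(a) < 5L || length(b) < 5L) abort("each sample must contain at least 5 angles")
  centre <- function(x) sort(wrap_angle(x - circ_summary(x)$mean))
  ca <- centre(a); cb <- centre(b)
  m <- min(length(a), length(b))
  p <- seq_len(m) / (m + 1)
  qa <- stats::quantile(ca, p, names = FALSE, type = 7)
  qb <- stats::quantile(cb, p, names = FALSE, type = 7)
  dev <- abs(qa - qb)
  structure(list(quantiles = cbind(a = qa, b = qb),
                 max_abs_deviation = max(dev),
                 mean_abs_deviation = mean(dev),
                 centering = "each sample centred on its own circular mean"),
            class = "angular_qq")
}

#' @export
plot.angular_qq <- function(x, ...) {
  graphics::plot(x$quantiles[, 1], x$quantiles[, 2], asp = 1,
                 xlab = "sample a quantiles (rad)", ylab = "sample b quantiles (rad)",
                 pch = 16, cex = 0.6, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used for calibration simulations of the
#' circular tests.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0; 0 is uniform).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) abort("`kappa` must be >= 0")
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  bb <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + bb^2) / (2 * bb)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  wrap_angle(out + mu)
}
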