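#' Fit a maturity ogive (logistic regression of maturity on length)
#'
#' Maximum-likelihood logit fit of the binary maturity outcome on total
#' length, `P(mature) = logistic(a + b * L)`. The length at 50% maturity is
#' `L50 = -a / b`. Log-likelihoods of the fitted and the intercept-only
#' model are retained for Nagelkerke's R².
#'
#' With completely separated data (every immature fish shorter than every
#' mature one) the MLE does not exist; the fit is flagged
#' `converged = FALSE` and `L50` is reported as the midpoint of the
#' separation gap, with a warning.
#'
#' @param length numeric lengths in cm, or a data frame with columns
#'   `length` (or `length_cm`) and `mature`.
#' @param mature logical (or 0/1) maturity outcomes.
#' @param class_midpoints if `TRUE`, lengths are first binned into 1-cm
#'   classes and replaced by the class midpoint (`floor(L) + 0.5`).
#' @return An `ogive_fit`: `intercept`, `slope` (per cm), `L50` (cm),
#'   `loglik_full`, `loglik_null`, `n`, `nagelkerke_r2`, `converged`.
#' @export
fit_ogive <- function(length, mature = NULL, class_midpoints = FALSE) {
  if (is.data.frame(length)) {
    df <- length
    len <- df$length %||% df$length_cm
    mature <- df$mature
  } else len <- length
  stopifnot(!is.null(len), !is.null(mature))
  mat <- as.integer(as.logical(mature))
  keep <- !is.na(len) & !is.na(mat)
  len <- len[keep]; mat <- mat[keep]
  n <- length(len)
  if (n < 2) stop("need at least 2 records")
  if (any(len <= 0)) stop("lengths must be positive")
  if (all(mat == 0) || all(mat == 1))
    stop("all records have the same maturity outcome; ogive undefined")
  if (class_midpoints) len <- floor(len) + 0.5

  separated <- max(len[mat == 0]) < min(len[mat == 1])
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, len), mat,
                   family = stats::binomial(link = "logit"))
  )
  co <- fit$coefficients
  ll_full <- -fit$deviance / 2
  p0 <- mean(mat)
  ll_null <- n * (p0 * log(p0) + (1 - p0) * log(1 - p0))
  converged <- isTRUE(fit$converged) && !separated && co[2] != 0
  L50 <- if (separated) {
    (max(len[mat == 0]) + min(len[mat == 1])) / 2
  } else -co[1] / co[2]
  if (separated)
    warning("complete separation: L50 reported as the separation midpoint (",
            signif(L50, 4), " cm), coefficients are not maximum-likelihood")
  out <- list(intercept = unname(co[1]), slope = unname(co[2]),
              L50 = unname(L50),
              loglik_full = ll_full, loglik_null = ll_null, n = n,
              nagelkerke_r2 = nagelkerke(ll_null, ll_full, n),
              converged = converged)
  class(out) <- "ogive_fit"
  out
}

#' Nagelkerke's pseudo R² for a logistic model
#'
#' Cox-Snell `1 - exp(2 (ll0 - ll1) / n)` rescaled by its maximum
#' `1 - exp(2 ll0 / n)` so that a saturated fit scores 1.
#'
#' @param loglik_null,loglik_full log-likelihoods of the intercept-only and
#'   the fitted model.
#' @param n number of observations.
#' @return R² in \[0, 1\].
#' @export
nagelkerke <- function(loglik_null, loglik_full, n) {
  if (n < 1) stop("n must be >= 1")
  if (loglik_full < loglik_null - 1e-8)
    stop("loglik_full must be >= loglik_null")
  cox_snell <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  r2 <- cox_snell / (1 - exp(2 * loglik_null / n))
  min(max(r2, 0), 1)
}

#' Predicted mature proportion along the ogive
#'
#' @param fit an `ogive_fit` (must have converged).
#' @param lengths numeric vector of lengths in cm.
#' @return predicted proportions; exactly 0.5 at `fit$L50`.
#' @export
ogive_curve <- function(fit, lengths) {
  stopifnot(inherits(fit, "ogive_fit"))
  if (!fit$converged) stop("ogive fit did not converge; no curve available")
  stats::plogis(fit$slope * (lengths - fit$L50))
}

#' Non-parametric bootstrap of L50
#'
#' Case (pairs) resampling: records are resampled with replacement, the
#' ogive refitted, and the per-replicate L50 collected. Replicates where the
#' fit fails, separates, or yields a non-positive slope are dropped and
#' counted. The interval is the percentile 2.5/97.5 of the retained L50s.
#'
#' @param length,mature as in [fit_ogive()] (data frame or two vectors).
#' @param reps bootstrap replications (default 1000).
#' @param seed integer seed, required.
#' @param class_midpoints passed to the refits.
#' @return A `bootstrap_result`: `reps`, `L50_median`, `ci_low`, `ci_high`,
#'   `values` (per-replicate L50), `n_dropped`, `seed`, `warning` flag set
#'   when more than 20% of replicates were dropped.
#' @export
bootstrap_L50 <- function(length, mature = NULL, reps = 1000, seed,
                          class_midpoints = FALSE) {
  if (missing(seed)) stop("bootstrap_L50 requires a seed")
  if (is.data.frame(length)) {
    len <- length$length %||% length$length_cm
    mature <- length$mature
  } else len <- length
  mat <- as.integer(as.logical(mature))
  full <- fit_ogive(len, mat, class_midpoints = class_midpoints)
  n <- length(len)
  with_seed(seed, {
    vals <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- tryCatch(
        suppressWarnings(fit_ogive(len[idx], mat[idx],
                                   class_midpoints = class_midpoints)),
        error = function(e) NULL)
      if (!is.null(f) && f$converged && f$slope > 0) vals[r] <- f$L50
    }
    ok <- vals[!is.na(vals)]
    n_dropped <- reps - length(ok)
    warn <- n_dropped > 0.2 * reps
    if (warn)
      warning(n_dropped, " of ", reps,
              " bootstrap replicates dropped (non-converged)")
    if (length(ok) == 0) stop("no bootstrap replicate converged")
    ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
    out <- list(reps = reps, L50_median = stats::median(ok),
                ci_low = ci[1], ci_high = ci[2], values = vals,
                n_dropped = n_dropped, seed = as.integer(seed),
                warning = warn, fit = full)
    class(out) <- "bootstrap_result"
    out
  })
}

#' @export
print.ogive_fit <- function(x, ...) {
  cat("<ogive_fit> n = ", x$n, ", L50 = ", signif(x$L50, 4),
      " cm, slope = ", signif(x$slope, 4), " per cm\n", sep = "")
  cat(sprintf("Nagelkerke R2 = %.3f; converged: %s\n",
              x$nagelkerke_r2, x$converged))
  invisible(x)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$reps, " reps (", x$n_dropped, " dropped)\n",
      "L50 median ", signif(x$L50_median, 4), " cm, 95% CI [",
      signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "] cm\n", sep = "")
  invisible(x)
}

#' Plot a maturity ogive
#'
#' Base-graphics rendering of the fitted curve, the observed outcomes, the
#' L50 marker and, when a bootstrap result is supplied, the CI band.
#'
#' @param fit an `ogive_fit`.
#' @param length,mature the data used for the fit.
#' @param boot optional `bootstrap_result`.
#' @param ... passed to `plot`.
#' @export
plot_ogive <- function(fit, length, mature, boot = NULL, ...) {
  xs <- seq(min(length) - 1, max(length) + 1, length.out = 200)
  plot(xs, ogive_curve(fit, xs), type = "l", xlab = "total length (cm)",
       ylab = "proportion mature", ylim = c(0, 1), ...)
  points(length, jitter(as.numeric(mature), amount = 0.02),
         col = "grey50", pch = 16, cex = 0.6)
  if (!is.null(boot)) {
    graphics::abline(v = c(boot$ci_low, boot$ci_high), lty = 3,
                     col = "grey40")
  }
  graphics::abline(v = fit$L50, lty = 2)
  graphics::points(fit$L50, 0.5, pch = 19)
  invisible(fit)
}
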