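# Decomposing Ks distributions into Gaussian components to locate
# whole-genome-duplication peaks.

#' Remove saturated Ks values
#'
#' Values exceeding `max_ks` are excluded as likely substitution-saturated;
#' the boundary value itself is kept ("exceeding" is strict). `NA` values
#' (pairs flagged saturated by [ng86()]) are also dropped.
#'
#' @param ks_values Numeric vector of Ks values.
#' @param max_ks Saturation threshold (default 5).
#' @return The filtered vector; the number of removals is attached as
#'   attribute `n_removed` and reported via `message()`.
#' @export
#' @examples
#' filter_saturated(c(1.2, 5.1, 0.3))  # drops 5.1
filter_saturated <- function(ks_values, max_ks = 5.0) {
  if (!is.numeric(max_ks) || length(max_ks) != 1L || max_ks <= 0)
    stop("max_ks must be a positive number")
  keep <- !is.na(ks_values) & ks_values <= max_ks
  out <- ks_values[keep]
  n_removed <- length(ks_values) - length(out)
  if (n_removed > 0)
    message(n_removed, " Ks value(s) removed as saturated (> ", max_ks,
            " or undefined)")
  attr(out, "n_removed") <- n_removed
  out
}

.fd_breaks <- function(x) {
  bw <- 2 * IQR(x) / length(x)^(1 / 3)  # Freedman-Diaconis
  if (bw <= 0) bw <- diff(range(x)) / ceiling(sqrt(length(x)))
  if (bw <= 0) stop("degenerate Ks distribution: all values identical")
  seq(min(x), max(x) + bw, by = bw)
}

#' Fit Gaussian mixture models to a Ks distribution
#'
#' Mixtures with `k` components over `k_range` are fitted by EM (univariate,
#' unequal variances, via \pkg{mclust}). For each fit a coefficient of
#' determination R^2 is computed between the mixture density and a
#' histogram density estimate (Freedman-Diaconis bin width, evaluated at bin
#' midpoints). The smallest `k` whose R^2 exceeds `r2_threshold` is
#' selected; if none qualifies, the best-R^2 `k` is returned with a warning.
#' BIC is reported as a secondary diagnostic.
#'
#' @param ks_values Filtered Ks values (>= 50 required).
#' @param k_range Candidate component counts (default `1:4`).
#' @param seed Integer seed (EM initialization is deterministic, but the
#'   seed is set and recorded for reproducibility of the whole stage).
#' @param r2_threshold R^2 acceptance threshold (default 0.95).
#' @return An object of class `gmm_fit`: `k`, `weights`, `means`, `sds`
#'   (components sorted by ascending mean), `r_squared`, `bic`,
#'   `dominant_peak` (mean of the heaviest component), `r_squared_all`,
#'   `seed`.
#' @export
fit_ks_mixture <- function(ks_values, k_range = 1:4, seed = 1L,
                           r2_threshold = 0.95) {
  ks_values <- as.numeric(ks_values)
  if (length(ks_values) < 50L)
    stop("need at least 50 Ks values to fit a mixture (got ",
         length(ks_values), ")")
  if (anyNA(ks_values)) stop("Ks values contain NA; filter first")
  set.seed(seed)

  breaks <- .fd_breaks(ks_values)
  h <- graphics::hist(ks_values, breaks = breaks, plot = FALSE)
  mids <- h$mids
  dens <- h$density

  fits <- list()
  for (k in k_range) {
    fit <- tryCatch(
      mclust::Mclust(ks_values, G = k, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    w <- fit$parameters$pro
    m <- fit$parameters$mean
    v <- fit$parameters$variance$sigmasq
    if (length(v) == 1L) v <- rep(v, k)
    s <- sqrt(v)
    fitted_dens <- vapply(mids, function(x) sum(w * dnorm(x, m, s)),
                          numeric(1))
    r2 <- 1 - sum((dens - fitted_dens)^2) / sum((dens - mean(dens))^2)
    fits[[as.character(k)]] <- list(k = k, weights = w, means = m, sds = s,
                                    r2 = r2, bic = fit$bic)
  }
  if (length(fits) == 0L)
    stop("EM failed to converge for every k in ",
         paste(range(k_range), collapse = ".."),
         "; n = ", length(ks_values),
         ", range = ", paste(signif(range(ks_values), 4), collapse = ".."))

  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  ok <- which(r2s > r2_threshold)
  if (length(ok)) {
    chosen <- fits[[ok[1]]]  # smallest k achieving the threshold
  } else {
    warning("no mixture reached R^2 > ", r2_threshold,
            "; returning the best fit (R^2 = ", signif(max(r2s), 4), ")")
    chosen <- fits[[which.max(r2s)]]
  }
  ord <- order(chosen$means)
  weights <- chosen$weights[ord]
  means <- chosen$means[ord]
  sds <- chosen$sds[ord]
  structure(list(k = chosen$k,
                 weights = weights, means = means, sds = sds,
                 r_squared = chosen$r2, bic = chosen$bic,
                 dominant_peak = means[which.max(weights)],
                 r_squared_all = setNames(unname(r2s), names(fits)),
                 seed = seed),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d (R^2 = %.4f, BIC = %.1f)\n",
              x$k, x$r_squared, x$bic))
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: weight %.3f, mean %.4f, sd %.4f\n",
                i, x$weights[i], x$means[i], x$sds[i]))
  cat(sprintf("  dominant peak at Ks = %.4f\n", x$dominant_peak))
  invisible(x)
}

#' Summary statistics of a Ks set
#'
#' @param ks_values Non-empty numeric vector (apply [filter_saturated()]
#'   first).
#' @return A list with `mean`, `median`, `n`.
#' @export
summarize_ks <- function(ks_values) {
  if (length(ks_values) == 0L) stop("empty Ks set")
  if (anyNA(ks_values)) stop("Ks values contain NA; filter first")
  list(mean = mean(ks_values), median = median(ks_values),
       n = length(ks_values))
}
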