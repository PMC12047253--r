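#' Beta-binomial background-error parameters
#'
#' Container for the (alpha, beta) shape parameters of the beta
#' distribution describing the per-site background error rate.  Every
#' significance decision in the caller (noise, germline, panel of
#' normals, single-cell genotyping, scWGS support) is a one-sided tail
#' test under the beta-binomial distribution these parameters define.
#'
#' @param alpha,beta Positive shape parameters of the error-rate beta
#'   distribution.  The mean background error rate is
#'   `alpha / (alpha + beta)`.
#' @param n_sites_fit Number of homozygous-reference sites used during
#'   fitting (`NA` for manually specified parameters).
#' @param source Character tag recording where the parameters came from
#'   (`"fit"`, `"default_LR"`, or `"manual"`).
#' @return An object of class `beta_params`.
#' @examples
#' beta_params(0.21, 104.95)
#' @export
beta_params <- function(alpha, beta, n_sites_fit = NA_integer_,
                        source = "manual") {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1L,
            length(beta) == 1L, alpha > 0, beta > 0)
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         n_sites_fit = as.integer(n_sites_fit), source = source),
    class = "beta_params"
  )
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf(
    "beta_params: alpha = %.6g, beta = %.6g (mean error rate %.3g)\n",
    x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  if (!is.na(x$n_sites_fit))
    cat(sprintf("  fitted on %d sites [%s]\n", x$n_sites_fit, x$source))
  invisible(x)
}

#' Shipped long-read error parameters
#'
#' Default beta-binomial parameters for PacBio-grade long-read
#' single-cell RNA-seq.  The `"primary"` set parameterizes the main
#' alternative-allele test, the `"other"` set the test applied to the
#' residual non-reference alleles at a locus after removing reads that
#' carry the candidate allele.
#'
#' @param which `"primary"` or `"other"`.
#' @return A [beta_params()] object.
#' @examples
#' default_beta_params("primary")
#' @export
default_beta_params <- function(which = c("primary", "other")) {
  which <- match.arg(which)
  if (which == "primary")
    beta_params(0.21, 104.95, source = "default_LR")
  else
    beta_params(0.25, 162.04, source = "default_LR")
}

as_beta_params <- function(params) {
  if (inherits(params, "beta_params")) return(params)
  if (is.numeric(params) && length(params) == 2L)
    return(beta_params(params[[1L]], params[[2L]]))
  stop("`params` must be a beta_params object or a numeric vector of length 2")
}

#' Beta-binomial probability mass function
#'
#' `P(X = k)` for `X ~ BetaBinomial(n, alpha, beta)`, computed on the
#' log-gamma scale.  Vectorized over `k` and `n`.
#'
#' @param k Number of successes (non-reference reads), `0 <= k <= n`.
#' @param n Number of trials (read depth).
#' @param params A [beta_params()] object (or numeric `c(alpha, beta)`).
#' @return Numeric vector of probabilities.
#' @export
bb_pmf <- function(k, n, params) {
  params <- as_beta_params(params)
  if (any(n < 0) || any(k < 0) || any(k > n))
    stop("invalid input: require 0 <= k <= n and n >= 0")
  exp(lchoose(n, k) + lbeta(k + params$alpha, n - k + params$beta) -
        lbeta(params$alpha, params$beta))
}

#' One-sided beta-binomial tail probability
#'
#' `P(X >= k)` for `X ~ BetaBinomial(n, alpha, beta)`: the p-value used
#' to decide whether an observed non-reference (or alternative) read
#' count is higher than expected under the background error model.
#' `bb_tail(0, n) == 1` exactly, and the tail is non-increasing in `k`
#' at fixed `n`.  Vectorized over `k` and `n`.
#'
#' @inheritParams bb_pmf
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' bb_tail(5, 30, default_beta_params("primary"))
#' bb_tail(2, 4, beta_params(1, 1))  # uniform case: (n - k + 1)/(n + 1)
#' @export
bb_tail <- function(k, n, params) {
  params <- as_beta_params(params)
  if (length(n) == 1L && length(k) > 1L) n <- rep(n, length(k))
  if (length(k) == 1L && length(n) > 1L) k <- rep(k, length(n))
  if (any(n < 0) || any(k < 0) || any(k > n))
    stop("invalid input: require 0 <= k <= n and n >= 0")
  a <- params$alpha; b <- params$beta
  lb0 <- lbeta(a, b)
  vapply(seq_along(k), function(i) {
    ki <- k[i]; ni <- n[i]
    if (ki <= 0) return(1)
    # sum the smaller side of the distribution for accuracy
    if (ki <= ni - ki + 1) {
      j <- 0:(ki - 1L)
      p <- 1 - sum(exp(lchoose(ni, j) + lbeta(j + a, ni - j + b) - lb0))
      max(p, 0)
    } else {
      j <- ki:ni
      min(sum(exp(lchoose(ni, j) + lbeta(j + a, ni - j + b) - lb0)), 1)
    }
  }, numeric(1L))
}

#' Strict significance decision
#'
#' TRUE iff the one-sided beta-binomial tail p-value is strictly below
#' `alpha_level`.  All thresholds in the calling filters use strict
#' inequality, so a p-value exactly at the level is not significant.
#'
#' @inheritParams bb_pmf
#' @param alpha_level Significance level in `(0, 1]`.
#' @return Logical vector.
#' @export
is_significant <- function(k, n, params, alpha_level) {
  bb_tail(k, n, params) < alpha_level
}

#' Fit the background error distribution
#'
#' Maximum-likelihood fit of the beta-binomial error model from
#' non-reference counts at homozygous-reference sites, initialized by
#' the method of moments.  Sites with depth 0 are dropped.  If there is
#' no dispersion signal (all non-reference counts zero) the fit is
#' degenerate and the shipped long-read defaults are returned with a
#' warning.
#'
#' @param nonref Integer vector of non-reference read counts per site.
#' @param depth Integer vector of site depths (same length).
#' @param min_sites Minimum number of usable sites; below this the fit
#'   refuses and suggests the shipped defaults.
#' @param max_sites Sites are randomly subsampled to at most this many
#'   before fitting (fixed by `seed` for reproducibility).
#' @param seed Integer seed used only for the subsampling step.
#' @return A [beta_params()] object with `source = "fit"`.
#' @examples
#' set.seed(1)
#' p <- rbeta(2000, 0.21, 104.95)
#' d <- rpois(2000, 30) + 1L
#' k <- rbinom(2000, d, p)
#' fit_background(k, d, min_sites = 1000)
#' @export
fit_background <- function(nonref, depth, min_sites = 1000L,
                           max_sites = 500000L, seed = 1L) {
  stopifnot(length(nonref) == length(depth))
  keep <- depth >= 1L
  nonref <- as.numeric(nonref[keep]); depth <- as.numeric(depth[keep])
  if (any(nonref > depth) || any(nonref < 0))
    stop("invalid site observations: require 0 <= nonref <= depth")
  if (length(depth) < min_sites)
    stop("fewer than ", min_sites, " sites with depth >= 1; ",
         "use default_beta_params() instead of fitting")
  if (length(depth) > max_sites) {
    idx <- local({
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      sample.int(length(depth), max_sites)
    })
    nonref <- nonref[idx]; depth <- depth[idx]
  }
  if (all(nonref == 0)) {
    warning("degenerate fit: all non-reference counts are zero; ",
            "returning shipped long-read defaults")
    return(default_beta_params("primary"))
  }
  # collapse duplicated (k, n) pairs for speed
  tab <- data.table::data.table(k = nonref, n = depth)
  tab <- tab[, list(w = .N), by = c("k", "n")]

  # method-of-moments start from per-site proportions
  ph <- tab[, sum(w * k / n) / sum(w)]
  vh <- tab[, sum(w * (k / n - ph)^2) / (sum(w) - 1)]
  m <- max(ph, 1e-6)
  s <- if (vh > m * (1 - m) / mean(depth)) {
    # crude moment inversion ignoring depth heterogeneity
    max(m * (1 - m) / vh - 1, 0.5)
  } else 100
  start <- log(c(m * s, (1 - m) * s))

  nll <- function(lp) {
    a <- exp(lp[1L]); b <- exp(lp[2L])
    -sum(tab$w * (lchoose(tab$n, tab$k) +
                    lbeta(tab$k + a, tab$n - tab$k + b) - lbeta(a, b)))
  }
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  beta_params(exp(fit$par[1L]), exp(fit$par[2L]),
              n_sites_fit = length(depth), source = "fit")
}

#' Persist / restore error parameters
#'
#' Small YAML sidecar so a fitted error model can be reused across
#' runs.
#'
#' @param params A [beta_params()] object.
#' @param path File path of the YAML sidecar.
#' @return `write_beta_params()` returns `path` invisibly;
#'   `read_beta_params()` returns a [beta_params()] object.
#' @export
write_beta_params <- function(params, path) {
  params <- as_beta_params(params)
  yaml::write_yaml(list(alpha = params$alpha, beta = params$beta,
                        n_sites_fit = params$n_sites_fit,
                        source = params$source), path)
  invisible(path)
}

#' @rdname write_beta_params
#' @export
read_beta_params <- function(path) {
  x <- yaml::read_yaml(path)
  beta_params(x$alpha, x$beta,
              n_sites_fit = if (is.null(x$n_sites_fit)) NA else x$n_sites_fit,
              source = if (is.null(x$source)) "manual" else x$source)
}

# save/restore the RNG state so helper subsampling does not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
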