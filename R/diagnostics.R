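#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance form. Convergence is flagged at
#' `R-hat <= 1.05` for every parameter.
#'
#' @param x a matrix (iterations x chains) for one parameter, a list of
#'   equal-length chain vectors, or an `scr_fit` (then computed for every
#'   parameter column).
#' @param threshold convergence threshold on R-hat.
#' @return for matrix/list input, a scalar R-hat; for an `scr_fit`, a named
#'   vector with attribute `converged`.
#' @export
gelman_rubin <- function(x, threshold = 1.05) {
  if (inherits(x, "scr_fit")) {
    pars <- monitored_parameters(x$spec)
    r <- vapply(pars, function(p) {
      gelman_rubin(sapply(x$chains, function(ch) ch$samples[, p]), threshold)
    }, numeric(1))
    attr(r, "converged") <- all(r <= threshold, na.rm = TRUE)
    return(r)
  }
  if (is.list(x) && !is.data.frame(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2L)
    stop("gelman_rubin needs >= 2 chains; split a single chain in half to use a split-chain version")
  means <- colMeans(x)
  B <- n * stats::var(means)
  W <- mean(apply(x, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

monitored_parameters <- function(spec) {
  pars <- c("lambda0", "sigma_F", "beta_eff", "psi", "psi_sex", "N_super")
  if (spec$sigma_sex_specific) pars <- append(pars, "sigma_M", after = 2)
  if (spec$include_playback) pars <- c(pars, "beta_eff2")
  if (spec$lambda0_sex_specific) pars <- c(pars, "beta_sex")
  pars
}

#' Highest posterior density interval
#'
#' Shortest contiguous window of sorted draws containing `ceiling(mass * n)`
#' samples; ties broken to the earliest window, so the result is
#' deterministic and brute-force verifiable.
#'
#' @param samples numeric draws.
#' @param mass interval mass, default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m < 1 || n < ceiling(1 / (1 - mass)))
    stop(sprintf("need at least %d samples for mass %.3f", ceiling(1 / (1 - mass)), mass))
  if (m >= n) return(c(x[1], x[n]))
  w <- x[seq.int(m, n)] - x[seq.int(1, n - m + 1)]
  i <- which.min(w)                      # which.min takes the earliest tie
  c(x[i], x[i + m - 1L])
}

#' Log marginal likelihood by the harmonic-mean estimator
#'
#' `log ML = -(logsumexp(-loglik) - log(T))`, computed stably in log space
#' from the stored per-iteration complete-data log likelihoods. Larger
#' values indicate more supported candidate models.
#'
#' @param loglik numeric vector of per-iteration log likelihood draws, or an
#'   `scr_fit` (pooled across chains).
#' @export
mlhm <- function(loglik) {
  if (inherits(loglik, "scr_fit")) loglik <- posterior_draws(loglik)[, "loglik"]
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood draws")
  nl <- -loglik
  mx <- max(nl)
  -(mx + log(mean(exp(nl - mx))))
}

#' Bayesian p-value from the posterior predictive check
#'
#' At every stored latent draw the sampler simulates a replicate data set
#' under the current parameters and latent states and evaluates the
#' Freeman-Tukey discrepancy over individual encounter frequencies,
#' `T = sum_i (sqrt(n_i) - sqrt(e_i))^2`. The p-value is the fraction of
#' draws with `T(rep) >= T(obs)` (ties count as extreme); values inside
#' roughly (0.15, 0.85) indicate adequate fit.
#'
#' @param fit an `scr_fit` with stored latent draws.
#' @return scalar p-value with attribute `discrepancy` (the pooled `T_obs`
#'   and `T_rep` draws).
#' @export
bayesian_p_value <- function(fit) {
  To <- unlist(lapply(fit$chains, `[[`, "T_obs"))
  Tr <- unlist(lapply(fit$chains, `[[`, "T_rep"))
  if (!length(To)) stop("no stored latent draws: refit with a latent_thin that stores draws")
  p <- mean(Tr >= To)
  attr(p, "discrepancy") <- cbind(T_obs = To, T_rep = Tr)
  p
}

#' Pairwise posterior correlations between parameters
#'
#' Pearson correlations of the pooled chains, with redundancy flags for
#' pairs above a threshold; rows involving the density-linked parameters
#' (`psi`, `N_super`) are the ones to watch for parameter redundancy.
#'
#' @param fit an `scr_fit` or a draws matrix.
#' @param threshold absolute correlation above which a pair is flagged.
#' @param plot_file optional path: writes a pairs plot (PNG or PDF by
#'   extension).
#' @return an `scr_correlations`: list with the correlation matrix and a
#'   data frame of flagged pairs (constant columns give `NA` correlations
#'   and are reported in `constant`).
#' @export
pairwise_correlations <- function(fit, threshold = 0.9, plot_file = NULL) {
  m <- if (inherits(fit, "scr_fit"))
    posterior_draws(fit)[, monitored_parameters(fit$spec), drop = FALSE]
  else as.matrix(fit)
  if (ncol(m) < 2L) stop("need at least two parameters")
  keep <- apply(m, 2, function(v) stats::sd(v) > 0)
  r <- matrix(NA_real_, ncol(m), ncol(m), dimnames = list(colnames(m), colnames(m)))
  diag(r) <- 1
  r[keep, keep] <- stats::cor(m[, keep, drop = FALSE])
  ut <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(par1 = rownames(r)[ut[, 1]], par2 = colnames(r)[ut[, 2]],
                        r = r[ut])
  if (!is.null(plot_file)) {
    ext <- tolower(tools::file_ext(plot_file))
    if (ext == "pdf") grDevices::pdf(plot_file) else grDevices::png(plot_file, 900, 900)
    sub <- m[seq(1, nrow(m), length.out = min(nrow(m), 2000)), keep, drop = FALSE]
    graphics::pairs(sub, pch = ".", main = "posterior pairwise correlations")
    grDevices::dev.off()
  }
  structure(list(correlations = r, flagged = flagged,
                 constant = colnames(m)[!keep], threshold = threshold),
            class = "scr_correlations")
}

#' @export
print.scr_correlations <- function(x, ...) {
  print(round(x$correlations, 3))
  if (nrow(x$flagged)) {
    cat(sprintf("Flagged |r| > %.2f:\n", x$threshold)); print(x$flagged)
  } else cat(sprintf("No pair exceeds |r| = %.2f\n", x$threshold))
  if (length(x$constant))
    cat("Constant (correlation undefined):", paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Posterior mean, posterior standard deviation (PSD), 95% highest posterior
#' density interval and R-hat per monitored parameter and derived quantity.
#'
#' @param fit an `scr_fit`.
#' @param extra optional named list of additional per-draw vectors (pooled
#'   length) to summarize alongside, e.g. region abundance draws.
#' @param mass HPD mass.
#' @return data frame of class `scr_summary` with columns `parameter`,
#'   `mean`, `psd`, `hpd_lower`, `hpd_upper`, `rhat`.
#' @export
posterior_summary <- function(fit, extra = NULL, mass = 0.95) {
  pars <- monitored_parameters(fit$spec)
  pooled <- posterior_draws(fit)
  multi <- length(fit$chains) >= 2L
  rows <- lapply(pars, function(p) {
    v <- pooled[, p]
    h <- hpd_interval(v, mass)
    data.frame(parameter = p, mean = mean(v), psd = stats::sd(v),
               hpd_lower = h[1], hpd_upper = h[2],
               rhat = if (multi) gelman_rubin(sapply(fit$chains, function(ch) ch$samples[, p])) else NA_real_)
  })
  if (!is.null(extra)) {
    rows <- c(rows, lapply(names(extra), function(nm) {
      v <- extra[[nm]]
      h <- hpd_interval(v, mass)
      data.frame(parameter = nm, mean = mean(v), psd = stats::sd(v),
                 hpd_lower = h[1], hpd_upper = h[2], rhat = NA_real_)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scr_summary", "data.frame")
  out
}

#' @export
summary.scr_fit <- function(object, ...) posterior_summary(object, ...)

#' Compare the candidate models on the three reported criteria
#'
#' Mechanically tabulates Bayesian p-value, log marginal likelihood (MLHM)
#' and maximum R-hat for a list of fits; no composite score is computed --
#' the criteria are reported side by side for judgment.
#'
#' @param fits named list of `scr_fit` objects.
#' @return data frame, one row per model.
#' @export
compare_models <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm,
               bayes_p = as.numeric(bayesian_p_value(f)),
               mlhm = mlhm(f),
               max_rhat = if (length(f$chains) >= 2) max(gelman_rubin(f), na.rm = TRUE) else NA_real_)
  }))
}
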