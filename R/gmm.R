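#' Fit Gaussian mixture models with BIC model selection
#'
#' Finite Gaussian mixture modelling of (typically two-dimensional)
#' points such as (genome-wide PRS, elevated-PES count) pairs.  For
#' every combination of covariance family and component count K the
#' model is fitted by expectation-maximisation with seeded k-means
#' initialisation and multiple restarts, and the fit maximising
#' `BIC = 2 * loglik - n_params * log(n)` (the mixture-model
#' convention: higher is better) is selected.
#'
#' Six covariance families are supported, crossed from shape
#' (spherical, diagonal, full) and cross-component constraint (equal,
#' variable); in mclust nomenclature: EII, VII, EEI, VVI, EEE, VVV.
#' Orientation-constrained ellipsoidal families (e.g. VEV) are not
#' implemented.
#'
#' @param points numeric matrix (n rows, d columns) or data frame.
#' @param k_range candidate component counts (default 1:9).
#' @param families subset of
#'   `c("EII","VII","EEI","VVI","EEE","VVV")`.
#' @param n_restarts EM restarts per candidate (default 10).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer seed making initialisation deterministic.
#' @return object of class `gmm_fit` for the best model: `model_name`,
#'   `K`, `weights`, `means` (K x d), `covariances` (list of d x d),
#'   `loglik`, `loglik_trace` (per accepted EM iteration), `bic`, `df`
#'   (parameter count), `assignments` (argmax posterior), `posterior`,
#'   `n`, and `bic_table` over all fitted candidates.
#' @export
fit_gmm <- function(points, k_range = 1:9,
                    families = c("EII", "VII", "EEI", "VVI", "EEE", "VVV"),
                    n_restarts = 10, max_iter = 500, tol = 1e-6,
                    seed = 1L) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  families <- match.arg(families, several.ok = TRUE)
  k_range <- k_range[k_range < n]
  if (length(k_range) == 0L) stop_input("fit_gmm: need n > max K")
  best <- NULL
  bic_rows <- list()
  for (fam in families) {
    for (k in k_range) {
      fit <- NULL
      n_try <- if (k == 1L) 1L else n_restarts
      for (r in seq_len(n_try)) {
        cand <- tryCatch(
          gmm_em_once(x, k, fam, max_iter, tol,
                      seed = derive_seed(seed, 1000L * k + r)),
          error = function(e) NULL
        )
        if (is.null(cand)) next
        if (is.null(fit) || cand$loglik > fit$loglik) fit <- cand
      }
      if (is.null(fit)) {
        pes_log("fit_gmm: %s K=%d degenerate, discarded", fam, k)
        next
      }
      npar <- gmm_n_params(fam, k, d)
      bic <- 2 * fit$loglik - npar * log(n)
      bic_rows[[length(bic_rows) + 1L]] <-
        data.frame(model = fam, K = k, loglik = fit$loglik, df = npar,
                   bic = bic, stringsAsFactors = FALSE)
      if (is.null(best) || bic > best$bic) {
        best <- c(fit, list(model_name = fam, K = k, df = npar, bic = bic,
                            n = n))
      }
    }
  }
  if (is.null(best)) stop_input("fit_gmm: all candidates degenerate")
  best$bic_table <- do.call(rbind, bic_rows)
  best$assignments <- max.col(best$posterior, ties.method = "first")
  class(best) <- "gmm_fit"
  best
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: %s model, K = %d, n = %d, loglik = %.3f, BIC = %.2f\n",
              x$model_name, x$K, x$n, x$loglik, x$bic))
  invisible(x)
}

# number of free parameters: weights + means + covariance structure
gmm_n_params <- function(family, k, d) {
  cov_par <- switch(family,
    EII = 1, VII = k, EEI = d, VVI = k * d,
    EEE = d * (d + 1) / 2, VVV = k * d * (d + 1) / 2
  )
  (k - 1) + k * d + cov_par
}

# One EM run from a k-means initialisation.  Returns weights, means,
# covariances (list of d x d), loglik, loglik_trace, posterior.
gmm_em_once <- function(x, k, family, max_iter, tol, seed) {
  n <- nrow(x); d <- ncol(x)
  floor_scale <- 1e-6 * mean(diag(stats::cov(x)))
  if (!is.finite(floor_scale) || floor_scale <= 0) floor_scale <- 1e-10
  set.seed(seed)
  if (k == 1L) {
    z <- matrix(1, n, 1)
  } else {
    km <- stats::kmeans(jitter_dups(x), centers = k, nstart = 1,
                        iter.max = 50)
    z <- matrix(0, n, k)
    z[cbind(seq_len(n), km$cluster)] <- 1
  }
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  params <- NULL
  for (it in seq_len(max_iter)) {
    params <- gmm_mstep(x, z, family, floor_scale)
    dens <- gmm_log_dens(x, params)           # n x k log(w_j f_j)
    mx <- apply(dens, 1, max)
    lse <- mx + log(rowSums(exp(dens - mx)))
    ll <- sum(lse)
    if (!is.finite(ll)) stop("EM diverged")
    z <- exp(dens - lse)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) break
    ll_old <- ll
  }
  if (any(params$weights < 1e-10)) stop("component collapsed")
  if (isTRUE(params$floored)) stop("collapsing covariance at convergence")
  list(weights = params$weights, means = params$means,
       covariances = params$covariances, loglik = ll,
       loglik_trace = loglik_trace, posterior = z)
}

# break exact duplicate rows so kmeans can find k distinct centres
jitter_dups <- function(x) {
  if (anyDuplicated(x)) {
    x + matrix(stats::rnorm(length(x), sd = 1e-8 * (stats::sd(x) + 1)),
               nrow(x))
  } else x
}

gmm_mstep <- function(x, z, family, floor_scale) {
  n <- nrow(x); d <- ncol(x); k <- ncol(z)
  nk <- colSums(z)
  if (any(nk < 1e-8)) stop("empty component")
  w <- nk / n
  means <- t(sapply(seq_len(k), function(j) colSums(z[, j] * x) / nk[j]))
  if (d == 1L) means <- matrix(means, ncol = 1)
  scatter <- lapply(seq_len(k), function(j) {
    xc <- sweep(x, 2, means[j, ])
    crossprod(xc * z[, j], xc)   # sum_i z_ij (x_i - mu_j)(x_i - mu_j)'
  })
  covs <- switch(family,
    VVV = lapply(seq_len(k), function(j) scatter[[j]] / nk[j]),
    EEE = {
      pooled <- Reduce(`+`, scatter) / n
      rep(list(pooled), k)
    },
    VVI = lapply(seq_len(k), function(j) diag(diag(scatter[[j]]) / nk[j], d)),
    EEI = {
      pooled <- diag(diag(Reduce(`+`, scatter)) / n, d)
      rep(list(pooled), k)
    },
    VII = lapply(seq_len(k), function(j) {
      diag(rep(sum(diag(scatter[[j]])) / (nk[j] * d), d), d)
    }),
    EII = {
      s2 <- sum(vapply(scatter, function(s) sum(diag(s)), numeric(1))) / (n * d)
      rep(list(diag(rep(s2, d), d)), k)
    }
  )
  # covariance floor guards collapsing components; a floor hit marks
  # the candidate as degenerate (a spiked component, not a real cluster)
  floored <- FALSE
  covs <- lapply(covs, function(s) {
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) <
        floor_scale) {
      floored <<- TRUE
      s + diag(rep(floor_scale, d), d)
    } else s
  })
  list(weights = w, means = means, covariances = covs, floored = floored)
}

gmm_log_dens <- function(x, params) {
  k <- length(params$weights)
  n <- nrow(x); d <- ncol(x)
  out <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    s <- params$covariances[[j]]
    ch <- chol(s)
    logdet <- 2 * sum(log(diag(ch)))
    xc <- sweep(x, 2, params$means[j, ])
    maha <- colSums(backsolve(ch, t(xc), transpose = TRUE)^2)
    out[, j] <- log(params$weights[j]) -
      0.5 * (d * log(2 * pi) + logdet + maha)
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments; 1 for
#' identical partitions (up to label permutation), ~0 for independent
#' ones.
#'
#' @param a,b integer/factor vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
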