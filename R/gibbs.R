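#' Sampler configuration for the latent-noise reduced-rank regression
#'
#' Defaults follow the analysis settings: latent dimension K = 30
#' (chosen by the elbow method), 1000 Gibbs iterations with the first
#' 500 discarded as burn-in, and a low latent-noise prior scale so the
#' subject covariates absorb most of the explained variation.
#'
#' @param K Latent dimension (>= 1).
#' @param n_iter Gibbs iterations.
#' @param burn_in Discarded iterations (< n_iter).
#' @param latent_noise_sd Prior SD of the latent noise rows (default 0.1,
#'   variance 0.01).
#' @param a1,a2 Multiplicative-gamma shrinkage hyperparameters for the
#'   first and subsequent column-scale increments.
#' @param nu Local-shrinkage gamma degrees of freedom.
#' @param sigma_shape,sigma_rate Inverse-gamma prior on residual
#'   variances.
#' @param psi_prior_sd Prior SD of the subject-effect entries.
#' @param seed Integer seed for the sampler.
#' @return A `brrr_config` list.
#' @export
brrr_config <- function(K = 30, n_iter = 1000, burn_in = 500,
                        latent_noise_sd = 0.1, a1 = 2.1, a2 = 3.1, nu = 3,
                        sigma_shape = 1, sigma_rate = 1,
                        psi_prior_sd = 1, seed = 1) {
  stopifnot(K >= 1, burn_in < n_iter, latent_noise_sd > 0)
  structure(as.list(environment()), class = "brrr_config")
}

# draw from N(A^{-1} b, A^{-1}) for each column of b given chol R of A
draw_gaussian_cols <- function(R, b) {
  mean <- backsolve(R, forwardsolve(t(R), b))
  mean + backsolve(R, matrix(stats::rnorm(length(b)), nrow(b), ncol(b)))
}

#' Fit the latent-noise Bayesian reduced-rank regression by Gibbs sampling
#'
#' The generative model is `Y = (X Psi + Omega) Gamma + E` with
#' independent Gaussian residuals `E` (feature-specific variances
#' `Sigma`), latent noise rows `Omega ~ N(0, sd_Omega^2 I)`, Gaussian
#' subject effects `Psi`, and a column-wise multiplicative-gamma
#' shrinkage prior on the rows of the shared projection `Gamma` that
#' orders latent components by importance and enforces an effective rank
#' well below both the subject and feature counts. Given all other
#' blocks the model is linear-Gaussian, so `Psi`, `Omega` and `Gamma`
#' have conjugate normal full conditionals, residual variances
#' inverse-gamma, and the shrinkage variables gamma updates. The chain
#' is initialized from Fisher-LDA directions ([init_lda()]) with `Psi`
#' set to the projected class means.
#'
#' @param Y A `feature_matrix` (standardize first for real pipelines;
#'   simulation-scale inputs can be fitted raw).
#' @param X A `subject_design` aligned with `Y`.
#' @param config A [brrr_config()].
#' @return A `brrr_posterior`: retained draws (`draws$Psi` T x p x k,
#'   `draws$Omega` T x n x k, `draws$Gamma` T x k x s, `draws$Sigma`
#'   T x s), posterior means (`posterior_mean`), `ptve_trace`, and the
#'   `config`.
#' @export
gibbs_fit <- function(Y, X, config = brrr_config()) {
  stopifnot(inherits(Y, "feature_matrix"), inherits(X, "subject_design"),
            inherits(config, "brrr_config"))
  Ym <- Y$values
  Xm <- X$values
  n <- nrow(Ym); s <- ncol(Ym); p <- ncol(Xm)
  k <- config$K
  set.seed(as.integer(config$seed))

  Gamma <- init_lda(Y, X, k)
  counts <- colSums(Xm)
  class_means <- diag(1 / counts) %*% crossprod(Xm, Ym)
  GGt <- Gamma %*% t(Gamma)
  Psi <- class_means %*% t(Gamma) %*% solve(GGt + 1e-8 * diag(k))
  Omega <- matrix(0, n, k)
  resid <- Ym - (Xm %*% Psi) %*% Gamma
  sigma2 <- pmax(apply(resid, 2, stats::var), 1e-6)
  phi <- matrix(1, k, s)
  delta <- rep(1, k)
  om_prec <- 1 / config$latent_noise_sd^2
  psi_prec <- 1 / config$psi_prior_sd^2
  tYvar <- sum(apply(Ym, 2, stats::var))
  if (tYvar <= 0) stop("constant response: zero total variance")

  n_keep <- config$n_iter - config$burn_in
  dr <- list(Psi = array(NA_real_, c(n_keep, p, k)),
             Omega = array(NA_real_, c(n_keep, n, k)),
             Gamma = array(NA_real_, c(n_keep, k, s)),
             Sigma = array(NA_real_, c(n_keep, s)))
  ptve_trace <- numeric(n_keep)

  count_groups <- split(seq_len(p), counts)

  for (it in seq_len(config$n_iter)) {
    tau <- cumprod(delta)
    GDt <- t(Gamma) / sigma2              # s x k, D Gamma'
    GDG <- Gamma %*% GDt                  # k x k

    # --- Psi | Gamma, Sigma with Omega marginalized out (Woodbury):
    # rows of Y given psi are N(psi Gamma, sd_Om^2 Gamma'Gamma + D^-1),
    # so Gamma Sigma_y^-1 Gamma' = W GDG with W = I - GDG M^-1,
    # M = I/sd_Om^2 + GDG. Integrating the latent noise out of this
    # block removes the Psi-Omega coupling and mixes much faster.
    M <- GDG + diag(om_prec, k)
    W <- diag(k) - GDG %*% solve(M)
    Q <- W %*% GDG
    Q <- (Q + t(Q)) / 2
    Bp <- (crossprod(Xm, Ym) %*% GDt) %*% t(W)            # p x k
    for (g in names(count_groups)) {
      nj <- as.numeric(g)
      idx <- count_groups[[g]]
      A <- nj * Q + diag(psi_prec, k)
      R <- chol((A + t(A)) / 2)
      Psi[idx, ] <- t(draw_gaussian_cols(R, t(Bp[idx, , drop = FALSE])))
    }
    XPsi <- Xm %*% Psi

    # --- Omega | rest: shared precision across rows
    Bo <- (Ym - XPsi %*% Gamma) %*% GDt                    # n x k
    A <- GDG + diag(om_prec, k)
    R <- chol((A + t(A)) / 2)
    Omega <- t(draw_gaussian_cols(R, t(Bo)))

    # --- Gamma | rest: per-feature conjugate normal with MGP prior
    H <- XPsi + Omega
    HtH <- crossprod(H)
    HtY <- crossprod(H, Ym)                                # k x s
    for (j in seq_len(s)) {
      A <- HtH / sigma2[j] + diag(phi[, j] * tau, k)
      R <- chol((A + t(A)) / 2)
      Gamma[, j] <- draw_gaussian_cols(R, HtY[, j, drop = FALSE] / sigma2[j])
    }

    # --- residual variances
    resid <- Ym - H %*% Gamma
    rss <- colSums(resid^2)
    sigma2 <- 1 / stats::rgamma(s, shape = config$sigma_shape + n / 2,
                                rate = config$sigma_rate + rss / 2)
    if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
      stop(sprintf(paste0("divergent residual variance at iteration %d ",
                          "(min rss=%.3g, max rss=%.3g)"),
                   it, min(rss), max(rss)))
    }

    # --- multiplicative-gamma shrinkage on Gamma rows
    phi <- matrix(stats::rgamma(k * s, shape = (config$nu + 1) / 2,
                                rate = (config$nu + tau * Gamma^2) / 2),
                  k, s)
    pg2 <- rowSums(phi * Gamma^2)          # k vector
    for (l in seq_len(k)) {
      tau_nol <- cumprod(delta)[l:k] / delta[l]
      shape <- (if (l == 1) config$a1 else config$a2) + s * (k - l + 1) / 2
      rate <- 1 + sum(tau_nol * pg2[l:k]) / 2
      delta[l] <- stats::rgamma(1, shape = shape, rate = rate)
    }

    if (it > config$burn_in) {
      t_keep <- it - config$burn_in
      dr$Psi[t_keep, , ] <- Psi
      dr$Omega[t_keep, , ] <- Omega
      dr$Gamma[t_keep, , ] <- Gamma
      dr$Sigma[t_keep, ] <- sigma2
      fitted <- XPsi %*% Gamma
      ptve_trace[t_keep] <- sum(apply(fitted, 2, stats::var)) / tYvar
    }
  }

  pm <- list(Psi = apply(dr$Psi, c(2, 3), mean),
             Omega = apply(dr$Omega, c(2, 3), mean),
             Gamma = apply(dr$Gamma, c(2, 3), mean),
             Sigma = apply(dr$Sigma, 2, mean))
  pm$Theta <- pm$Psi %*% pm$Gamma
  structure(list(
    draws = dr,
    posterior_mean = pm,
    ptve_trace = ptve_trace,
    config = config,
    subject_order = X$subject_order,
    row_meta = Y$row_meta,
    standardization = Y$standardization
  ), class = "brrr_posterior")
}

#' @export
print.brrr_posterior <- function(x, ...) {
  d <- dim(x$draws$Gamma)
  cat(sprintf(paste0("<brrr_posterior: K=%d, %d retained draws, ",
                     "%d subjects x %d features; mean PTVE %.3f>\n"),
              d[2], d[1], dim(x$draws$Psi)[2], d[3], mean(x$ptve_trace)))
  invisible(x)
}

#' Proportion of total variance explained (PTVE)
#'
#' `Tr(Cov(X Psi Gamma)) / Tr(Cov(Y))`: the share of the response's
#' total variance captured by the subject-driven low-rank mean,
#' excluding the latent noise.
#'
#' @param fit A `brrr_posterior` (posterior means used) or a list with
#'   elements `Psi` and `Gamma`.
#' @param Y,X The response `feature_matrix` and `subject_design`.
#' @return Scalar in `[0, Inf)` (typically `[0, 1]`).
#' @export
ptve <- function(fit, Y, X) {
  if (inherits(fit, "brrr_posterior")) fit <- fit$posterior_mean
  stopifnot(!is.null(fit$Psi), !is.null(fit$Gamma))
  denom <- sum(apply(Y$values, 2, stats::var))
  if (denom <= 0) stop("constant response: PTVE undefined")
  fitted <- (X$values %*% fit$Psi) %*% fit$Gamma
  sum(apply(fitted, 2, stats::var)) / denom
}
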