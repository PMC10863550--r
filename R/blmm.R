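# Conjugate blocked Gibbs sampler for the Gaussian linear mixed model
#
#   y_i = x_i' beta + u_person(i) + u_set(i) + e_i,   e_i ~ N(0, sigma_e^2 / w_i)
#
# Priors: beta_j ~ N(0, sd_beta^2) on the (internally standardized) scale;
# half-Student-t(nu = 3, scale A) on each of sigma_person, sigma_set,
# sigma_e via the Huang–Wand inverse-gamma mixture
#   sigma^2 | a ~ IG(nu/2, nu/a),  a ~ IG(1/2, 1/A^2),
# which keeps every full conditional conjugate. Fixed and random effects are
# updated in one block through a sparse Cholesky solve of the joint normal
# equations (the symbolic factorization is computed once and refreshed each
# sweep), so chains mix essentially immediately; likelihood weights (used by
# the missingness-weighted sensitivity analysis) scale each observation's
# contribution.

#' Gibbs sampler for a Gaussian mixed model with two random intercepts
#'
#' Internal engine behind [fit_outcome_model()]. Operates on an already
#' standardized response/design; see the package vignette for the model and
#' prior details.
#'
#' @param y numeric response
#' @param X dense fixed-effects design matrix (including intercept)
#' @param person,set grouping factors for the random intercepts
#' @param weights positive per-observation likelihood weights
#' @param chains,iter,warmup sampler size (per chain, post-warmup `iter`)
#' @param seed integer seed; chain c uses a sub-stream of it
#' @param sd_beta prior SD of fixed-effect coefficients
#' @param halft_scale scale A of the half-t(3) priors on the three SDs
#' @return list with per-chain draws of `beta` (iter x p), `sigma`
#'   (iter x 3: person, set, residual), and dimensions
#' @keywords internal
blmm_gibbs <- function(y, X, person, set, weights = NULL,
                       chains = 2, iter = 1000, warmup = 500, seed = 1L,
                       sd_beta = 10, halft_scale = 1, nu = 3) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  person <- droplevels(factor(person))
  set <- droplevels(factor(set))
  qp <- nlevels(person)
  qs <- nlevels(set)
  p <- ncol(X)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(all(w > 0), length(w) == n)

  Zp <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(person),
                             x = 1, dims = c(n, qp))
  Zs <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(set),
                             x = 1, dims = c(n, qs))
  W <- methods::cbind2(methods::cbind2(
    Matrix::Matrix(X, sparse = TRUE), Zp), Zs)
  Ww <- W * sqrt(w)
  C <- Matrix::forceSymmetric(Matrix::crossprod(Ww))
  d <- as.numeric(Matrix::crossprod(W, w * y))
  yty <- sum(w * y^2)
  ptot <- p + qp + qs
  idx_b <- seq_len(p)
  idx_p <- p + seq_len(qp)
  idx_s <- p + qp + seq_len(qs)

  run_chain <- function(chain) {
    set.seed(sub_seed(seed, 100L + chain))
    se2 <- 1; sp2 <- 0.5; ss2 <- 0.5
    a_e <- a_p <- a_s <- 1
    keep_b <- matrix(NA_real_, iter, p,
                     dimnames = list(NULL, colnames(X)))
    keep_s <- matrix(NA_real_, iter, 3,
                     dimnames = list(NULL, c("sigma_person", "sigma_set",
                                             "sigma_resid")))
    Ch <- NULL
    for (it in seq_len(warmup + iter)) {
      prec <- c(rep(1 / sd_beta^2, p), rep(1 / sp2, qp), rep(1 / ss2, qs))
      Q <- Matrix::forceSymmetric(C / se2 + Matrix::Diagonal(x = prec))
      if (is.null(Ch)) {
        Ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
      } else {
        Ch <- Matrix::.updateCHMfactor(Ch, Q, mult = 0)
      }
      mu <- Matrix::solve(Ch, d / se2, system = "A")
      zv <- Matrix::solve(Ch, stats::rnorm(ptot), system = "Lt")
      theta <- as.numeric(mu) + as.numeric(
        Matrix::solve(Ch, zv, system = "Pt"))
      ssr <- yty - 2 * sum(theta * d) +
        as.numeric(Matrix::crossprod(theta, C %*% theta))
      ssr <- max(ssr, 1e-12)
      se2 <- 1 / stats::rgamma(1, (n + nu) / 2, rate = (ssr + nu / a_e) / 2)
      a_e <- 1 / stats::rgamma(1, (nu + 1) / 2,
                               rate = nu / se2 + 1 / halft_scale^2)
      up <- theta[idx_p]; us <- theta[idx_s]
      sp2 <- 1 / stats::rgamma(1, (qp + nu) / 2,
                               rate = (sum(up^2) + nu / a_p) / 2)
      a_p <- 1 / stats::rgamma(1, (nu + 1) / 2,
                               rate = nu / sp2 + 1 / halft_scale^2)
      ss2 <- 1 / stats::rgamma(1, (qs + nu) / 2,
                               rate = (sum(us^2) + nu / a_s) / 2)
      a_s <- 1 / stats::rgamma(1, (nu + 1) / 2,
                               rate = nu / ss2 + 1 / halft_scale^2)
      if (it > warmup) {
        keep_b[it - warmup, ] <- theta[idx_b]
        keep_s[it - warmup, ] <- sqrt(c(sp2, ss2, se2))
      }
    }
    list(beta = keep_b, sigma = keep_s)
  }
  chains_out <- lapply(seq_len(chains), run_chain)
  list(chains = chains_out, p = p, qp = qp, qs = qs, n = n,
       chains_n = chains, iter = iter, warmup = warmup)
}

#' Split-chain R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half; values near 1 indicate between-chain agreement.
#'
#' @param mat iterations x chains matrix of draws of one parameter
#' @return scalar R-hat (NA for constant draws)
#' @keywords internal
split_rhat <- function(mat) {
  half <- floor(nrow(mat) / 2)
  if (half < 2) return(NA_real_)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[half + seq_len(half), , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, stats::var)
  Wv <- mean(s2)
  if (!is.finite(Wv) || Wv <= 0) return(NA_real_)
  B <- nn * stats::var(mu)
  sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
}

# Effective sample size from pooled chains via the initial positive
# sequence of autocorrelations.
ess_basic <- function(mat) {
  x <- as.numeric(mat)
  nn <- length(x)
  if (stats::var(x) == 0) return(nn)
  ac <- stats::acf(x, lag.max = min(200, nn - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  nn / (1 + 2 * s)
}
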