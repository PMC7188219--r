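#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm pchisq plogis qnorm rnorm rbinom rgamma runif
#'   lm glm coef vcov fitted density mad sd var qr qr.resid uniroot optimize
#'   setNames predict complete.cases Gamma ave cor
NULL

# set the RNG state if a seed is supplied, otherwise leave it alone
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("`seed` must be a single finite number.", class = "mrcost_error_seed")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# closed-form simple regression slope with normal-reference inference
simple_slope <- function(y, x) {
  n <- length(y)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx == 0) {
    return(list(beta = NA_real_, se = NA_real_, pval = NA_real_, n = n))
  }
  beta <- sum(xc * yc) / sxx
  rss <- sum((yc - beta * xc)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  z <- if (se > 0) beta / se else Inf * sign(beta)
  list(beta = beta, se = se, pval = 2 * pnorm(-abs(z)), n = n)
}

# weighted least squares with variance treated as known (meta-regression style):
# se from (X'WX)^-1 only, no residual-variance rescaling
wls_known_var <- function(X, y, w) {
  Xw <- X * sqrt(w)
  yw <- y * sqrt(w)
  XtX <- crossprod(Xw)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    abort("design matrix is rank deficient.", class = "mrcost_error_rank")
  }
  V <- solve(XtX)
  beta <- drop(V %*% crossprod(Xw, yw))
  fitted <- drop(X %*% beta)
  rss <- sum(w * (y - fitted)^2)
  list(beta = beta, se = sqrt(diag(V)), vcov = V, rss = rss, fitted = fitted)
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))
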