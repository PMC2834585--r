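#' Gaussian GEE with exchangeable working correlation
#'
#' Marginal linear model for repeated measures, fit by generalized estimating
#' equations with the identity link: coefficients solve the estimating
#' equation under a working intra-cluster correlation (exchangeable by
#' default), the correlation and dispersion are re-estimated from Pearson
#' residuals by the method of moments, and inference uses the robust
#' (sandwich) variance, so standard errors are valid even when the working
#' correlation is wrong. With `corstr = "independence"` the coefficients
#' coincide with the ordinary least-squares fit.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param id Cluster (patient) identifier: a bare column name.
#' @param corstr Working correlation: `"exchangeable"` or `"independence"`.
#' @param sandwich Robust-variance flavour: `"md"` (default) applies the
#'   Mancl-DeRouen small-sample bias correction, inflating each cluster's
#'   residual by the inverse of its leverage complement — the classic
#'   sandwich (`"classic"`) is biased downward when an exposure varies in
#'   only a modest number of clusters, as a rare treatment-gap flag does.
#' @param maxit,tol Iteration control.
#' @return A `gee_gauss` object with `coefficients`, robust and model-based
#'   covariance (`vcov_robust`, `vcov_naive`), the working correlation
#'   estimate `rho`, dispersion `phi`, and bookkeeping; supports [coef()],
#'   [vcov()], [tidy()], [glance()].
#' @export
gee_gauss <- function(formula, data, id, corstr = c("exchangeable",
                                                    "independence"),
                      sandwich = c("md", "classic"),
                      maxit = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  sandwich <- match.arg(sandwich)
  id_q <- rlang::enquo(id)
  cluster <- rlang::eval_tidy(id_q, data)
  if (is.null(cluster)) abort("`id` must name a column of `data`")

  mf <- model.frame(formula, data = data, na.action = na.omit)
  dropped <- attr(mf, "na.action")
  if (!is.null(dropped)) cluster <- cluster[-dropped]
  y <- stats::model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  p <- ncol(X)
  N <- nrow(X)
  if (qr(X)$rank < p) abort("design matrix is rank-deficient")

  cluster <- factor(cluster)
  nobs <- as.integer(table(cluster)[levels(cluster)])
  ncl <- nlevels(cluster)

  # cluster sums via rowsum (X and y ordered arbitrarily; rowsum aligns by id)
  beta <- qr.solve(X, y)
  rho <- 0
  for (it in seq_len(maxit)) {
    r <- as.numeric(y - X %*% beta)
    phi <- sum(r^2) / (N - p)
    if (corstr == "exchangeable") {
      Sr <- rowsum(r, cluster)
      # sum over clusters of all within-cluster residual cross-products
      cross <- (Sr^2 - rowsum(r^2, cluster)) / 2
      denom <- sum(nobs * (nobs - 1)) / 2 - p
      rho_new <- sum(cross) / (phi * max(denom, 1))
      rho_new <- max(min(rho_new, 0.99), 0)
    } else {
      rho_new <- 0
    }
    # exchangeable inverse: V^-1 = (I - c J) / (1 - rho),
    # c = rho / (1 + (n_i - 1) rho)
    cc <- rho_new / (1 + (nobs - 1) * rho_new)
    wc <- sqrt(cc)[as.integer(cluster)]
    SX <- rowsum(X, cluster)
    Sy <- rowsum(y, cluster)
    ccl <- cc
    B <- (crossprod(X) - crossprod(SX * sqrt(ccl), SX * sqrt(ccl))) /
      (1 - rho_new)
    rhs <- (crossprod(X, y) - crossprod(SX * sqrt(ccl), Sy * sqrt(ccl))) /
      (1 - rho_new)
    beta_new <- solve(B, rhs)
    delta <- max(abs(beta_new - beta))
    beta <- as.numeric(beta_new)
    rho <- rho_new
    if (delta < tol) break
  }
  converged <- delta < tol || corstr == "independence"

  r <- as.numeric(y - X %*% beta)
  phi <- sum(r^2) / (N - p)
  cc <- rho / (1 + (nobs - 1) * rho)
  SX <- rowsum(X, cluster)
  Sr <- rowsum(r, cluster)
  B <- (crossprod(X) - crossprod(SX * sqrt(cc), SX * sqrt(cc))) / (1 - rho)
  Binv <- solve(B)
  if (sandwich == "classic") {
    # cluster score contributions g_i = X_i' V_i^-1 r_i
    G <- (rowsum(X * r, cluster) - (cc * Sr[, 1L]) * SX) / (1 - rho)
  } else {
    # Mancl-DeRouen: g_i = X_i' V_i^-1 (I - H_i)^-1 r_i with
    # H_i = X_i B^-1 X_i' V_i^-1 (cluster leverage)
    idx <- split(seq_len(N), cluster)
    G <- matrix(0, ncl, ncol(X))
    for (k in seq_len(ncl)) {
      sel <- idx[[k]]
      ni <- length(sel)
      Xi <- X[sel, , drop = FALSE]
      Vinv <- (diag(ni) - matrix(cc[k], ni, ni)) / (1 - rho)
      XV <- crossprod(Xi, Vinv)
      Hi <- Xi %*% Binv %*% XV
      ei <- solve(diag(ni) - Hi, r[sel])
      G[k, ] <- XV %*% ei
    }
  }
  vcov_robust <- Binv %*% crossprod(G) %*% Binv
  vcov_naive <- phi * Binv
  dimnames(vcov_robust) <- dimnames(vcov_naive) <- list(colnames(X), colnames(X))

  # Satterthwaite-style effective degrees of freedom per coefficient: the
  # robust variance of beta_l is a sum of per-cluster contributions w_li;
  # df_l = (sum w)^2 / sum w^2 shrinks toward the number of clusters that
  # actually carry information about that coefficient (few, for a rare
  # binary exposure), so Wald intervals use t rather than normal quantiles
  infl <- G %*% Binv
  w <- infl^2
  df_satt <- colSums(w)^2 / colSums(w^2)
  df_satt <- pmax(pmin(df_satt, ncl - p), 2)
  names(df_satt) <- colnames(X)

  structure(
    list(
      coefficients = setNames(beta, colnames(X)),
      vcov_robust = vcov_robust,
      vcov_naive = vcov_naive,
      rho = rho, phi = phi, df = df_satt,
      n_clusters = ncl, n_obs = N,
      iterations = it, converged = converged,
      corstr = corstr, sandwich = sandwich,
      terms = attr(mf, "terms"),
      xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
      model = mf,
      call = match.call()
    ),
    class = "gee_gauss"
  )
}

#' @export
coef.gee_gauss <- function(object, ...) object$coefficients

#' @export
vcov.gee_gauss <- function(object, robust = TRUE, ...) {
  if (robust) object$vcov_robust else object$vcov_naive
}

#' @export
print.gee_gauss <- function(x, ...) {
  cat("Gaussian GEE (", x$corstr, " working correlation)\n", sep = "")
  cat("  clusters:", x$n_clusters, " observations:", x$n_obs,
      " rho:", round(x$rho, 3), " phi:", round(x$phi, 3), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname gee_gauss
#' @param x,object A `gee_gauss` fit.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @method tidy gee_gauss
#' @export
tidy.gee_gauss <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov_robust))
  est <- x$coefficients
  df <- x$df %||% rep(Inf, length(est))
  tq <- stats::qt(1 - (1 - conf.level) / 2, df)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    df = unname(df),
    p.value = unname(2 * stats::pt(-abs(est / se), df)),
    conf.low = unname(est - tq * se),
    conf.high = unname(est + tq * se)
  )
}

#' @rdname gee_gauss
#' @method glance gee_gauss
#' @export
glance.gee_gauss <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters, n_obs = x$n_obs, rho = x$rho, phi = x$phi,
    iterations = x$iterations, converged = x$converged, corstr = x$corstr
  )
}
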