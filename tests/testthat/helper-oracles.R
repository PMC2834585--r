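# Independent brute-force oracles. These deliberately share no code with the
# package internals: coverage is simulated day by day from a supply pool, and
# Kendall's tau-b is computed by exhaustive pair counting.

# day-by-day supply-pool simulation over window [0, t)
naive_coverage <- function(disp_day, supply, t) {
  pool <- 0
  covered <- logical(t)
  for (day in seq_len(t) - 1L) {
    pool <- pool + sum(supply[disp_day == day])
    if (pool > 0) {
      covered[day + 1L] <- TRUE
      pool <- pool - 1
    }
  }
  runs <- rle(covered)
  gaps <- runs$lengths[!runs$values]
  list(
    pct = 100 * sum(covered) / t,
    longest_gap = if (length(gaps)) max(gaps) else 0L
  )
}

# direct re-computation of exhaustion-timeliness: visit i (i >= 2) is timely
# iff it is on/before previous visit day + supply dispensed that day; pairs
# whose previous visit has no dispensing are skipped
naive_exhaustion <- function(visit_day, disp_day, supply) {
  visit_day <- sort(visit_day)
  num <- den <- 0L
  for (i in seq_along(visit_day)[-1]) {
    prev <- visit_day[i - 1L]
    s <- supply[disp_day == prev]
    if (!length(s)) next
    s <- min(s)
    den <- den + 1L
    if (visit_day[i] <= prev + s) num <- num + 1L
  }
  if (den == 0L) NA_real_ else 100 * num / den
}

# tau-b by exhaustive concordant/discordant pair counting with tie correction
brute_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) {
        tx <- tx + 1; ty <- ty + 1
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (dx * dy > 0) {
        C <- C + 1
      } else {
        D <- D + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# naive GEE for the identity-link Gaussian model with exchangeable working
# correlation: explicit per-cluster matrix algebra (dense V_i, solve())
naive_gee <- function(X, y, cluster, maxit = 50, tol = 1e-10) {
  ids <- unique(cluster)
  p <- ncol(X)
  beta <- solve(crossprod(X), crossprod(X, y))
  rho <- 0
  for (iter in seq_len(maxit)) {
    r <- as.numeric(y - X %*% beta)
    phi <- sum(r^2) / (length(y) - p)
    num <- 0; cnt <- 0
    for (id in ids) {
      ri <- r[cluster == id]
      ni <- length(ri)
      if (ni > 1) {
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        cnt <- cnt + ni * (ni - 1) / 2
      }
    }
    rho_new <- max(min(num / (phi * max(cnt - p, 1)), 0.99), 0)
    A <- matrix(0, p, p); b <- rep(0, p)
    for (id in ids) {
      sel <- cluster == id
      Xi <- X[sel, , drop = FALSE]
      ni <- sum(sel)
      Vi <- (diag(ni) * (1 - rho_new) + rho_new)
      Vinv <- solve(Vi)
      A <- A + t(Xi) %*% Vinv %*% Xi
      b <- b + t(Xi) %*% Vinv %*% y[sel]
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; rho <- rho_new; break
    }
    beta <- beta_new; rho <- rho_new
  }
  r <- as.numeric(y - X %*% beta)
  A <- matrix(0, p, p); M <- matrix(0, p, p)
  for (id in ids) {
    sel <- cluster == id
    Xi <- X[sel, , drop = FALSE]
    ni <- sum(sel)
    Vinv <- solve(diag(ni) * (1 - rho) + rho)
    A <- A + t(Xi) %*% Vinv %*% Xi
    gi <- t(Xi) %*% Vinv %*% r[sel]
    M <- M + gi %*% t(gi)
  }
  Ainv <- solve(A)
  list(beta = as.numeric(beta), rho = rho,
       vcov_robust = Ainv %*% M %*% Ainv)
}

# random dispensing/visit histories for the oracle-equivalence checks
random_history <- function() {
  n_disp <- sample(0:8, 1)
  disp_day <- sort(sample(0:120, n_disp))
  supply <- sample(c(7, 14, 30, 60), max(n_disp, 1), replace = TRUE)[seq_len(n_disp)]
  n_vis <- sample(2:8, 1)
  visit_day <- sort(sample(0:150, n_vis))
  t <- sample(60:180, 1)
  list(disp_day = disp_day, supply = supply, visit_day = visit_day, t = t)
}
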