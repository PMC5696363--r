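# Independent oracles, re-derived from the model definitions (not calls into
# the package's own code paths).

# log upper tail of Gamma(1/2, 1) via the incomplete gamma function
o_logQ <- function(k) pgamma(k, 0.5, 1, lower.tail = FALSE, log.p = TRUE)

# dense posterior through the S x S information matrix (the route the
# package never takes)
o_dense_posterior <- function(K, v, lam, beta) {
  S <- ncol(K)
  supp <- lam > 0
  Ks <- K[, supp, drop = FALSE]
  Sig <- solve(crossprod(Ks) / beta + diag(1 / lam[supp],
                                           nrow = sum(supp)))
  mu_s <- Sig %*% crossprod(Ks, v) / beta
  mu <- numeric(S); mu[supp] <- mu_s
  sd_full <- numeric(S); sd_full[supp] <- diag(Sig)
  list(mu = mu, sigma_diag = sd_full,
       sigma_logdet = determinant(Sig)$modulus[1],
       residual = as.numeric(v - K %*% mu))
}

# term-by-term re-evaluation of the Type-II objective from scratch
o_type2 <- function(K, V, lam_mat, beta, neglogprior) {
  total <- 0
  for (t in seq_len(ncol(V))) {
    p <- o_dense_posterior(K, V[, t], lam_mat[, t], beta[t])
    supp <- lam_mat[, t] > 0
    total <- total + 0.5 * (
      nrow(K) * log(beta[t]) + sum(p$residual^2) / beta[t] +
        sum(log(lam_mat[supp, t])) +
        sum(p$mu[supp]^2 / lam_mat[supp, t]) - p$sigma_logdet)
  }
  total + neglogprior
}

# ---- coordinate objectives (restrictions of the EM surrogate) ---------------

o_gamma_obj <- function(gam, m, alpha1, k) {
  lb <- 1 - k / gam
  ifelse(lb <= 0, Inf,
         0.5 * (log(lb) - log(2 * alpha1)) + alpha1 * m / lb +
           0.5 * log(gam) + gam)
}

o_alpha1_obj <- function(a1, m_supp, lb_supp) {
  -length(m_supp) / 2 * log(2 * a1) + a1 * sum(m_supp / lb_supp)
}

o_beta_obj <- function(beta, expected_rss, N) {
  0.5 * (N * log(beta) + expected_rss / beta)
}

o_k_obj <- function(k, gamma, lam_bar, m, alpha1, tau, ups, S) {
  supp <- lam_bar > 0
  lb <- 1 - k / gamma[supp]
  if (any(lb <= 0) || k <= 0) return(Inf)
  gr <- pmax(gamma[!supp], k)
  sum(0.5 * (log(lb) - log(2 * alpha1)) + alpha1 * m[supp] / lb +
        0.5 * log(gamma[supp]) + gamma[supp]) +
    S * o_logQ(k) + sum(0.5 * log(gr) + gr) -
    tau * log(max(k, 1e-12)) + ups * k
}

o_k_prof <- function(k, m_supp, gamma_pruned, alpha1, tau, ups, S) {
  if (k <= 0) return(Inf)
  # per-coordinate gamma at its conditional argmin: u^2 + u/2 = c k
  cc <- alpha1 * m_supp
  u <- (-1 + sqrt(1 + 16 * cc * k)) / 4
  u <- ifelse(u > 0, u, 4 * cc * k / 2)  # series fallback for tiny ck
  gam <- k + u
  lb <- u / gam
  gr <- pmax(gamma_pruned, k)
  sum(0.5 * (log(lb) - log(2 * alpha1)) + alpha1 * m_supp / lb +
        0.5 * log(gam) + gam) +
    S * o_logQ(k) + sum(0.5 * log(gr) + gr) -
    tau * log(max(k, 1e-12)) + ups * k
}

o_elasso_alpha_obj <- function(alpha, delta, gamma, lam_bar, m_mat, S) {
  if (alpha <= 0) return(Inf)
  tot <- 0
  for (t in seq_len(ncol(m_mat))) {
    d <- delta[, t]; g <- gamma[, t]
    supp <- lam_bar[, t] > 0
    k <- alpha * d^2
    lb <- ifelse(d == 0, 1, 1 - k / g)
    if (any(lb[supp] <= 0)) return(Inf)
    ride <- !supp & d > 0
    gr <- pmax(g[ride], k[ride])
    wnorm <- sum(abs(sum(d) / (length(d) - 1) - d))
    tot <- tot + sum(0.5 * (log(lb[supp]) - log(2 * alpha)) +
                       alpha * m_mat[supp, t] / lb[supp] +
                       0.5 * log(g[supp]) + g[supp]) +
      sum(o_logQ(k[d > 0])) + sum(0.5 * log(gr) + gr) +
      alpha * wnorm^2
  }
  tot
}

# ---- metrics oracles --------------------------------------------------------

# Mann-Whitney AUC by explicit pair counting
o_auc <- function(truth, est) {
  pos <- abs(est[truth != 0]); neg <- abs(est[truth == 0])
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  100 * wins / (length(pos) * length(neg))
}

# textbook dense tableau simplex for min c'x, Ax = b, x >= 0 (Big-M); only
# for tiny instances
o_simplex_lp <- function(cvec, A, b) {
  m <- nrow(A); n <- ncol(A)
  bigM <- 1e7 * (max(abs(cvec)) + 1)
  Tab <- cbind(A, diag(m), b)
  cost <- c(cvec, rep(bigM, m), 0)
  basis <- n + seq_len(m)
  for (iter in 1:10000) {
    red <- cost[seq_len(n + m)] -
      as.numeric(cost[basis] %*% Tab[, seq_len(n + m), drop = FALSE])
    piv <- which.min(red)
    if (red[piv] >= -1e-9 * bigM * 1e-6) break
    col <- Tab[, piv]
    ratios <- ifelse(col > 1e-12, Tab[, n + m + 1] / col, Inf)
    if (all(!is.finite(ratios))) stop("unbounded LP")
    r <- which.min(ratios)
    Tab[r, ] <- Tab[r, ] / Tab[r, piv]
    for (rr in seq_len(m)) if (rr != r)
      Tab[rr, ] <- Tab[rr, ] - Tab[rr, piv] * Tab[r, ]
    basis[r] <- piv
  }
  x <- numeric(n + m)
  x[basis] <- Tab[, n + m + 1]
  list(objective = sum(cost[seq_len(n + m)] * x), x = x[seq_len(n)])
}

# exact transportation cost by dense LP (equality constraints, one dropped
# row for rank)
o_emd_lp <- function(a, b, C) {
  m <- length(a); n <- length(b)
  A <- matrix(0, m + n - 1, m * n)
  for (i in seq_len(m)) A[i, (seq_len(n) - 1) * m + i] <- 1
  for (j in seq_len(n - 1)) A[m + j, (j - 1) * m + seq_len(m)] <- 1
  o_simplex_lp(as.numeric(C), A, c(a, b[-n]))$objective
}

# 1-D closed form: EMD on collinear points equals the integrated |CDF gap|
o_emd_1d <- function(x, a, b) {
  ord <- order(x)
  x <- x[ord]; a <- a[ord]; b <- b[ord]
  cum <- cumsum(a / sum(a) - b / sum(b))
  sum(abs(cum[-length(cum)]) * diff(x))
}

# LP duality certificate: flow feasibility + complementary slackness +
# matching primal/dual objectives prove optimality
o_check_transport_optimal <- function(res, a, b, C, tol = 1e-7) {
  ok_feas <- max(abs(rowSums(res$flow) - a)) < tol &&
    max(abs(colSums(res$flow) - b)) < tol && all(res$flow > -tol)
  red <- C - outer(res$u, res$v, `+`)
  ok_dual <- min(red) > -tol
  ok_cs <- max(abs(res$flow * red)) < tol * 10
  ok_obj <- abs(sum(res$u * a) + sum(res$v * b) - res$cost) <
    tol * (1 + abs(res$cost))
  ok_feas && ok_dual && ok_cs && ok_obj
}
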