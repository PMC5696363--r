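test_that("elasso_effective_variance follows its definition", {
  # delta = 0: uncoupled ridge coordinate
  pv <- elasso_effective_variance(c(0.5, 3), delta = c(0, 0), alpha = 2)
  expect_equal(pv$lam_bar, c(1, 1))
  expect_equal(pv$lam, c(0.25, 0.25))
  # direct substitution: alpha = 1, delta = 2, gamma = 8
  pv2 <- elasso_effective_variance(8, 2, 1)
  expect_equal(pv2$lam_bar, 0.5)
  expect_equal(pv2$lam, 0.25)
  # truncation-limit pruning
  pv3 <- elasso_effective_variance(4 * (1 + 1e-12), 2, 1)
  expect_identical(pv3$lam, 0)
  expect_error(elasso_effective_variance(3, 2, 1), "support")
})

test_that("update_delta equals the literal leave-one-out sum", {
  expect_equal(update_delta(cbind(c(1, -2, 3)))[, 1], c(5, 4, 3))
  expect_equal(update_delta(matrix(0, 4, 2)), matrix(0, 4, 2))
  set.seed(10)
  mu <- matrix(rnorm(50 * 7), 50, 7)
  d <- update_delta(mu)
  for (t in c(1, 4, 7)) for (i in c(1, 25, 50))
    expect_equal(d[i, t], sum(abs(mu[-i, t])), tolerance = 1e-12)
})

test_that("winv_apply is the closed-form inverse of the coupling matrix", {
  # round trip through W = ones - I
  j <- c(1, 2, 3)
  delta <- sum(j) - j          # W |j|
  expect_equal(winv_apply(delta), j, tolerance = 1e-12)
  # S = 2: W^-1 = W
  expect_equal(winv_apply(c(3, 5)), c(5, 3))
  # dense-solve oracle
  set.seed(12)
  S <- 9
  W <- matrix(1, S, S) - diag(S)
  x <- rexp(S)
  expect_equal(winv_apply(x), as.numeric(solve(W, x)), tolerance = 1e-12)
  expect_error(winv_apply(1), "singular")
})

test_that("alpha coordinate objective matches independent re-evaluation", {
  for (seed in 1:2) {
    inst <- rand_elasso_state(seed)
    st <- inst$state
    m_mat <- vapply(inst$posts, function(p) p$mu^2 + p$sigma_diag,
                    numeric(inst$S))
    for (a in c(st$alpha * 0.7, st$alpha * 0.99)) {
      mine <- ssbleeg:::elasso_alpha_objective(a, st, m_mat, inst$S)
      # oracle includes identical terms up to an alpha-independent constant;
      # compare differences between two evaluation points
      mine2 <- ssbleeg:::elasso_alpha_objective(a * 0.9, st, m_mat, inst$S)
      orac <- o_elasso_alpha_obj(a, st$delta, st$gamma, st$lam_bar, m_mat,
                                 inst$S)
      orac2 <- o_elasso_alpha_obj(a * 0.9, st$delta, st$gamma, st$lam_bar,
                                  m_mat, inst$S)
      expect_equal(mine - mine2, orac - orac2, tolerance = 1e-10)
    }
  }
})

test_that("swept gamma and alpha beat the grid oracle on their objectives", {
  cfg <- elasso_config()
  for (seed in 1:2) {
    inst <- rand_elasso_state(seed)
    st <- inst$state
    m_mat <- matrix(vapply(inst$posts, function(p) p$mu^2 + p$sigma_diag,
                           numeric(inst$S)), inst$S, inst$T_)
    # gamma closed form per coordinate (same form as the enet update with
    # per-coordinate truncation alpha delta^2)
    t <- 1L
    k <- st$alpha * st$delta[, t]^2
    for (i in sample(inst$S, 3)) {
      gnew <- ssbleeg:::enet_update_gamma_one(m_mat[i, t], st$alpha, k[i])
      grid <- k[i] * (1 + exp(seq(log(1e-6), log(1e3), length.out = 1000)))
      fg <- o_gamma_obj(grid, m_mat[i, t], st$alpha, k[i])
      expect_lte(o_gamma_obj(gnew, m_mat[i, t], st$alpha, k[i]),
                 min(fg) + 1e-8)
    }
    # one full sweep: the updated alpha must be at least as good as a
    # 1000-point grid search of the fixed-gamma objective evaluated at the
    # swept delta/gamma state
    st2 <- elasso_update_hyperparameters(st, inst$posts, inst$V, inst$K,
                                         cfg)
    hard <- st2$lam_bar > 0 & st2$delta > 0
    hi <- min(st2$gamma[hard] / st2$delta[hard]^2)
    grid_a <- exp(seq(log(hi * 1e-5), log(hi * (1 - 1e-9)),
                      length.out = 1000))
    fa <- vapply(grid_a, o_elasso_alpha_obj, numeric(1), delta = st2$delta,
                 gamma = st2$gamma, lam_bar = st2$lam_bar, m_mat = m_mat,
                 S = inst$S)
    f_upd <- o_elasso_alpha_obj(st2$alpha, st2$delta, st2$gamma,
                                st2$lam_bar, m_mat, inst$S)
    expect_lte(f_upd, min(fa) + 1e-6 * (1 + abs(min(fa))))
  }
})

test_that("with mu = 0 the delta update returns 0 (ridge reduction)", {
  set.seed(3)
  N <- 5; S <- 8
  K <- matrix(rnorm(N * S), N, S)
  st <- list(gamma = matrix(0.5, S, 1), delta = matrix(1, S, 1),
             lam_bar = matrix(1, S, 1), alpha = 2, beta = 1)
  p <- gaussian_posterior(K, rep(0, N), rep(0.25, S), 1)
  expect_equal(max(abs(p$mu)), 0)
  st2 <- elasso_update_hyperparameters(st, list(p), matrix(0, N, 1), K,
                                       elasso_config())
  expect_equal(max(st2$delta), 0)
  expect_true(all(st2$lam_bar[, 1] %in% c(0, 1)))
})

test_that("elasso_fit recovers identity-operator support with exclusivity", {
  V <- matrix(0, 6, 2)
  V[2, 1] <- 3; V[5, 2] <- 2
  f <- elasso_fit(V, diag(6), elasso_config(max_iter = 20))
  J <- f$estimate$J
  expect_equal(which.max(abs(J[, 1])), 2L)
  expect_equal(which.max(abs(J[, 2])), 5L)
  # elitist behavior: nearly all of each column's L1 mass on the truth
  expect_gte(abs(J[2, 1]) / sum(abs(J[, 1])), 0.95)
  expect_gte(abs(J[5, 2]) / sum(abs(J[, 2])), 0.95)
})

test_that("elasso_fit on zero data returns zero", {
  f <- elasso_fit(matrix(0, 4, 2), matrix(rnorm(28), 4, 7),
                  elasso_config(max_iter = 8))
  expect_equal(max(abs(f$estimate$J)), 0)
})

test_that("objective is non-increasing across sweeps (property)", {
  for (seed in 1:4) {
    inst <- rand_instance(seed + 20, N = 7, S = 16, T_ = 4, snr_db = 8)
    f <- elasso_fit(inst$V, inst$K, elasso_config(max_iter = 25))
    ot <- f$objective_trajectory
    fin <- ot[is.finite(ot)]
    expect_true(all(diff(fin) <= 1e-8 * pmax(1, abs(fin[-length(fin)]))))
  }
})

test_that("marginal-prior consistency holds for S = 2 (Lemma-style check)", {
  # direct marginal of J1 under (1/z) exp(-alpha ||J||_1^2) vs the
  # hierarchical route integral p(J1 | delta1) p(delta1, delta2) d delta
  alpha <- 1.3
  direct_un <- function(j1) vapply(j1, function(a)
    integrate(function(j2) exp(-alpha * (abs(a) + abs(j2))^2),
              -Inf, Inf, rel.tol = 1e-10)$value, numeric(1))
  z <- integrate(direct_un, -Inf, Inf, rel.tol = 1e-8)$value
  # hierarchical: p(delta) on R+^2 proportional to exp(-alpha (d1 + d2)^2)
  # (for S = 2, W^-1 delta = (d2, d1)); p(J1 | d1) Laplace/Normal
  zbar <- integrate(function(d1) vapply(d1, function(a)
    integrate(function(d2) exp(-alpha * (a + d2)^2), 0, Inf,
              rel.tol = 1e-10)$value, numeric(1)), 0, Inf,
    rel.tol = 1e-8)$value
  cond <- function(j1, d1) {
    zc <- integrate(function(x) exp(-alpha * x^2 - 2 * alpha * d1 * abs(x)),
                    -Inf, Inf, rel.tol = 1e-10)$value
    exp(-alpha * j1^2 - 2 * alpha * d1 * abs(j1)) / zc
  }
  hier <- function(j1) {
    integrate(function(d1) vapply(d1, function(a) {
      pd1 <- integrate(function(d2) exp(-alpha * (a + d2)^2), 0, Inf,
                       rel.tol = 1e-10)$value / zbar
      cond(j1, a) * pd1
    }, numeric(1)), 0, Inf, rel.tol = 1e-8)$value
  }
  for (j1 in c(0.2, 0.8, 1.5)) {
    expect_equal(hier(j1), direct_un(j1) / z, tolerance = 1e-4)
  }
})

test_that("converged alpha is reported in the result", {
  inst <- rand_instance(31, N = 6, S = 10, T_ = 3)
  f <- elasso_fit(inst$V, inst$K, elasso_config(max_iter = 10))
  expect_true(is.finite(f$hyper$alpha) && f$hyper$alpha > 0)
})
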