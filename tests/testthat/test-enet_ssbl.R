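test_that("enet_effective_variance implements truncation, clip and pruning", {
  # k = 0: pure ridge variance 1/(2 alpha1)
  pv <- enet_effective_variance(c(0.2, 5), alpha1 = 1, k = 0)
  expect_equal(pv$lam_bar, c(1, 1))
  expect_equal(pv$lam, c(0.5, 0.5))

  # alpha1 = 1, alpha2 = 2 -> k = alpha2^2/(4 alpha1) = 1; gamma = 2
  pv2 <- enet_effective_variance(2, alpha1 = 1, k = 1)
  expect_equal(pv2$lam_bar, 0.5)
  expect_equal(pv2$lam, 0.25)

  # truncation-limit sparsity: gamma -> k+ collapses to exact zero
  pv3 <- enet_effective_variance(1 * (1 + 1e-12), alpha1 = 2, k = 1)
  expect_identical(pv3$lam_bar, 0)
  expect_identical(pv3$lam, 0)

  # clip floor binds between floor/2 and floor
  pv4 <- enet_effective_variance(1 / (1 - 8e-7), 1, 1, lam_bar_floor = 1e-6)
  expect_equal(pv4$lam_bar, 1e-6)
  expect_error(enet_effective_variance(c(2, 0.5), 1, 1), "support")
})

test_that("enet_mixture_marginal reproduces the Laplace/Normal density", {
  # k = 0 collapses to the centred Gaussian
  for (a1 in c(0.5, 2)) {
    j <- c(0, 0.4, 1.3)
    expect_equal(enet_mixture_marginal(j, a1, 0),
                 dnorm(j, 0, sqrt(1 / (2 * a1))), tolerance = 1e-8)
  }
  # (a1, a2) = (1, 1) => k = 0.25: direct normalization oracle
  a1 <- 1; a2 <- 1; k <- a2^2 / (4 * a1)
  z <- integrate(function(x) exp(-a1 * x^2 - a2 * abs(x)), -Inf, Inf,
                 rel.tol = 1e-12)$value
  for (j in c(0, 0.5, 1, 2)) {
    expect_equal(enet_mixture_marginal(j, a1, k),
                 exp(-a1 * j^2 - a2 * abs(j)) / z, tolerance = 1e-6)
  }
  # symmetry
  expect_equal(enet_mixture_marginal(0.7, 2, 0.3),
               enet_mixture_marginal(-0.7, 2, 0.3), tolerance = 1e-12)
})

test_that("gamma and alpha1 updates are coordinate argmins (grid oracle)", {
  for (seed in 1:3) {
    inst <- rand_enet_state(seed)
    st <- inst$state
    for (t in 1:2) {
      m <- inst$posts[[t]]$mu^2 + inst$posts[[t]]$sigma_diag
      k <- st$k[t]; a1 <- st$alpha1[t]
      # gamma: closed form vs 1000-point grid per coordinate
      for (i in sample(inst$S, 3)) {
        gnew <- ssbleeg:::enet_update_gamma_one(m[i], a1, k)
        grid <- k * (1 + exp(seq(log(1e-6), log(1e3), length.out = 1000)))
        fg <- o_gamma_obj(grid, m[i], a1, k)
        expect_lte(o_gamma_obj(gnew, m[i], a1, k), min(fg) + 1e-8)
      }
      # alpha1: closed form vs grid
      lb <- st$lam_bar[, t]
      supp <- lb > 0
      a1_new <- sum(supp) / (2 * sum(m[supp] / lb[supp]))
      grid_a <- a1_new * exp(seq(log(1e-4), log(1e4), length.out = 1000))
      fa <- vapply(grid_a, o_alpha1_obj, numeric(1), m_supp = m[supp],
                   lb_supp = lb[supp])
      expect_lte(o_alpha1_obj(a1_new, m[supp], lb[supp]), min(fa) + 1e-10)
    }
  }
})

test_that("k update matches the fixed-gamma grid oracle", {
  cfg <- enet_config()
  for (seed in 1:3) {
    inst <- rand_enet_state(seed)
    st <- inst$state
    t <- 1L
    m <- inst$posts[[t]]$mu^2 + inst$posts[[t]]$sigma_diag
    knew <- ssbleeg:::enet_update_k(st$gamma[, t], st$lam_bar[, t], m,
                                    st$alpha1[t], st$k[t], cfg$tau,
                                    cfg$upsilon, inst$S)
    hi <- min(st$gamma[, t][st$lam_bar[, t] > 0]) * (1 - 1e-9)
    grid <- exp(seq(log(1e-8), log(hi), length.out = 1000))
    fk <- vapply(grid, o_k_obj, numeric(1), gamma = st$gamma[, t],
                 lam_bar = st$lam_bar[, t], m = m, alpha1 = st$alpha1[t],
                 tau = cfg$tau, ups = cfg$upsilon, S = inst$S)
    expect_lte(o_k_obj(knew, st$gamma[, t], st$lam_bar[, t], m,
                       st$alpha1[t], cfg$tau, cfg$upsilon, inst$S),
               min(fk) + 1e-6 * (1 + abs(min(fk))))
  }
})

test_that("profiled k objective matches an independent re-derivation", {
  set.seed(3)
  m <- rexp(8); gp <- rexp(3)
  for (k in c(0.05, 0.4, 2)) {
    a <- ssbleeg:::enet_k_profiled(k, m, gp, 1.4, 1e-3, 1e-3, 11)
    b <- o_k_prof(k, m, gp, 1.4, 1e-3, 1e-3, 11)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("beta update is the expected residual power", {
  # with mu = 0 and Sigma = 0 held fixed, beta update = ||v||^2 / N
  set.seed(2)
  N <- 6; S <- 9
  K <- matrix(rnorm(N * S), N, S)
  v <- rnorm(N)
  st <- list(gamma = matrix(1, S, 1), lam_bar = matrix(0, S, 1),
             k = 0.2, alpha1 = 1, beta = 1)
  p <- gaussian_posterior(K, v, rep(0, S), 1)   # mu = 0, Sigma = 0
  st2 <- enet_update_hyperparameters(st, list(p), matrix(v), K,
                                     enet_config())
  expect_equal(st2$beta, sum(v^2) / N)
  # grid check of the coordinate objective
  grid <- st2$beta * exp(seq(log(1e-3), log(1e3), length.out = 1000))
  fb <- vapply(grid, o_beta_obj, numeric(1), expected_rss = sum(v^2), N = N)
  expect_lte(o_beta_obj(st2$beta, sum(v^2), N), min(fb) + 1e-10)
})

test_that("enet_fit recovers an identity-operator source exactly", {
  v <- c(0, 0, 3, 0, 0)
  f <- enet_fit(matrix(v), diag(5), enet_config(max_iter = 20))
  J <- f$estimate$J[, 1]
  expect_equal(which.max(abs(J)), 3L)
  expect_true(all(abs(J[-3]) <= 1e-3 * abs(J[3])))
})

test_that("enet_fit on zero data returns zero with a positive truncation", {
  f <- enet_fit(matrix(0, 4, 2), matrix(rnorm(20), 4, 5),
                enet_config(max_iter = 10))
  expect_equal(max(abs(f$estimate$J)), 0)
  expect_true(all(f$hyper$k > 0))   # sparsity-promoting limit grew from 0
})

test_that("objective is non-increasing across sweeps (property)", {
  for (seed in 1:4) {
    inst <- rand_instance(seed, N = 7, S = 16, T_ = 4, snr_db = 8)
    f <- enet_fit(inst$V, inst$K, enet_config(max_iter = 25))
    ot <- f$objective_trajectory
    fin <- ot[is.finite(ot)]
    expect_true(all(diff(fin) <= 1e-8 * pmax(1, abs(fin[-length(fin)]))))
    expect_lte(f$n_iter, 25)
  }
})

test_that("ridge limit: k frozen at zero reproduces the ridge closed form", {
  for (seed in 1:2) {
    inst <- rand_instance(seed, N = 6, S = 12, T_ = 2)
    f <- enet_fit(inst$V, inst$K,
                  enet_config(fix_k_zero = TRUE, max_iter = 40))
    a1 <- f$hyper$alpha1; be <- f$hyper$beta
    for (t in 1:2) {
      ridge <- solve(crossprod(inst$K) + diag(2 * a1[t] * be[t], inst$S),
                     crossprod(inst$K, inst$V[, t]))
      expect_equal(f$estimate$J[, t], as.numeric(ridge), tolerance = 1e-8)
    }
  }
})

test_that("sparsity is monotone in the truncation limit (frozen sweep)", {
  set.seed(6)
  # gammas log-clustered just above the largest k so the 1% threshold is
  # actually crossed as k grows
  gam <- 0.2 * (1 + exp(runif(30, log(1e-4), log(5))))
  n_small <- vapply(c(0.01, 0.05, 0.1, 0.2), function(k) {
    pv <- enet_effective_variance(gam, 1.5, k)
    sum(pv$lam_bar < 0.01)
  }, numeric(1))
  expect_true(all(diff(n_small) >= 0))
  expect_gt(n_small[4], n_small[1])
})

test_that("dimension mismatches are rejected", {
  expect_error(enet_fit(matrix(0, 3, 1), matrix(0, 4, 5)), "differ")
})
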