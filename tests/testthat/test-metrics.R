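make_line_space <- function(n) {
  pos <- cbind(seq(0, 100, length.out = n), 0, 0)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- TRUE
  list(positions = pos, adjacency = A)
}

test_that("emd matches trivial transports and is a metric on random triples", {
  pos <- matrix(rnorm(90), 30, 3) * 20
  x <- runif(30)
  # the anti-degeneracy perturbation leaves a sub-1e-5 mm residual
  expect_lt(emd(x, x, pos), 1e-5)

  # unit point masses 40 mm apart
  pos2 <- rbind(c(0, 0, 0), c(40, 0, 0))
  a <- c(1, 0); b <- c(0, 1)
  expect_equal(emd(a, b, pos2), 40, tolerance = 1e-9)

  expect_error(emd(rep(0, 5), runif(5), matrix(0, 5, 3)), "all-zero")

  # triangle inequality and rescaling invariance
  set.seed(7)
  for (r in 1:4) {
    p <- matrix(rnorm(45), 15, 3) * 30
    x <- rexp(15); y <- rexp(15); z <- rexp(15)
    dxy <- emd(x, y, p); dyz <- emd(y, z, p); dxz <- emd(x, z, p)
    expect_lte(dxz, dxy + dyz + 1e-7)
    expect_equal(emd(3.7 * x, y, p), dxy, tolerance = 1e-8)
  }
})

test_that("emd agrees with the 1-D closed form on collinear points", {
  set.seed(2)
  for (r in 1:5) {
    n <- 12
    sp <- make_line_space(n)
    a <- rexp(n); b <- rexp(n)
    expect_equal(emd(a, b, sp$positions),
                 o_emd_1d(sp$positions[, 1], a, b), tolerance = 1e-8)
  }
})

test_that("emd agrees with an independent dense simplex LP", {
  set.seed(5)
  for (r in 1:3) {
    m <- 5; n <- 6
    posa <- matrix(rnorm(m * 3), m) * 25
    posb <- matrix(rnorm(n * 3), n) * 25
    a <- rexp(m); a <- a / sum(a)
    b <- rexp(n); b <- b / sum(b)
    C <- sqrt(outer(rowSums(posa^2), rowSums(posb^2), `+`) -
                2 * posa %*% t(posb))
    res <- ssbleeg:::transport_simplex(a, b, C)
    expect_equal(res$cost, o_emd_lp(a, b, C), tolerance = 1e-7)
    expect_true(o_check_transport_optimal(res, a, b, C))
  }
})

test_that("transport solutions carry a valid optimality certificate at scale", {
  set.seed(9)
  m <- 40; n <- 55
  posa <- matrix(rnorm(m * 3), m) * 40
  posb <- matrix(rnorm(n * 3), n) * 40
  a <- rexp(m); a <- a / sum(a)
  b <- rexp(n); b <- b / sum(b)
  C <- sqrt(pmax(outer(rowSums(posa^2), rowSums(posb^2), `+`) -
                   2 * posa %*% t(posb), 0))
  res <- ssbleeg:::transport_simplex(a, b, C)
  expect_true(o_check_transport_optimal(res, a, b, C))
})

test_that("dle measures distance from true centers to estimated peaks", {
  n <- 20
  sp <- make_line_space(n)
  est <- numeric(n); est[5] <- 1
  truth <- numeric(n); truth[5] <- 1
  expect_equal(dle(truth, est, sp$positions, sp$adjacency, 5), 0)

  # single peak a known distance from the center
  est2 <- numeric(n); est2[8] <- 1
  gap <- sp$positions[8, 1] - sp$positions[5, 1]
  expect_equal(dle(truth, est2, sp$positions, sp$adjacency, 5), gap)

  # multi-center case against exhaustive nearest-peak search
  set.seed(4)
  est3 <- rexp(n)
  centers <- c(3, 12, 17)
  x <- abs(est3)
  peaks <- which(vapply(seq_len(n), function(i) {
    nb <- which(sp$adjacency[i, ]); all(x[i] >= x[nb])
  }, logical(1)))
  expected <- mean(vapply(centers, function(cc)
    min(abs(sp$positions[cc, 1] - sp$positions[peaks, 1])), numeric(1)))
  expect_equal(dle(truth, est3, sp$positions, sp$adjacency, centers),
               expected)
  expect_error(dle(truth, numeric(n), sp$positions, sp$adjacency, 5),
               "all-zero")
  # rescaling invariance
  expect_equal(dle(truth, 5 * est3, sp$positions, sp$adjacency, centers),
               expected)
})

test_that("roc_auc matches the Mann-Whitney oracle and its identities", {
  set.seed(11)
  truth <- numeric(40); truth[sample.int(40, 12)] <- rnorm(12)
  est <- rnorm(40)
  expect_equal(roc_auc(truth, est), o_auc(truth, est), tolerance = 1e-12)
  expect_equal(roc_auc(truth, abs(truth)), 100)         # perfect scorer
  expect_equal(roc_auc(truth, rep(0.3, 40)), 50)        # uninformative
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "single-class")
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(truth, est), roc_auc(truth, tanh(abs(est)) + 1),
               tolerance = 1e-10)
})

test_that("f1_optimal reproduces hand-computed operating points", {
  truth <- c(rep(1, 10), rep(0, 90))
  est <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 88))
  r <- f1_optimal(truth, est)
  expect_equal(r$recall, 0.8)
  expect_equal(r$precision, 0.8)
  expect_equal(r$f1, 80)
  g <- f1_optimal(truth, est, mean = "geometric")
  expect_equal(g$f1, 80)   # equal P and R: harmonic == geometric

  # perfect reconstruction
  set.seed(2)
  truth2 <- numeric(30); truth2[1:7] <- runif(7, 0.5, 2)
  expect_equal(f1_optimal(truth2, truth2)$f1, 100)
  # disjoint support
  est3 <- numeric(30); est3[8:10] <- 1
  expect_equal(f1_optimal(truth2, est3)$f1, 0)
})

test_that("sparsity and activation curves follow their definitions", {
  J <- cbind(c(1, 1, 0), c(0.5, 0.5, 0), c(2, 1, 1))  # L1: 2, 1, 4
  expect_equal(sparsity_level(J), c(0.5, 0.75, 0))
  expect_equal(activation_level(J), c(2, 1, 4))
  J2 <- cbind(c(1, 0), c(0, 0))
  expect_equal(sparsity_level(J2), c(0, 1))
  expect_error(sparsity_level(matrix(0, 2, 2)), "all-zero")
})

test_that("rank_summaries selects median trials and counts wins", {
  # single method, three trials: middle-ranked trial is typical
  df <- data.frame(method = "a", trial = 1:3, cell = "all",
                   emd = c(10, 20, 30), dle = c(1, 2, 3),
                   auc = c(90, 80, 70), f1 = c(60, 50, 40))
  rs <- rank_summaries(df)
  expect_equal(unname(rs$typical_trial["a"]), 2)

  # two methods with a strong known shift: wins match wilcox.test
  set.seed(8)
  n <- 20
  mk <- function(method, shift) data.frame(
    method = method, trial = seq_len(n), cell = "c1",
    emd = rnorm(n, 100 + shift, 5), dle = rnorm(n, 5 + shift / 50, 0.5),
    auc = rnorm(n, 90 - shift / 10, 1), f1 = rnorm(n, 50 - shift / 5, 2))
  df2 <- rbind(mk("good", 0), mk("bad", 40))
  rs2 <- rank_summaries(df2)
  w <- rs2$win_counts
  gb <- w[w$method_a == "good" & w$method_b == "bad", ]
  expect_true(all(gb$win_pct == 100))
  bg <- w[w$method_a == "bad" & w$method_b == "good", ]
  expect_true(all(bg$win_pct == 0))
  # reference check for one cell/measure
  p_ref <- wilcox.test(df2$emd[df2$method == "good"],
                       df2$emd[df2$method == "bad"], exact = FALSE)$p.value
  expect_lt(p_ref, 0.05)
  expect_error(rank_summaries(df), NA)
  expect_error(rank_summaries(df[df$method == "none", ]))
})
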