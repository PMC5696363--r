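# Shared fixtures: small random inverse-problem instances and an in-session
# cache for the (expensive) desk benchmark shared by the acceptance tests.

rand_instance <- function(seed, N = 6, S = 15, T_ = 3, snr_db = 10) {
  set.seed(seed)
  K <- matrix(rnorm(N * S), N, S)
  K <- sweep(K, 2, sqrt(colSums(K^2)), "/")
  J <- matrix(0, S, T_)
  act <- sample.int(S, 2)
  J[act, ] <- matrix(rnorm(2 * T_, sd = 1), 2, T_)
  sig <- K %*% J
  E <- matrix(rnorm(N * T_), N, T_)
  E <- E * sqrt(sum(sig^2) / 10^(snr_db / 10) / sum(E^2))
  list(K = K, J = J, V = sig + E, active = act, N = N, S = S, T_ = T_)
}

# random hyperparameter state + matching posteriors for update-oracle tests
rand_enet_state <- function(seed, N = 4, S = 10, T_ = 3) {
  set.seed(seed)
  inst <- rand_instance(seed, N, S, T_)
  k <- runif(T_, 0.05, 0.4)
  gamma <- matrix(0, S, T_)
  lam_bar <- matrix(0, S, T_)
  for (t in seq_len(T_)) {
    gamma[, t] <- k[t] + rexp(S, 2)
    lam_bar[, t] <- 1 - k[t] / gamma[, t]
  }
  state <- list(gamma = gamma, lam_bar = lam_bar, k = k,
                alpha1 = runif(T_, 0.5, 5), beta = runif(T_, 0.05, 0.5))
  posts <- lapply(seq_len(T_), function(t)
    gaussian_posterior(inst$K, inst$V[, t],
                       prior_variance(lam_bar[, t] / (2 * state$alpha1[t]),
                                      lam_bar[, t]),
                       state$beta[t]))
  c(inst, list(state = state, posts = posts))
}

rand_elasso_state <- function(seed, N = 4, S = 10, T_ = 3) {
  set.seed(seed)
  inst <- rand_instance(seed, N, S, T_)
  alpha <- runif(1, 0.5, 3)
  delta <- matrix(rexp(S * T_, 2), S, T_)
  k <- alpha * delta^2
  gamma <- k + matrix(rexp(S * T_, 2), S, T_)
  lam_bar <- 1 - k / gamma
  state <- list(gamma = gamma, delta = delta, lam_bar = lam_bar,
                alpha = alpha, beta = runif(T_, 0.05, 0.5))
  posts <- lapply(seq_len(T_), function(t)
    gaussian_posterior(inst$K, inst$V[, t],
                       prior_variance(lam_bar[, t] / (2 * alpha),
                                      lam_bar[, t]),
                       state$beta[t]))
  c(inst, list(state = state, posts = posts))
}

# desk-scale benchmark shared by the acceptance tests (built once per run)
.bench_cache <- new.env(parent = emptyenv())

desk_benchmark <- function() {
  if (!is.null(.bench_cache$res)) return(.bench_cache$res)
  cfg <- sim_config(seed = 11L)
  rows <- list(); fits <- list()
  for (cc in 1:4) {
    ctx <- ssbleeg:::sim_context(cfg, cc)
    sp_true <- sparsity_level(ctx$J)
    act_true <- activation_level(ctx$J)
    for (i in 1:5) {
      tr <- simulate_trial(cfg, 11000L + cc * 100L + i, cc, context = ctx)
      f1 <- enet_fit(tr$recording, tr$lead_field_inv)
      f2 <- elasso_fit(tr$recording, tr$lead_field_inv)
      lf <- loreta_fit(tr$recording, tr$lead_field_inv)
      tps <- c(1L, 29L, 38L)
      mauc <- function(est) mean(vapply(tps, function(t)
        roc_auc(ctx$J$J[, t], est[, t]), numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        config = cc, trial = i,
        auc_enet = mauc(f1$estimate$J),
        auc_elasso = mauc(f2$estimate$J),
        auc_loreta = mauc(lf$solution$J),
        kcor = suppressWarnings(
          cor(f1$hyper$k, sp_true, method = "spearman")),
        a2cor = suppressWarnings(
          cor(2 * sqrt(f1$hyper$alpha1 * f1$hyper$k), sp_true,
              method = "spearman")),
        actcor = suppressWarnings(
          cor(activation_level(f2$estimate), act_true,
              method = "spearman")),
        enet_iter = f1$n_iter, enet_conv = f1$converged,
        elasso_iter = f2$n_iter, elasso_conv = f2$converged)
    }
  }
  .bench_cache$res <- do.call(rbind, rows)
  .bench_cache$res
}
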