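#' @keywords internal
"_PACKAGE"

# ---- domain types (lightweight S3 containers) --------------------------------

#' Source space: generator geometry and neighborhood structure
#'
#' Bundles the generator coordinates, a symmetric boolean adjacency relation
#' and the combinatorial graph Laplacian used both by the simulator (geodesic
#' patch supports) and by the LORETA baseline (smoothness operator).
#'
#' @param positions numeric S x 3 matrix of generator coordinates (mm).
#' @param adjacency logical (or 0/1) symmetric S x S matrix with empty
#'   diagonal; `adjacency[i, j]` marks i and j as neighbors.
#' @return An object of class `source_space` with elements `positions`,
#'   `adjacency` (logical matrix) and `laplacian`.
#' @export
source_space <- function(positions, adjacency) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !all(is.finite(positions)))
    stop("positions must be a finite S x 3 matrix")
  S <- nrow(positions)
  adjacency <- matrix(as.logical(adjacency), S, S)
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  diag(adjacency) <- FALSE
  out <- structure(
    list(positions = positions, adjacency = adjacency, laplacian = NULL),
    class = "source_space")
  out$laplacian <- graph_laplacian(out)
  out
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d generators, %d edges\n",
              nrow(x$positions), sum(x$adjacency) / 2L))
  invisible(x)
}

#' Combinatorial graph Laplacian of a source space
#'
#' `L = Deg - A`: rows sum to zero, positive semidefinite, with the constant
#' vector in its nullspace on every connected component. Isolated generators
#' yield zero rows.
#'
#' @param space a [source_space()] (or a list with an `adjacency` element).
#' @return S x S numeric Laplacian matrix.
#' @export
graph_laplacian <- function(space) {
  A <- space$adjacency
  A <- matrix(as.numeric(A), nrow(A), ncol(A))
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  diag(A) <- 0
  diag(rowSums(A)) - A
}

#' EEG recording container
#'
#' @param V numeric N x T matrix of scalp potentials (microvolts).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(V, fs = 1, t0 = 0) {
  V <- as.matrix(V)
  if (ncol(V) < 1L || !all(is.finite(V))) stop("V must be finite with T >= 1")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  structure(list(V = V, fs = fs, t0 = t0), class = "eeg_recording")
}

#' Lead field container
#'
#' @param K numeric N x S gain matrix (microvolts per unit source amplitude).
#' @param sensor_labels character vector of N sensor identifiers.
#' @param space the [source_space()] the columns refer to (optional but needed
#'   by the simulator and the distance-based metrics).
#' @param sensor_positions optional N x 3 sensor coordinates (mm).
#' @param model,seed provenance metadata used by [perturb_lead_field()].
#' @return Object of class `lead_field`.
#' @export
lead_field <- function(K, sensor_labels = NULL, space = NULL,
                       sensor_positions = NULL, model = NULL, seed = NULL) {
  K <- as.matrix(K)
  if (!all(is.finite(K))) stop("lead field entries must be finite")
  if (is.null(sensor_labels))
    sensor_labels <- sprintf("E%03d", seq_len(nrow(K)))
  structure(list(K = K, sensor_labels = sensor_labels, space = space,
                 sensor_positions = sensor_positions, model = model,
                 seed = seed),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d sensors x %d generators (model: %s)\n",
              nrow(x$K), ncol(x$K), x$model %||% "unknown"))
  invisible(x)
}

#' Spatio-temporal source container
#'
#' @param J numeric S x T current-density matrix.
#' @param space optional [source_space()] reference.
#' @return Object of class `st_source`.
#' @export
st_source <- function(J, space = NULL) {
  J <- as.matrix(J)
  if (!all(is.finite(J))) stop("J must be finite")
  structure(list(J = J, space = space), class = "st_source")
}

#' Effective prior variance container
#'
#' `lam` holds the per-generator prior variances Lambda and `lam_bar` the
#' dimensionless factors in `[0, 1]` (1 = unshrunk ridge coordinate, 0 = the
#' coordinate is pruned exactly).
#'
#' @param lam nonnegative numeric vector of prior variances.
#' @param lam_bar numeric vector in `[0, 1]`, same length.
#' @return Object of class `prior_variance`.
#' @export
prior_variance <- function(lam, lam_bar) {
  if (length(lam) != length(lam_bar)) stop("lam and lam_bar lengths differ")
  if (any(lam < 0) || any(lam_bar < 0) || any(lam_bar > 1 + 1e-12))
    stop("prior variance admissibility violated")
  structure(list(lam = as.numeric(lam), lam_bar = as.numeric(lam_bar)),
            class = "prior_variance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_K <- function(K) if (inherits(K, "lead_field")) K$K else as.matrix(K)
as_V <- function(V) if (inherits(V, "eeg_recording")) V$V else as.matrix(V)

# ---- Gaussian posterior ------------------------------------------------------

#' Per-time-point Gaussian posterior of the sources
#'
#' For the instantaneous model `v = K j + e`, `e ~ N(0, beta I)`,
#' `j ~ N(0, diag(lam))`, returns the posterior mean
#' `mu = D K' (K D K' + beta I)^-1 v` (D = diag(lam)), the diagonal of the
#' posterior covariance `Sigma = D - D K' (K D K')^-1 ... K D`, its
#' log-determinant and the data residual. Everything is computed through the
#' N x N system (cost O(N^2 S)); the S x S covariance is never formed.
#' Coordinates with `lam = 0` are pinned exactly at zero, and the
#' log-determinant is the pseudo-determinant over the positive support.
#'
#' @param K lead field ([lead_field()] or N x S matrix).
#' @param v length-N data vector.
#' @param lam a [prior_variance()] or a nonnegative S-vector of variances.
#' @param beta positive noise variance.
#' @return list of class `gaussian_posterior` with `mu`, `sigma_diag`,
#'   `sigma_logdet`, `residual`, and `tr_KSKt` (trace of `K Sigma K'`, used by
#'   the noise-variance update).
#' @export
gaussian_posterior <- function(K, v, lam, beta) {
  K <- as_K(K)
  lamv <- if (inherits(lam, "prior_variance")) lam$lam else as.numeric(lam)
  if (!all(is.finite(K)) || !all(is.finite(v)) || !all(is.finite(lamv)) ||
      !is.finite(beta))
    stop("nonfinite inputs to gaussian_posterior")
  if (beta <= 0) stop("beta must be > 0")
  if (any(lamv < 0)) stop("lam must be nonnegative")
  N <- nrow(K); S <- ncol(K)
  if (length(v) != N || length(lamv) != S) stop("dimension mismatch")

  KD <- K * rep(lamv, each = N)              # K D, N x S
  A <- tcrossprod(KD, K)                     # K D K', N x N
  M <- A + diag(beta, N)
  R <- tryCatch(chol(M), error = function(e)
    stop("singular N x N posterior system: ", conditionMessage(e)))
  Minv <- chol2inv(R)
  mu <- as.numeric(crossprod(KD, Minv %*% v))  # D K' M^-1 v
  quad <- colSums(K * (Minv %*% K))            # k_i' M^-1 k_i
  sigma_diag <- lamv - lamv^2 * quad
  sigma_diag[lamv == 0] <- 0
  sigma_diag <- pmax(sigma_diag, 0)
  # log|Sigma| (pseudo-det): log|D_P| + N log beta - log|M|
  logdetM <- 2 * sum(log(diag(R)))
  supp <- lamv > 0
  sigma_logdet <- sum(log(lamv[supp])) + N * log(beta) - logdetM
  resid <- as.numeric(v - K %*% mu)
  MA <- Minv %*% A
  tr_KSKt <- sum(diag(A)) - sum(A * MA)
  structure(list(mu = mu, sigma_diag = sigma_diag,
                 sigma_logdet = sigma_logdet, residual = resid,
                 tr_KSKt = tr_KSKt),
            class = "gaussian_posterior")
}

# ---- Type-II objective -------------------------------------------------------

#' Negative log-posterior of the hyperparameters (Type-II likelihood)
#'
#' Evaluates
#' `L = 1/2 sum_t { N log beta_t + ||v_t - K mu_t||^2 / beta_t
#'   + sum_i log Lambda_it + mu_t' diag(Lambda_t)^-1 mu_t + log|Sigma_t^-1| }
#'   + hyper_neglogprior`,
#' with all log and division terms restricted to the positive support of
#' `Lambda`. The posterior covariance convention for the `log|Sigma^-1|` term
#' is the instantaneous source posterior returned by [gaussian_posterior()].
#'
#' @param posteriors list of `gaussian_posterior` objects, one per time point.
#' @param lam list of [prior_variance()] (or numeric vectors), one per time
#'   point, the same used to compute `posteriors`.
#' @param hyper_neglogprior scalar: minus the log prior of the hyperparameters
#'   (model specific; see [enet_hyper_neglogprior()] and
#'   [elasso_hyper_neglogprior()]).
#' @param beta numeric T-vector of noise variances.
#' @return scalar objective value.
#' @export
type2_objective <- function(posteriors, lam, hyper_neglogprior, beta) {
  T_ <- length(posteriors)
  if (length(lam) != T_ || length(beta) != T_)
    stop("mismatched dimensions in type2_objective")
  total <- 0
  for (t in seq_len(T_)) {
    p <- posteriors[[t]]
    lv <- if (inherits(lam[[t]], "prior_variance")) lam[[t]]$lam
          else as.numeric(lam[[t]])
    if (length(lv) != length(p$mu)) stop("mismatched dimensions")
    N <- length(p$residual)
    supp <- lv > 0
    total <- total + 0.5 * (
      N * log(beta[t]) +
        sum(p$residual^2) / beta[t] +
        sum(log(lv[supp])) +
        sum(p$mu[supp]^2 / lv[supp]) -
        p$sigma_logdet)
  }
  total + hyper_neglogprior
}
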