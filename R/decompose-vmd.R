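#' Settings for variational mode decomposition
#'
#' @param K Number of modes (default 5).
#' @param alpha Bandwidth constraint weight (default 2000); larger values
#'   give narrower modes.
#' @param tol Convergence tolerance on the relative change of the mode
#'   spectra between iterations (default 1e-7).
#' @param noise_tolerance Lagrangian dual-ascent slack tau (default 0.0:
#'   no exact-reconstruction enforcement, which tolerates noise).
#' @param max_iter Iteration cap (default 500).
#' @return A list of class `vmd_settings`.
#' @export
vmd_settings <- function(K = 5L, alpha = 2000, tol = 1e-7,
                         noise_tolerance = 0, max_iter = 500L) {
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (!is.finite(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  structure(list(K = K, alpha = alpha, tol = tol,
                 noise_tolerance = noise_tolerance,
                 max_iter = as.integer(max_iter)),
            class = "vmd_settings")
}

#' Variational mode decomposition
#'
#' Decomposes a signal into `K` band-limited modes by the standard
#' alternating spectral scheme: each mode spectrum is updated by a Wiener
#' filter centred on its current centre frequency, the centre frequency is
#' re-estimated as the power-weighted mean frequency of the mode, and a
#' dual variable ascends with slack `noise_tolerance`, until the relative
#' change of the mode spectra falls below `tol` or `max_iter` is reached.
#' The signal is mirror-extended by half its length on each side before
#' the spectral iteration (odd-length inputs are padded by one sample and
#' trimmed on return). Modes are returned sorted by ascending centre
#' frequency, and `residual = signal - sum(modes)` so the conservation
#' identity holds exactly.
#'
#' @param signal An [ecg_signal()] or numeric vector.
#' @param settings A [vmd_settings()].
#' @param fs Sampling rate; taken from `signal` if it is an
#'   [ecg_signal()].
#' @return A list of class `mode_set` with elements `modes` (n x K
#'   matrix), `residual`, `center_frequencies` (Hz, ascending), `fs`,
#'   `source` (the decomposed samples), `settings`, `converged`,
#'   `iterations`.
#' @examples
#' t <- seq(0, 2, by = 1 / 200)[-1]
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 50 * t)
#' ms <- vmd(x, vmd_settings(K = 2), fs = 200)
#' ms$center_frequencies
#' @export
vmd <- function(signal, settings = vmd_settings(), fs = NULL) {
  fs <- signal_fs(signal, fs)
  x <- as_samples(signal)
  if (!all(is.finite(x))) stop("samples must be finite", call. = FALSE)
  n0 <- length(x)
  K <- settings$K
  if (n0 < 2L * K) stop("signal too short for the requested K", call. = FALSE)

  if (all(x == 0)) {
    return(new_mode_set(matrix(0, n0, K), rep(0, n0), rep(0, K), fs, x,
                        settings, TRUE, 0L))
  }

  padded <- n0 %% 2L == 1L
  xs <- if (padded) c(x, x[n0]) else x
  Tn <- length(xs)
  half <- Tn / 2L
  f <- c(rev(xs[1:half]), xs, rev(xs[(half + 1L):Tn]))
  N <- length(f)                       # = 2 * Tn, even
  Nh <- N / 2L                         # index of Nyquist bin is Nh + 1

  f_hat <- stats::fft(f)
  fh <- f_hat[1:(Nh + 1L)]             # one-sided spectrum, DC..Nyquist
  w <- (0:Nh) / N                      # normalized frequency, cycles/sample

  alpha <- settings$alpha              # acts on normalized frequency
  u_hat <- matrix(complex(real = 0, imaginary = 0), Nh + 1L, K)
  omega <- 0.5 * (seq_len(K) - 1L) / K # uniform initialization in [0, 0.5)
  lambda_hat <- complex(real = rep(0, Nh + 1L))
  tau <- settings$noise_tolerance

  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    u_prev <- u_hat
    sum_u <- rowSums(u_hat)
    for (k in seq_len(K)) {
      sum_others <- sum_u - u_hat[, k]
      u_hat[, k] <- (fh - sum_others + lambda_hat / 2) /
        (1 + 2 * alpha * (w - omega[k])^2)
      pw <- Mod(u_hat[, k])^2
      tot <- sum(pw)
      omega[k] <- if (tot > 0) sum(w * pw) / tot else omega[k]
      sum_u <- sum_others + u_hat[, k]
    }
    lambda_hat <- lambda_hat + tau * (sum_u - fh)
    denom <- sum(Mod(u_prev)^2)
    u_diff <- if (denom > 0) sum(Mod(u_hat - u_prev)^2) / denom else Inf
    if (u_diff < settings$tol) { converged <- TRUE; break }
    if (it >= settings$max_iter) break
  }

  # Back to time domain: hermitian-symmetrize each one-sided mode spectrum.
  modes <- matrix(0, n0, K)
  for (k in seq_len(K)) {
    full <- complex(real = rep(0, N))
    full[1:(Nh + 1L)] <- u_hat[, k]
    full[N:(Nh + 2L)] <- Conj(u_hat[2:Nh, k])
    ut <- Re(stats::fft(full, inverse = TRUE)) / N
    seg <- ut[(half + 1L):(half + Tn)]
    modes[, k] <- seg[1:n0]
  }

  ord <- order(omega)
  modes <- modes[, ord, drop = FALSE]
  cf <- omega[ord] * fs
  residual <- x - rowSums(modes)
  new_mode_set(modes, residual, cf, fs, x, settings, converged, it)
}

new_mode_set <- function(modes, residual, cf, fs, source, settings,
                         converged, iterations) {
  structure(
    list(modes = modes, residual = residual, center_frequencies = cf,
         fs = fs, source = source, settings = settings,
         converged = converged, iterations = iterations),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> K=%d, n=%d, fs=%g Hz, %sconverged (%d iter)\n",
              ncol(x$modes), nrow(x$modes), x$fs,
              if (x$converged) "" else "NOT ", x$iterations))
  cat("  center frequencies (Hz):",
      paste(sprintf("%.2f", x$center_frequencies), collapse = ", "), "\n")
  invisible(x)
}

#' Parameters for the adaptive refinement stage
#'
#' Controls the gradient-descent refinement of a mode set under the
#' noise-regularized objective
#' `Obj(s, n) = ||x - sum(s_i) - n||^2 + sum(lambda_i ||s_i||_p) +
#' gamma_reg ||n||_q`.
#'
#' @param eta Learning rate (default 0.01).
#' @param lambda Per-mode regularization weights (default 1e-3; recycled
#'   to `K`).
#' @param gamma_reg Residual-noise regularization weight (default 1e-3).
#'   Named to avoid clashing with the half-life light intensity used in
#'   key generation.
#' @param p,q Norm orders for the mode and noise penalties; 1 or 2
#'   (default 2).
#' @param iterations Maximum refinement steps (default 50).
#' @param tol Stop when the objective decreases by less than this
#'   (default 1e-9).
#' @return A list of class `adaptive_vmd_params`.
#' @export
adaptive_vmd_params <- function(eta = 0.01, lambda = 1e-3, gamma_reg = 1e-3,
                                p = 2L, q = 2L, iterations = 50L,
                                tol = 1e-9) {
  if (!is.finite(eta) || eta <= 0) stop("`eta` must be > 0", call. = FALSE)
  if (any(lambda < 0) || gamma_reg < 0) {
    stop("regularization weights must be >= 0", call. = FALSE)
  }
  if (!p %in% c(1L, 2L) || !q %in% c(1L, 2L)) {
    stop("`p` and `q` must be 1 or 2", call. = FALSE)
  }
  structure(list(eta = eta, lambda = lambda, gamma_reg = gamma_reg,
                 p = as.integer(p), q = as.integer(q),
                 iterations = as.integer(iterations), tol = tol),
            class = "adaptive_vmd_params")
}

# Value and subgradient of w * ||v||_p for p in {1, 2}.
norm_penalty <- function(v, w, p) {
  if (w == 0) return(list(value = 0, grad = numeric(length(v))))
  if (p == 2L) {
    nv <- sqrt(sum(v^2))
    g <- if (nv > 0) w * v / nv else numeric(length(v))
    list(value = w * nv, grad = g)
  } else {
    list(value = w * sum(abs(v)), grad = w * sign(v))
  }
}

#' Noise-regularized gradient refinement of a mode set
#'
#' Runs gradient descent jointly on the modes `s_i` and the residual-noise
#' estimate `n` under
#' `Obj = ||x - sum(s_i) - n||^2 + sum(lambda_i ||s_i||_p) +
#' gamma_reg ||n||_q`,
#' with updates `s_i <- s_i - eta * dObj/ds_i` and
#' `n <- n - eta * dObj/dn`. Stops after `iterations` steps or as soon as
#' the objective decreases by less than `tol`; aborts with an error if the
#' objective increases on five consecutive steps (divergence -- reduce
#' `eta`). The recorded objective trajectory is returned in the
#' `"objective_trajectory"` attribute of the result.
#'
#' @param modeset A `mode_set` from [vmd()].
#' @param params An [adaptive_vmd_params()].
#' @return A refined `mode_set` (centre frequencies re-estimated from the
#'   refined modes) with attribute `objective_trajectory`.
#' @export
adaptive_refine <- function(modeset, params = adaptive_vmd_params()) {
  stopifnot(inherits(modeset, "mode_set"))
  x <- modeset$source
  s <- modeset$modes
  n_est <- modeset$residual
  K <- ncol(s)
  lambda <- rep_len(params$lambda, K)

  objective <- function(s, n_est) {
    r <- x - rowSums(s) - n_est
    val <- sum(r^2)
    for (k in seq_len(K)) {
      val <- val + norm_penalty(s[, k], lambda[k], params$p)$value
    }
    val + norm_penalty(n_est, params$gamma_reg, params$q)$value
  }

  traj <- objective(s, n_est)
  inc_run <- 0L
  for (step in seq_len(params$iterations)) {
    r <- x - rowSums(s) - n_est
    s_new <- s
    for (k in seq_len(K)) {
      g <- -2 * r + norm_penalty(s[, k], lambda[k], params$p)$grad
      s_new[, k] <- s[, k] - params$eta * g
    }
    gn <- -2 * r + norm_penalty(n_est, params$gamma_reg, params$q)$grad
    n_new <- n_est - params$eta * gn

    obj_new <- objective(s_new, n_new)
    obj_prev <- traj[length(traj)]
    if (obj_new > obj_prev) {
      inc_run <- inc_run + 1L
      if (inc_run >= 5L) {
        stop("adaptive refinement diverged (objective increased on 5 ",
             "consecutive steps); try a smaller `eta`", call. = FALSE)
      }
    } else {
      inc_run <- 0L
    }
    s <- s_new
    n_est <- n_new
    traj <- c(traj, obj_new)
    if (obj_prev - obj_new >= 0 && obj_prev - obj_new < params$tol) break
  }

  cf <- vapply(seq_len(K), function(k) {
    mode_center_frequency(s[, k], modeset$fs)
  }, numeric(1))
  ord <- order(cf)
  out <- new_mode_set(s[, ord, drop = FALSE], n_est, cf[ord], modeset$fs,
                      x, modeset$settings, TRUE, length(traj) - 1L)
  attr(out, "objective_trajectory") <- traj
  attr(out, "refine_params") <- unclass(params)
  out
}

# Power-weighted mean frequency of a sequence (Hz).
mode_center_frequency <- function(v, fs) {
  n <- length(v)
  sp <- Mod(stats::fft(v))^2
  nh <- floor(n / 2)
  pw <- sp[1:(nh + 1L)]
  fr <- (0:nh) * fs / n
  tot <- sum(pw)
  if (tot == 0) 0 else sum(fr * pw) / tot
}

#' Reconstruct a signal from selected modes
#'
#' Sums the selected modes of a decomposition. The residual is always
#' excluded -- dropping it is the denoising step.
#'
#' @param modeset A `mode_set`.
#' @param include_modes Indices of modes to sum (default: all).
#' @return An [ecg_signal()] holding the reconstruction.
#' @export
reconstruct <- function(modeset, include_modes = seq_len(ncol(modeset$modes))) {
  stopifnot(inherits(modeset, "mode_set"))
  include_modes <- as.integer(include_modes)
  if (length(include_modes) == 0L) {
    stop("`include_modes` must select at least one mode", call. = FALSE)
  }
  if (any(include_modes < 1L | include_modes > ncol(modeset$modes))) {
    stop("mode index out of range", call. = FALSE)
  }
  y <- rowSums(modeset$modes[, include_modes, drop = FALSE])
  ecg_signal(y, modeset$fs, label = "vmd reconstruction")
}
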