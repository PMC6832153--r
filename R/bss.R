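# Blind source separation: whitening, fixed-point fastICA (higher-order
# statistics) and SOBI (second-order statistics via approximate joint
# diagonalization of time-lagged covariances).
#
# Model: observed channels x(t) = A s(t) with A unknown and instantaneous.
# Both algorithms estimate a separation matrix B so that s'(t) = B x(t)
# recovers the sources up to scale and permutation; recovery quality is
# therefore always judged with the permutation-invariant Amari index.

#' Whiten a channel matrix
#'
#' Removes the channel means and applies an eigendecomposition-based linear
#' transform so the output has identity sample covariance.
#'
#' @param x Channel-by-time numeric matrix (>= 2 channels, more samples
#'   than channels).
#' @return List with `z` (whitened matrix), `K` (whitening matrix),
#'   `means` (channel means) and `K_inv` (its pseudo-inverse).
#' @export
whiten <- function(x) {
  mp_assert(is.matrix(x) && nrow(x) >= 2, "need a matrix with at least 2 channels",
            "parameter")
  mp_assert(ncol(x) > nrow(x), "need more samples than channels", "parameter")
  mp_assert(all(is.finite(x)), "input contains non-finite values", "data")
  means <- rowMeans(x)
  xc <- x - means
  C <- tcrossprod(xc) / (ncol(x) - 1)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= max(e$values) * 1e-10) {
    mp_abort("covariance is rank deficient; channels are linearly dependent", "degenerate")
  }
  K <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  list(z = K %*% xc, K = K, means = means,
       K_inv = e$vectors %*% diag(sqrt(e$values)))
}

#' fastICA contrast configuration
#'
#' @param name Nonlinearity approximating negentropy: `"tanh"` or `"cube"`.
#' @param tolerance Convergence tolerance on the unmixing row directions.
#' @param max_iterations Iteration cap.
#' @param mode `"symmetric"` (all rows updated and re-decorrelated each
#'   step) or `"deflation"` (rows extracted one by one).
#' @param seed Seed for the random initial unmixing matrix.
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(name = c("tanh", "cube"), tolerance = 1e-4,
                          max_iterations = 200, mode = c("symmetric", "deflation"),
                          seed = 1) {
  name <- match.arg(name); mode <- match.arg(mode)
  mp_assert(is.finite(tolerance) && tolerance > 0, "tolerance must be > 0", "parameter")
  mp_assert(is_count(max_iterations), "max_iterations must be >= 1", "parameter")
  structure(list(name = name, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations), mode = mode,
                 seed = as.integer(seed)),
            class = "contrast_spec")
}

new_unmixing_result <- function(B, sources, whitener, converged, n_iterations, method) {
  structure(list(B = B, sources = sources, whitener = whitener,
                 converged = converged, n_iterations = n_iterations, method = method),
            class = "unmixing_result")
}

#' @export
print.unmixing_result <- function(x, ...) {
  cat(sprintf("<unmixing_result> %s: %d sources x %d samples, %sconverged in %d iterations\n",
              x$method, nrow(x$sources), ncol(x$sources),
              if (x$converged) "" else "NOT ", x$n_iterations))
  invisible(x)
}

orthonormalize <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300))) %*% t(e$vectors) %*% W
}

#' Estimate sources with fixed-point fastICA
#'
#' Whitens the input, then runs the fixed-point iteration that maximizes the
#' sum of marginal negentropy approximations (equivalently, minimizes mutual
#' information after whitening). Non-convergence is reported through the
#' `converged` flag, not an error.
#'
#' @param x Channel-by-time matrix.
#' @param spec A [contrast_spec()].
#' @return An `unmixing_result` with separation matrix `B` (so that
#'   `sources = B %*% (x - means)`), unit-variance estimated `sources`,
#'   the whitener, and convergence metadata.
#' @examples
#' s <- rbind(runif(1000), sin(2 * pi * 7 * (1:1000) / 100))
#' res <- fastica(matrix(c(1, 0.4, -0.3, 1), 2, 2) %*% s)
#' res$converged
#' @export
fastica <- function(x, spec = contrast_spec()) {
  mp_assert(inherits(spec, "contrast_spec"), "spec must be a contrast_spec", "parameter")
  mp_assert(is.matrix(x), "x must be a matrix", "parameter")
  mp_assert(all(is.finite(x)), "input contains non-finite values", "data")
  wh <- whiten(x)
  z <- wh$z
  p <- nrow(z); n <- ncol(z)
  g <- if (spec$name == "tanh") {
    function(u) list(gu = tanh(u), dg = 1 - tanh(u)^2)
  } else {
    function(u) list(gu = u^3, dg = 3 * u^2)
  }
  W0 <- with_seed(spec$seed, matrix(rnorm(p * p), p, p))
  if (spec$mode == "symmetric") {
    W <- sym_decorrelate(orthonormalize(W0))
    converged <- FALSE
    iter <- 0L
    while (iter < spec$max_iterations) {
      iter <- iter + 1L
      U <- W %*% z
      gg <- g(U)
      W1 <- gg$gu %*% t(z) / n - diag(rowMeans(gg$dg), p) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < spec$tolerance) { converged <- TRUE; break }
    }
  } else {
    W <- matrix(0, p, p)
    total_iter <- 0L
    converged <- TRUE
    for (i in seq_len(p)) {
      w <- W0[i, ] / sqrt(sum(W0[i, ]^2))
      ok <- FALSE
      for (it in seq_len(spec$max_iterations)) {
        total_iter <- total_iter + 1L
        u <- drop(w %*% z)
        gg <- g(u)
        w1 <- drop(z %*% gg$gu) / n - mean(gg$dg) * w
        if (i > 1) {
          Wp <- W[seq_len(i - 1), , drop = FALSE]
          w1 <- w1 - drop(t(Wp) %*% (Wp %*% w1))
        }
        w1 <- w1 / sqrt(sum(w1^2))
        if (abs(abs(sum(w1 * w)) - 1) < spec$tolerance) { w <- w1; ok <- TRUE; break }
        w <- w1
      }
      if (!ok) converged <- FALSE
      W[i, ] <- w
    }
    iter <- total_iter
  }
  B <- W %*% wh$K
  new_unmixing_result(B, W %*% z, wh[c("K", "means", "K_inv")], converged, iter, "fastica")
}

# Approximate joint diagonalization of symmetric matrices by Jacobi
# rotations (Cardoso-Souloumiac). Returns the orthogonal V and the
# off-diagonal energy after each sweep.
joint_diagonalize <- function(mats, tol = 1e-8, max_sweeps = 100) {
  p <- nrow(mats[[1]])
  V <- diag(p)
  off_energy <- function(ms) sum(vapply(ms, function(m) sum(m^2) - sum(diag(m)^2),
                                        numeric(1)))
  energy <- off_energy(mats)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    max_s <- 0
    for (pp in seq_len(p - 1)) {
      for (qq in (pp + 1):p) {
        ton <- vapply(mats, function(m) m[pp, pp] - m[qq, qq], numeric(1))
        toff <- vapply(mats, function(m) m[pp, qq] + m[qq, pp], numeric(1))
        G <- matrix(c(sum(ton * ton), sum(ton * toff),
                      sum(ton * toff), sum(toff * toff)), 2, 2)
        ev <- eigen(G, symmetric = TRUE)
        angles <- ev$vectors[, 1]
        if (angles[1] < 0) angles <- -angles
        r <- sqrt(sum(angles^2))
        cth <- sqrt((angles[1] + r) / (2 * r))
        sth <- angles[2] / sqrt(2 * r * (angles[1] + r))
        if (abs(sth) > max_s) max_s <- abs(sth)
        if (abs(sth) > .Machine$double.eps) {
          R <- diag(p); R[pp, pp] <- cth; R[qq, qq] <- cth
          R[pp, qq] <- -sth; R[qq, pp] <- sth
          mats <- lapply(mats, function(m) t(R) %*% m %*% R)
          V <- V %*% R
        }
      }
    }
    energy <- c(energy, off_energy(mats))
    if (max_s < tol || sweeps >= max_sweeps) break
  }
  list(V = V, sweeps = sweeps, off_energy = energy, converged = sweeps < max_sweeps)
}

#' Estimate sources with SOBI
#'
#' Second-order blind identification: whitens the input, forms symmetrized
#' time-lagged covariance matrices of the whitened data at the given lags,
#' and jointly diagonalizes them with Jacobi rotations. Suited to sources
#' with distinct spectra; separation of temporally white sources is
#' undefined (the call still succeeds).
#'
#' @param x Channel-by-time matrix.
#' @param lags Positive integer sample lags; the largest must be below half
#'   the sample count.
#' @return An `unmixing_result`; `n_iterations` counts Jacobi sweeps and
#'   the off-diagonal energy path is attached as attribute `off_energy`.
#' @export
sobi <- function(x, lags = 1:min(100, floor(ncol(x) / 3))) {
  mp_assert(is.matrix(x), "x must be a matrix", "parameter")
  if (!length(lags)) mp_abort("lags must be a nonempty set of positive offsets", "parameter")
  mp_assert(all(lags >= 1) && all(lags == floor(lags)), "lags must be positive integers",
            "parameter")
  mp_assert(max(lags) < ncol(x) / 2, "max lag must be below half the sample count",
            "parameter")
  mp_assert(all(is.finite(x)), "input contains non-finite values", "data")
  wh <- whiten(x)
  z <- wh$z
  n <- ncol(z)
  mats <- lapply(lags, function(l) {
    R <- z[, 1:(n - l), drop = FALSE] %*% t(z[, (l + 1):n, drop = FALSE]) / (n - l)
    (R + t(R)) / 2
  })
  jd <- joint_diagonalize(mats)
  B <- t(jd$V) %*% wh$K
  res <- new_unmixing_result(B, t(jd$V) %*% z, wh[c("K", "means", "K_inv")],
                             jd$converged, jd$sweeps, "sobi")
  attr(res, "off_energy") <- jd$off_energy
  res
}

#' Amari separation error
#'
#' Permutation- and scale-invariant distance between an estimated
#' separation and the true mixing: 0 if and only if `B_eff %*% A` is a
#' scaled permutation matrix; the worst case approaches `m - 1` for an
#' m-dimensional problem (2 for 3x3 all-ones).
#'
#' @param B_eff Estimated separation matrix (e.g. `result$B`).
#' @param A True mixing matrix; `B_eff %*% A` must be square.
#' @return Nonnegative scalar.
#' @examples
#' amari_index(diag(3), diag(3))  # 0
#' @export
amari_index <- function(B_eff, A) {
  P <- B_eff %*% A
  if (nrow(P) != ncol(P)) mp_abort("B_eff %*% A must be square", "shape")
  Pa <- abs(P)
  m <- nrow(Pa)
  rows <- sum(rowSums(Pa) / apply(Pa, 1, max) - 1)
  cols <- sum(colSums(Pa) / apply(Pa, 2, max) - 1)
  (rows + cols) / (2 * m)
}
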