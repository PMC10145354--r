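# FastICA (hyperbolic-tangent contrast, symmetric decorrelation) on a
# channels x samples matrix. Deterministic given `seed`. Returns the
# unmixing matrix in sensor space (sources = unmixing %*% centered data),
# the mixing matrix (its pseudo-inverse), the sources, and the row means.
#
# When `n_comp` is NULL the dimensionality is chosen by PCA to retain
# `var_keep` of the total variance: trailing near-noise dimensions carry
# no separable structure and, being Gaussian, make the symmetric update
# rotate indefinitely without this reduction. Full-rank data keeps all
# components, so reconstruction with nothing rejected is then exact.
fast_ica <- function(x, n_comp = NULL, seed = 1L,
                     max_iter = 1000L, tol = 1e-6, var_keep = 0.999) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  n_ch <- nrow(x)
  n_t <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu

  cv <- tcrossprod(xc) / (n_t - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (is.null(n_comp)) {
    cum <- cumsum(eg$values) / sum(eg$values)
    n_comp <- which(cum >= var_keep)[1]
  }
  if (min(eg$values) < max(eg$values) * 1e-12) {
    cm <- stats::cor(t(xc))
    labels <- rownames(x) %||% paste0("ch", seq_len(n_ch))
    diag(cm) <- 0
    idx <- which(abs(cm) > 0.999, arr.ind = TRUE)
    pairs <- unique(apply(idx, 1, function(i) {
      paste(sort(labels[i]), collapse = "~")
    }))
    stop("rank-deficient data: channel pair(s) ",
         paste(pairs, collapse = ", "), " are (nearly) collinear",
         call. = FALSE)
  }
  keep <- seq_len(n_comp)
  k_mat <- diag(1 / sqrt(eg$values[keep])) %*% t(eg$vectors[, keep, drop = FALSE])
  z <- k_mat %*% xc                      # whitened: n_comp x n_t

  sym_orth <- function(w) {
    sv <- svd(w)
    sv$u %*% t(sv$v)
  }
  w <- with_seed(seed, matrix(stats::rnorm(n_comp^2), n_comp))
  w <- sym_orth(w)

  iter <- 0L
  delta <- Inf
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    wz <- w %*% z
    g <- tanh(wz)
    g_prime <- rowMeans(1 - g^2)
    w_new <- sym_orth(g %*% t(z) / n_t - diag(g_prime) %*% w)
    d_comp <- abs(1 - abs(rowSums(w_new * w)))
    delta <- max(d_comp)
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    # ICA directions are non-identifiable for Gaussian sources: once every
    # still-moving component is indistinguishable from Gaussian (excess
    # kurtosis ~ 0), further rotation within that subspace is arbitrary
    # and the decomposition is as converged as it can be. The symmetric
    # decorrelation couples all rows, so "settled" uses a looser
    # per-component threshold than the global tolerance.
    if (iter >= 20L && iter %% 5L == 0L) {
      moving <- which(d_comp >= 1e-3)
      s_mov <- w[moving, , drop = FALSE] %*% z
      exk <- abs(rowMeans(s_mov^4) / rowMeans(s_mov^2)^2 - 3)
      if (all(exk < 0.15)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    stop("FastICA failed to converge: after ", iter,
         " iterations the update delta was ", format(delta, digits = 3),
         " (tolerance ", tol, ") and non-Gaussian components were still ",
         "moving", call. = FALSE)
  }

  unmixing <- w %*% k_mat                # n_comp x n_ch, sensor space
  sources <- unmixing %*% xc
  mixing <- if (n_comp == n_ch) {
    solve(unmixing)
  } else {
    # least-squares inverse for reduced decompositions
    t(unmixing) %*% solve(unmixing %*% t(unmixing))
  }
  list(unmixing = unmixing, mixing = mixing, sources = sources,
       means = mu, n_iter = iter)
}
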