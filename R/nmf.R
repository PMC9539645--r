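# Nonnegative matrix factorization by multiplicative updates (Frobenius
# loss) with nonnegative-double-SVD initialization. This factorizer is the
# engine of both topic layers; it is deliberately minimal, deterministic
# given a seed, and records its error trace so the monotone-descent
# guarantee of the update rule can be asserted.

.NMF_EPS <- 1e-10

#' Nonnegative matrix factorization
#'
#' Factorizes a nonnegative matrix `A` (n x m) into `W` (n x k) and `H`
#' (k x m), minimizing the Frobenius reconstruction error with the classical
#' multiplicative update rules. Initialization is NNDSVD with zero entries
#' replaced by small seeded random values, so runs are reproducible and the
#' update rules cannot lock on structural zeros.
#'
#' @param A Nonnegative numeric matrix or `Matrix` sparse matrix.
#' @param k Number of factors, `1 <= k <= min(dim(A))`.
#' @param seed Integer seed controlling the random fill of the initializer.
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative-improvement convergence tolerance on the error,
#'   checked every 10 iterations (default 1e-6).
#' @param init `"nndsvdar"` (default) or `"random"`; alternatively supply
#'   `W0`/`H0` explicitly.
#' @param W0,H0 Optional explicit initial factors (override `init`).
#' @param normalize If `TRUE` (default), rows of `H` are rescaled to sum to
#'   one after convergence, with the inverse scaling applied to the columns
#'   of `W` so the product is unchanged.
#' @return List of class `nmf_fit`: `W`, `H`, `error` (final Frobenius
#'   error), `error_trace`, `iters`, `converged`.
#' @export
fit_nmf <- function(A, k, seed = 1L, max_iter = 500L, tol = 1e-6,
                    init = c("nndsvdar", "random"), W0 = NULL, H0 = NULL,
                    normalize = TRUE) {
  init <- match.arg(init)
  Ad <- as.matrix(A)
  if (any(!is.finite(Ad))) stop("A contains non-finite entries")
  if (any(Ad < 0)) stop("A must be nonnegative")
  n <- nrow(Ad); m <- ncol(Ad)
  k <- as.integer(k)
  if (k < 1L || k > min(n, m)) {
    stop(sprintf("k must satisfy 1 <= k <= min(%d, %d)", n, m))
  }

  if (is.null(W0) || is.null(H0)) {
    fac <- if (init == "nndsvdar") .nndsvdar(Ad, k, seed) else .random_init(Ad, k, seed)
    W <- fac$W; H <- fac$H
  } else {
    W <- W0; H <- H0
  }

  err <- .frob_err(Ad, W, H)
  trace <- err
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    # H <- H * (W'A) / (W'W H)
    H <- H * crossprod(W, Ad) / (crossprod(W) %*% H + .NMF_EPS)
    # W <- W * (A H') / (W H H')
    W <- W * tcrossprod(Ad, H) / (W %*% tcrossprod(H) + .NMF_EPS)
    iters <- it
    if (it %% 10L == 0L || it == max_iter) {
      new_err <- .frob_err(Ad, W, H)
      trace <- c(trace, new_err)
      if (err - new_err < tol * max(err, .NMF_EPS)) {
        err <- new_err
        converged <- TRUE
        break
      }
      err <- new_err
    }
  }

  if (normalize) {
    s <- rowSums(H)
    s[s == 0] <- 1
    H <- H / s
    W <- W %*% diag(s, nrow = k)
  }
  rownames(W) <- rownames(Ad)
  colnames(H) <- colnames(Ad)
  structure(list(W = W, H = H, k = k, error = .frob_err(Ad, W, H),
                 error_trace = trace, iters = iters, converged = converged),
            class = "nmf_fit")
}

.frob_err <- function(A, W, H) sqrt(sum((A - W %*% H)^2))

# NNDSVD (Boutsidis & Gallopoulos) with the "ar" variant: structural zeros
# of the SVD-based seed are filled with small seeded random values.
.nndsvdar <- function(A, k, seed) {
  sv <- svd(A, nu = k, nv = k)
  n <- nrow(A); m <- ncol(A)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2L) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn) {
        sig <- nup * nvp
        if (sig > 0) {
          W[, j] <- sqrt(sv$d[j] * sig) * up / nup
          H[j, ] <- sqrt(sv$d[j] * sig) * vp / nvp
        }
      } else {
        sig <- nun * nvn
        if (sig > 0) {
          W[, j] <- sqrt(sv$d[j] * sig) * un / nun
          H[j, ] <- sqrt(sv$d[j] * sig) * vn / nvn
        }
      }
    }
  }
  avg <- mean(A) / 100
  old <- .Random.seed_get()
  set.seed(seed)
  W[W == 0] <- avg * stats::runif(sum(W == 0))
  H[H == 0] <- avg * stats::runif(sum(H == 0))
  .Random.seed_restore(old)
  list(W = W, H = H)
}

.random_init <- function(A, k, seed) {
  old <- .Random.seed_get()
  set.seed(seed)
  scale <- sqrt(mean(A) / k)
  W <- matrix(scale * stats::runif(nrow(A) * k), nrow(A), k)
  H <- matrix(scale * stats::runif(k * ncol(A)), k, ncol(A))
  .Random.seed_restore(old)
  list(W = W, H = H)
}

# save/restore the global RNG state so model fitting does not perturb the
# caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: k = %d, %d iterations (%s), Frobenius error %.6g\n",
              x$k, x$iters, if (x$converged) "converged" else "cap reached",
              x$error))
  invisible(x)
}
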