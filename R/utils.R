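# Internal numerical helpers shared across modules.

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; cached because every polychoric likelihood evaluation reuses them.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- res
  res
}

# Standard bivariate normal CDF P(X <= h, Y <= k) with correlation rho,
# vectorized over h and k.  Uses the identity
#   Phi2(h, k, rho) = Phi(h) Phi(k) + int_0^rho phi2(h, k, r) dr
# (derivative of the CDF with respect to rho equals the density), with the
# integral evaluated by 48-node Gauss-Legendre quadrature.  The integrand is
# smooth on |r| <= 1 - 1e-6, so the quadrature is accurate to near machine
# precision over the range used by the polychoric estimator.
pbinorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), abs(rho) < 1)
  n <- max(length(h), length(k))
  h <- rep_len(h, n)
  k <- rep_len(k, n)
  out <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(out)
  fin <- is.finite(h) & is.finite(k)
  # infinite bounds: the rho term vanishes (CDF reduces to a marginal or 0/1)
  if (any(fin)) {
    gl <- gauss_legendre(48L)
    r <- rho / 2 * (gl$nodes + 1)        # map [-1,1] -> [0, rho]
    w <- gl$weights * rho / 2
    hf <- h[fin]; kf <- k[fin]
    acc <- numeric(length(hf))
    for (j in seq_along(r)) {
      rj <- r[j]
      om <- 1 - rj^2
      acc <- acc + w[j] *
        exp(-(hf^2 - 2 * rj * hf * kf + kf^2) / (2 * om)) / (2 * pi * sqrt(om))
    }
    out[fin] <- out[fin] + acc
  }
  pmin(pmax(out, 0), 1)
}

# Unbiased (n-1) sample variance of a vector; the package-wide convention.
sample_var <- function(x) stats::var(x)

# FNV-1a 32-bit hash of a character scalar, reported as 8 hex digits.  Used to
# stamp pipeline outputs with a configuration fingerprint without adding a
# dependency.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h2 <- bitwXor(lo, b) + hi * 65536
    lo <- h2 %% 65536
    hi <- (h2 - lo) / 65536
    # split multiply keeps intermediates below 2^53 so doubles stay exact
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", (h - h %% 65536) / 65536), sprintf("%04x", h %% 65536))
}
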