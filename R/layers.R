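# Layer primitives for the 2D segmentation network. Activations are stored
# as (H, W, C, N) arrays; convolutions delegate to the C++ im2col + GEMM
# kernels, batch normalization and activations are vectorized R.

as_nhwc <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3D or 4D array", call. = FALSE)
  x
}

conv_fwd <- function(x, w, b) .cpp_conv2d_fwd(as_nhwc(x), w, b)

conv_bwd <- function(x, w, dy) .cpp_conv2d_bwd(as_nhwc(x), w, dy)

conv_init <- function(k, cin, cout, leaky_slope = 0.01) {
  fan_in <- k * k * cin
  sd <- sqrt(2 / (fan_in * (1 + leaky_slope^2)))
  list(W = array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

bn_fwd <- function(x, gamma, beta, rm, rv, mode, momentum = 0.1,
                   eps = 1e-5) {
  x <- as_nhwc(x)
  C <- dim(x)[3]
  y <- x
  cache <- vector("list", C)
  for (c in seq_len(C)) {
    xc <- x[, , c, , drop = FALSE]
    if (mode == "train") {
      mu <- mean(xc)
      v <- mean((xc - mu)^2)
      rm[c] <- (1 - momentum) * rm[c] + momentum * mu
      rv[c] <- (1 - momentum) * rv[c] + momentum * v
    } else {
      mu <- rm[c]
      v <- rv[c]
    }
    invstd <- 1 / sqrt(v + eps)
    xhat <- (xc - mu) * invstd
    y[, , c, ] <- gamma[c] * xhat + beta[c]
    cache[[c]] <- list(xhat = xhat, invstd = invstd)
  }
  list(y = y, cache = cache, rm = rm, rv = rv)
}

bn_bwd <- function(dy, cache, gamma) {
  dy <- as_nhwc(dy)
  C <- dim(dy)[3]
  dx <- dy
  dgamma <- numeric(C)
  dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dyc <- dy[, , c, , drop = FALSE]
    xhat <- cache[[c]]$xhat
    invstd <- cache[[c]]$invstd
    dgamma[c] <- sum(dyc * xhat)
    dbeta[c] <- sum(dyc)
    m <- length(dyc)
    dxhat <- dyc * gamma[c]
    dx[, , c, ] <- invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

lrelu_bwd <- function(dy, x, slope) dy * (slope + (1 - slope) * (x > 0))

dropout_fwd <- function(x, rate, mode) {
  if (mode != "train" || rate <= 0)
    return(list(y = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

maxpool_fwd <- function(x) .cpp_maxpool2_fwd(as_nhwc(x))

maxpool_bwd <- function(dy, idx, dim_in) .cpp_maxpool2_bwd(dy, idx, dim_in)

upsample_fwd <- function(x) .cpp_upsample2_fwd(as_nhwc(x))

upsample_bwd <- function(dy, dim_in) .cpp_upsample2_bwd(dy, dim_in)

concat_c <- function(a, b) {
  a <- as_nhwc(a); b <- as_nhwc(b)
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_c <- function(x, c1) {
  x <- as_nhwc(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , -seq_len(c1), , drop = FALSE])
}
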