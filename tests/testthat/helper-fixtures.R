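# Shared fixtures. Phantoms are generated in code; the trained benchmark
# model is built once on first use and cached for the session, since the
# end-to-end checks share it.

small_phantom <- function(seed = 3, n_slices = 6, slice_size = 256, ...) {
  generate_phantom_case(phantom_spec(n_slices = n_slices,
                                     slice_size = slice_size,
                                     seed = seed, ...))
}

clean_phantom <- function(seed = 3, n_slices = 6, slice_size = 256) {
  small_phantom(seed, n_slices, slice_size, artifact_level = 0,
                dropout_probability = 0, noise_sigma = 0)
}

# brute-force 3D flood fill used as the independent labeling oracle
oracle_label3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- expand.grid(dh = -1:1, dw = -1:1, ds = -1:1)
  nb <- nb[rowSums(abs(nb)) > 0, ]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, ]
  k <- 0L
  for (i in seq_along(mask)) {
    if (mask[i] == 0 || lab[i] != 0) next
    k <- k + 1L
    queue <- i
    lab[i] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      s <- (v - 1) %/% (d[1] * d[2]) + 1
      rem <- (v - 1) %% (d[1] * d[2])
      w <- rem %/% d[1] + 1
      h <- rem %% d[1] + 1
      for (q in seq_len(nrow(nb))) {
        hh <- h + nb$dh[q]; ww <- w + nb$dw[q]; ss <- s + nb$ds[q]
        if (hh < 1 || hh > d[1] || ww < 1 || ww > d[2] ||
            ss < 1 || ss > d[3]) next
        u <- hh + d[1] * (ww - 1) + d[1] * d[2] * (ss - 1)
        if (mask[u] != 0 && lab[u] == 0L) {
          lab[u] <- k
          queue <- c(queue, u)
        }
      }
    }
  }
  lab
}

# central finite-difference gradient of a scalar loss w.r.t. f
numeric_grad <- function(fn, f, h = 1e-5) {
  g <- array(0, dim(f))
  for (i in seq_along(f)) {
    fp <- f; fm <- f
    fp[i] <- fp[i] + h; fm[i] <- fm[i] - h
    g[i] <- (fn(fp) - fn(fm)) / (2 * h)
  }
  g
}

# The reduced-scale phantom benchmark shared by the end-to-end checks:
# 24 cases x 16 slices at 256^2, 12 held-out test cases, 128^2 crops,
# base-8 depth-2 network, 10 epochs of RMSprop(0.001) on the combined loss.
benchmark_env <- new.env()

get_benchmark <- function() {
  if (!is.null(benchmark_env$fit)) return(as.list(benchmark_env))
  seed <- 42L
  cases <- lapply(1:24, function(i)
    generate_phantom_case(phantom_spec(n_slices = 16, slice_size = 256,
                                       seed = seed * 1000L + i)))
  split <- split_dataset(cases, n_test = 12, split = 0.9, seed = seed)
  pre <- preprocess_config(out_size = 128)
  data <- make_training_set(cases, split, pre)
  tcfg <- train_config(seed = seed,
                       model = model_config(base_channels = 8, depth = 2))
  fit <- train_segmentation(tcfg, data)
  benchmark_env$cases <- cases
  benchmark_env$split <- split
  benchmark_env$pre <- pre
  benchmark_env$data <- data
  benchmark_env$fit <- fit
  as.list(benchmark_env)
}
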