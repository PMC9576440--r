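#' Loss configuration
#'
#' Houses the parameters of the three segmentation losses. The combined loss
#' weights the log of the Dice loss against the focal term,
#' `L_all = alpha_combined * log(L_Dice) + L_f`, with `alpha_combined = 0.3`
#' by default. The focal parameters follow the original focal-loss defaults
#' (`focal_alpha = 0.25`, `focal_gamma = 2`); `smooth` stabilizes the Dice
#' ratio and `log_floor` clamps `L_Dice` before the logarithm, which is
#' otherwise unbounded below at perfect overlap.
#'
#' @param alpha_combined weight of the log-Dice term (> 0).
#' @param focal_alpha class-balance weight in (0, 1).
#' @param focal_gamma focusing exponent (>= 0).
#' @param smooth stabilizer added to numerator and denominator of the Dice
#'   ratio (>= 0; must be > 0 when both masks can be empty).
#' @param log_floor lower clamp on L_Dice before taking the logarithm (> 0).
#' @return object of class `loss_config`.
#' @export
loss_config <- function(alpha_combined = 0.3, focal_alpha = 0.25,
                        focal_gamma = 2, smooth = 1, log_floor = 1e-4) {
  check_scalar(alpha_combined, "alpha_combined", lower = 0, open_lower = TRUE)
  check_scalar(focal_alpha, "focal_alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(focal_gamma, "focal_gamma", lower = 0)
  check_scalar(smooth, "smooth", lower = 0)
  check_scalar(log_floor, "log_floor", lower = 0, open_lower = TRUE)
  structure(list(alpha_combined = alpha_combined, focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, smooth = smooth,
                 log_floor = log_floor),
            class = "loss_config")
}

check_loss_inputs <- function(e, f) {
  check_same_shape(e, f, "ground truth and prediction")
  check_binary(e, "ground truth")
  if (any(f < 0 | f > 1))
    stop("prediction values must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Dice loss
#'
#' `1 - (2 * sum(e*f) + smooth) / (sum(e) + sum(f) + smooth)`: 0 at complete
#' overlap, approaching 1 for disjoint nonempty masks as `smooth` goes to 0.
#'
#' @param e binary ground-truth array.
#' @param f predicted probability array in \[0, 1\], same shape as `e`.
#' @param smooth stabilizer (>= 0; with 0 both masks must not be empty).
#' @return scalar loss.
#' @export
dice_loss <- function(e, f, smooth = 1) {
  check_loss_inputs(e, f)
  check_scalar(smooth, "smooth", lower = 0)
  den <- sum(e) + sum(f) + smooth
  if (den == 0)
    stop("dice loss undefined: both masks empty and smooth = 0",
         call. = FALSE)
  1 - (2 * sum(e * f) + smooth) / den
}

#' @rdname dice_loss
#' @return `dice_loss_grad`: array of the same shape, d(loss)/d(f).
#' @export
dice_loss_grad <- function(e, f, smooth = 1) {
  check_loss_inputs(e, f)
  num <- 2 * sum(e * f) + smooth
  den <- sum(e) + sum(f) + smooth
  -2 * e / den + num / den^2
}

#' Focal loss
#'
#' Mean over pixels of the two-branch focal term: for positive pixels
#' `-alpha * (1 - f)^gamma * log(f)`, for negative pixels
#' `-(1 - alpha) * f^gamma * log(1 - f)`. With `gamma = 0`,
#' `alpha = 0.5` this reduces to half the binary cross-entropy.
#'
#' @param e binary ground-truth array.
#' @param f predicted probability array.
#' @param alpha class-balance weight in (0, 1).
#' @param gamma focusing exponent (>= 0).
#' @param eps probability clamp keeping the logs finite.
#' @return scalar loss (mean over pixels).
#' @export
focal_loss <- function(e, f, alpha = 0.25, gamma = 2, eps = 1e-7) {
  check_loss_inputs(e, f)
  f <- clip(f, eps, 1 - eps)
  pos <- -alpha * (1 - f)^gamma * log(f)
  neg <- -(1 - alpha) * f^gamma * log(1 - f)
  mean(e * pos + (1 - e) * neg)
}

#' @rdname focal_loss
#' @export
focal_loss_grad <- function(e, f, alpha = 0.25, gamma = 2, eps = 1e-7) {
  check_loss_inputs(e, f)
  f <- clip(f, eps, 1 - eps)
  # d/df of the positive branch; the gamma = 0 case avoids 0^(-1)
  dpos <- if (gamma == 0) -alpha / f else
    -alpha * (-gamma * (1 - f)^(gamma - 1) * log(f) + (1 - f)^gamma / f)
  dneg <- if (gamma == 0) (1 - alpha) / (1 - f) else
    -(1 - alpha) * (gamma * f^(gamma - 1) * log(1 - f) - f^gamma / (1 - f))
  (e * dpos + (1 - e) * dneg) / length(f)
}

#' Combined log-Dice + focal loss
#'
#' `L_all = alpha_combined * log(max(L_Dice, log_floor)) + L_f`. The
#' logarithm balances the scale of the two terms; the floor keeps the loss
#' finite as the Dice loss approaches 0.
#'
#' @param e binary ground-truth array.
#' @param f predicted probability array.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(e, f, cfg = loss_config()) {
  ld <- dice_loss(e, f, cfg$smooth)
  lf <- focal_loss(e, f, cfg$focal_alpha, cfg$focal_gamma)
  cfg$alpha_combined * log(max(ld, cfg$log_floor)) + lf
}

#' @rdname combined_loss
#' @export
combined_loss_grad <- function(e, f, cfg = loss_config()) {
  ld <- dice_loss(e, f, cfg$smooth)
  g <- focal_loss_grad(e, f, cfg$focal_alpha, cfg$focal_gamma)
  if (ld > cfg$log_floor)
    g <- g + cfg$alpha_combined / ld * dice_loss_grad(e, f, cfg$smooth)
  g
}

# name -> (value, grad) pair used by the training loop
loss_by_name <- function(name, cfg = loss_config()) {
  switch(name,
    dice = list(
      value = function(e, f) dice_loss(e, f, cfg$smooth),
      grad  = function(e, f) dice_loss_grad(e, f, cfg$smooth)),
    focal = list(
      value = function(e, f) focal_loss(e, f, cfg$focal_alpha,
                                        cfg$focal_gamma),
      grad  = function(e, f) focal_loss_grad(e, f, cfg$focal_alpha,
                                             cfg$focal_gamma)),
    combined = list(
      value = function(e, f) combined_loss(e, f, cfg),
      grad  = function(e, f) combined_loss_grad(e, f, cfg)),
    stop_param("loss", "must be one of 'dice', 'focal', 'combined'"))
}
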