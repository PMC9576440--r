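#' Specification of a synthetic pediatric chest phantom
#'
#' Defines the geometry, intensity palette and defect rates of a synthetic
#' chest CT case. The phantom reproduces the three features that make
#' preschool CT hard: a small chest (body ellipse covering well under 20% of
#' the frame), motion streak artifacts, and localized breath-hold lung
#' dropout. Intensities use a fixed HU palette: air -1000, aerated lung -800,
#' soft tissue +40, bone rim +400, table +300 — placed so that body/air/lung
#' contrasts sit where the preprocessing thresholds must discriminate, without
#' claiming anatomical fidelity.
#'
#' @param n_slices number of axial slices (>= 1).
#' @param slice_size pixels per side of each square slice (default 512).
#' @param chest_fraction fraction of the frame covered by the body ellipse;
#'   pediatric chests occupy less than 0.20 of the frame, so the default is
#'   0.18.
#' @param artifact_level streak-artifact amplitude in HU (>= 0; 0 disables).
#' @param dropout_probability per-slice probability of a breath-hold lung
#'   dropout defect, in \[0, 1\].
#' @param noise_sigma standard deviation of additive Gaussian noise in HU.
#' @param seed integer random seed; identical spec + seed yields a
#'   bit-identical phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 12, slice_size = 512,
                         chest_fraction = 0.18, artifact_level = 150,
                         dropout_probability = 0.1, noise_sigma = 15,
                         seed = 1) {
  check_scalar(n_slices, "n_slices", lower = 1, integer = TRUE)
  check_scalar(slice_size, "slice_size", lower = 32, integer = TRUE)
  check_scalar(chest_fraction, "chest_fraction", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(artifact_level, "artifact_level", lower = 0)
  check_scalar(dropout_probability, "dropout_probability", lower = 0, upper = 1)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_slices = as.integer(n_slices),
                 slice_size = as.integer(slice_size),
                 chest_fraction = chest_fraction,
                 artifact_level = artifact_level,
                 dropout_probability = dropout_probability,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# HU palette shared by generator and documentation
.hu <- list(air = -1000, lung = -800, soft = 40, bone = 400, table = 300)

#' Generate a synthetic chest CT case with ground-truth lung masks
#'
#' Builds an axial CT volume containing an air background, a bright table
#' band outside the body, an elliptical soft-tissue body with a bone rim whose
#' area fraction matches `chest_fraction`, and two elliptical lungs whose
#' in-plane size tapers toward apex and base. The pristine ground-truth mask
#' always has exactly two 3D connected lung components. When the spec enables
#' them, streak artifacts and breath-hold dropout defects are then applied
#' (see [add_streak_artifacts()] and [add_breath_hold_dropout()]); every
#' defect is recorded in `defect_log` so tests can audit recovery.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_case`: list with `image` (ct_volume),
#'   `mask` (pristine ground-truth mask_volume), `degraded_mask` (mask with
#'   dropout regions removed, as a lung-appearance-only observer would draw
#'   it), `spec`, and `defect_log` (data.frame with columns slice, kind).
#' @export
generate_phantom_case <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  S <- spec$slice_size
  n <- spec$n_slices
  case <- withr::with_seed(spec$seed, {
    cy <- S * (0.5 + runif(1, -0.02, 0.02))
    cx <- S * (0.5 + runif(1, -0.02, 0.02))
    # body ellipse: area = chest_fraction * S^2, height/width ratio 0.75
    a <- sqrt(spec$chest_fraction * S^2 / (pi * 0.75))  # col semi-axis
    b <- 0.75 * a                                       # row semi-axis

    rr <- matrix(seq_len(S), S, S)
    cc <- matrix(seq_len(S), S, S, byrow = TRUE)
    eb <- ((cc - cx) / a)^2 + ((rr - cy) / b)^2   # body ellipse metric
    body <- eb <= 1
    rim <- eb <= 1 & eb > 0.92^2

    img <- array(.hu$air, c(S, S, n))
    msk <- array(0, c(S, S, n))

    # table: bright band below the body, separated by air
    t0 <- round(S * 0.92)
    t1 <- min(S, t0 + max(3L, S %/% 96))
    tc0 <- round(S * 0.2); tc1 <- round(S * 0.8)

    zc <- (n + 1) / 2
    for (z in seq_len(n)) {
      sl <- matrix(.hu$air, S, S)
      sl[body] <- .hu$soft
      sl[rim] <- .hu$bone
      sl[t0:t1, tc0:tc1] <- .hu$table
      rel <- if (n > 1) (z - zc) / zc else 0
      taper <- sqrt(1 - 0.6 * rel^2)   # in-plane lung scale, apex/base taper
      for (side in c(-1, 1)) {
        lcx <- cx + side * 0.45 * a
        lcy <- cy - 0.03 * b
        lx <- 0.30 * a * taper
        ly <- 0.55 * b * taper
        lung <- ((cc - lcx) / lx)^2 + ((rr - lcy) / ly)^2 <= 1
        sl[lung] <- .hu$lung
        msk[, , z][lung] <- 1
      }
      img[, , z] <- sl
    }
    if (spec$noise_sigma > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))

    id <- sprintf("phantom-%d", spec$seed)
    structure(list(image = ct_volume(img, spacing = c(5, 1, 1) * 512 / S,
                                     case_id = id),
                   mask = mask_volume(msk, case_id = id),
                   degraded_mask = mask_volume(msk, case_id = id),
                   spec = spec,
                   defect_log = data.frame(slice = integer(),
                                           kind = character(),
                                           stringsAsFactors = FALSE)),
              class = "phantom_case")
  })
  if (spec$artifact_level > 0)
    case <- add_streak_artifacts(case, spec$artifact_level,
                                 seed = derive_seed(spec$seed, "streak"))
  if (spec$dropout_probability > 0)
    case <- add_breath_hold_dropout(case, spec$dropout_probability,
                                    seed = derive_seed(spec$seed, "dropout"))
  case
}

#' Superimpose motion streak artifacts on a phantom case
#'
#' Adds oriented linear streaks (rotated line profiles with a narrow Gaussian
#' cross-section) of amplitude `level` HU to a random subset of slices,
#' mimicking the streaking produced by patient motion. The ground-truth mask
#' is untouched; affected slices are appended to the defect log. For a fixed
#' seed the streak pattern is fixed, so the perturbation scales linearly with
#' `level`.
#'
#' @param case a `phantom_case`.
#' @param level streak amplitude in HU (>= 0; 0 returns the case unchanged).
#' @param seed integer seed controlling slice choice and streak geometry.
#' @return the modified `phantom_case`.
#' @export
add_streak_artifacts <- function(case, level, seed = 1) {
  stopifnot(inherits(case, "phantom_case"))
  check_scalar(level, "level", lower = 0)
  if (level == 0) return(case)
  S <- dim(case$image)[1]
  n <- dim(case$image)[3]
  withr::with_seed(as.integer(seed), {
    affected <- which(runif(n) < 0.5)
    if (length(affected) == 0) affected <- sample.int(n, 1)
    rr <- matrix(seq_len(S), S, S)
    cc <- matrix(seq_len(S), S, S, byrow = TRUE)
    for (z in affected) {
      pert <- matrix(0, S, S)
      for (k in seq_len(sample(2:4, 1))) {
        th <- runif(1, 0, pi)
        y0 <- runif(1, 0.3, 0.7) * S
        x0 <- runif(1, 0.3, 0.7) * S
        d <- abs(-(rr - y0) * sin(th) + (cc - x0) * cos(th))
        pert <- pert + exp(-d^2 / (2 * 1.5^2))
      }
      case$image$voxels[, , z] <- case$image$voxels[, , z] + level * pert
      case$defect_log <- rbind(case$defect_log,
                               data.frame(slice = z, kind = "streak",
                                          stringsAsFactors = FALSE))
    }
  })
  case
}

#' Apply breath-hold dropout defects to a phantom case
#'
#' With per-slice probability `p`, raises a contiguous elliptical subregion of
#' one lung toward soft-tissue intensity — emulating the localized loss of
#' aerated-lung appearance when a child fails to hold their breath — and
#' removes that subregion from the *degraded* working mask. The pristine
#' ground-truth mask is left intact, so downstream stages can be scored on
#' their ability to recover the lost area.
#'
#' @param case a `phantom_case`.
#' @param p per-slice dropout probability in \[0, 1\].
#' @param seed integer seed.
#' @return the modified `phantom_case` (image + degraded_mask changed,
#'   `mask` untouched, defect log extended).
#' @export
add_breath_hold_dropout <- function(case, p, seed = 1) {
  stopifnot(inherits(case, "phantom_case"))
  check_scalar(p, "p", lower = 0, upper = 1)
  if (p == 0) return(case)
  S <- dim(case$image)[1]
  n <- dim(case$image)[3]
  withr::with_seed(as.integer(seed), {
    rr <- matrix(seq_len(S), S, S)
    cc <- matrix(seq_len(S), S, S, byrow = TRUE)
    for (z in seq_len(n)) {
      if (runif(1) > p) next
      m <- case$degraded_mask$voxels[, , z]
      if (sum(m) == 0) next
      # pick one lung: split foreground by column median
      cols <- cc[m == 1]
      rows <- rr[m == 1]
      left <- cols < stats::median(cols)
      use <- if (runif(1) < 0.5 && any(left)) left else !left
      if (!any(use)) use <- !use
      ctr_r <- mean(rows[use]); ctr_c <- mean(cols[use])
      ry <- max(3, 0.6 * stats::sd(rows[use]) * 2)
      rx <- max(3, 0.6 * stats::sd(cols[use]) * 2)
      reg <- (((cc - ctr_c) / rx)^2 + ((rr - ctr_r) / ry)^2 <= 1) & m == 1
      case$image$voxels[, , z][reg] <-
        .hu$soft + rnorm(sum(reg), 0, 5)
      m[reg] <- 0
      case$degraded_mask$voxels[, , z] <- m
      case$defect_log <- rbind(case$defect_log,
                               data.frame(slice = z, kind = "dropout",
                                          stringsAsFactors = FALSE))
    }
  })
  case
}

#' Measure the body-pixel fraction of a slice
#'
#' Estimates the fraction of the frame occupied by the body: pixels above
#' `threshold` HU are binarized, opened, and the largest 2D connected
#' component (the body, excluding the table) is measured. Used to verify the
#' small-chest property of generated phantoms.
#'
#' @param slice 2D numeric HU matrix.
#' @param threshold HU threshold separating body from air (default -300).
#' @param opening_radius structuring-element radius in pixels.
#' @return scalar fraction in \[0, 1\].
#' @export
measure_body_fraction <- function(slice, threshold = -300,
                                  opening_radius = 3) {
  bin <- body_binary(slice, threshold, opening_radius)
  lab <- EBImage::bwlabel(bin)
  if (max(lab) == 0) return(0)
  max(tabulate(lab[lab > 0])) / length(slice)
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<phantom_case '%s': %d x %d x %d, %d defects (%s), seed %d>\n",
    x$image$case_id, d[1], d[2], d[3], nrow(x$defect_log),
    paste(unique(x$defect_log$kind), collapse = ","), x$spec$seed))
  invisible(x)
}
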