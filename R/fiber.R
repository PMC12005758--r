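#' Orientation histogram of a fiber image by FFT
#'
#' The image is windowed (raised cosine in both directions), its 2D power
#' spectrum computed, and the power accumulated into angular bins over
#' \[0, 180) degrees. A spatial frequency at angle phi corresponds to
#' stripes (fibers) oriented at phi + 90 degrees, which is the angle
#' recorded. The DC component and the lowest-frequency ring are excluded,
#' as is everything beyond the Nyquist circle; weights are normalized to
#' sum to 1. A constant (or effectively signal-free) image yields a
#' uniform histogram with attribute `low_signal = TRUE`.
#'
#' @param image 2D numeric matrix (grayscale), at least 64 x 64.
#' @param n_bins number of angular bins (>= 18).
#' @param min_freq lowest spatial-frequency radius kept (cycles per
#'   image).
#' @return An object of class `mba_orientation`: data.frame with `angle`
#'   (bin centres, degrees) and `weight` (sums to 1), with attribute
#'   `low_signal`.
#' @export
orientation_histogram <- function(image, n_bins = 90, min_freq = 3) {
  image <- as.matrix(image)
  if (nrow(image) < 64 || ncol(image) < 64)
    stop("image must be at least 64 x 64")
  if (n_bins < 18) stop("n_bins must be >= 18")
  nr <- nrow(image); nc <- ncol(image)
  win <- outer(0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))),
               0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))))
  img <- (image - mean(image)) * win
  P <- Mod(stats::fft(img))^2
  # frequency coordinates, cycles per image: rows = y, cols = x
  ky <- ifelse(seq_len(nr) - 1 <= nr / 2, seq_len(nr) - 1,
               seq_len(nr) - 1 - nr)
  kx <- ifelse(seq_len(nc) - 1 <= nc / 2, seq_len(nc) - 1,
               seq_len(nc) - 1 - nc)
  KY <- matrix(ky, nr, nc)
  KX <- matrix(kx, nr, nc, byrow = TRUE)
  rad <- sqrt(KX^2 + KY^2)
  keep <- rad >= min_freq & rad <= min(nr, nc) / 2
  phi <- atan2(KY, KX) * 180 / pi          # frequency angle
  theta <- (phi + 90) %% 180               # fiber angle
  w <- 180 / n_bins
  bin <- pmin(floor(theta[keep] / w) + 1, n_bins)
  pw <- P[keep]
  weights <- as.numeric(tapply(pw, factor(bin, levels = seq_len(n_bins)),
                               sum))
  weights[is.na(weights)] <- 0
  tot <- sum(weights)
  low_signal <- FALSE
  if (tot <= .Machine$double.eps * max(1, sum(image^2))) {
    weights <- rep(1 / n_bins, n_bins)
    low_signal <- TRUE
  } else {
    weights <- weights / tot
  }
  out <- data.frame(angle = (seq_len(n_bins) - 0.5) * w, weight = weights)
  class(out) <- c("mba_orientation", "data.frame")
  attr(out, "low_signal") <- low_signal
  out
}

# wrapped angular difference on [0, 180): result in [-90, 90)
wrap180 <- function(d) ((d + 90) %% 180) - 90

# circular mean of axial data (angles on [0, 180)) with weights
circular_mean180 <- function(angles, weights) {
  a2 <- angles * pi / 90  # double the angle
  s <- sum(weights * sin(a2)); c <- sum(weights * cos(a2))
  (atan2(s, c) * 90 / pi) %% 180
}

#' Fit the dominant orientation of an angular histogram
#'
#' Least-squares fit of a wrapped Gaussian plus constant offset,
#' w(theta) = A exp(-0.5 d(theta, mu)^2 / sigma^2) + c with d the wrapped
#' angular difference on \[0, 180). Initialised from the axial circular
#' mean. Histograms that are flat, or whose fit explains little variance
#' (R^2 below `min_r2`), are flagged and the circular mean is returned as
#' the fallback location.
#'
#' @param hist an `mba_orientation` histogram.
#' @param min_r2 goodness threshold below which the result is flagged.
#' @return list with `mean_angle` (degrees), `sd_angle` (degrees),
#'   `r_squared` and `flagged`.
#' @export
fit_orientation <- function(hist, min_r2 = 0.2) {
  a <- hist$angle; wts <- hist$weight
  cm <- circular_mean180(a, wts)
  flat <- diff(range(wts)) < 1e-12 || isTRUE(attr(hist, "low_signal"))
  if (flat)
    return(list(mean_angle = cm, sd_angle = NA_real_, r_squared = 0,
                flagged = TRUE))
  # moment-based init for the dispersion
  d0 <- wrap180(a - cm)
  sig0 <- sqrt(sum(wts * d0^2) / sum(wts))
  sig0 <- min(max(sig0, 2), 60)
  obj <- function(p) {
    mu <- p[1]; sig <- exp(p[2]); A <- p[3]; cc <- p[4]
    pred <- A * exp(-0.5 * (wrap180(a - mu) / sig)^2) + cc
    sum((wts - pred)^2)
  }
  p0 <- c(cm, log(sig0), max(wts) - min(wts), min(wts))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- fit$par[1] %% 180
  sig <- exp(fit$par[2])
  ss_res <- fit$value
  ss_tot <- sum((wts - mean(wts))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  flagged <- !is.finite(r2) || r2 < min_r2
  if (flagged) mu <- cm
  list(mean_angle = mu, sd_angle = sig, r_squared = r2, flagged = flagged)
}
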