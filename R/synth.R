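# ---------------------------------------------------------------------------
# Synthetic dermoscopy lesion generator. Emulates the features that make
# dermoscopic segmentation hard: irregular star-convex lesions with
# Fourier-perturbed boundaries, adjustable lesion/skin contrast with a
# Gaussian-blurred (fuzzy) border, dark hair-like Bezier strokes occluding
# both lesion and skin (never added to the mask), and additive pixel noise.
# ---------------------------------------------------------------------------

#' Generator parameters
#'
#' @param canvas Integer (h, w), at least 64 pixels on each side.
#' @param n_blobs Number of lesion blobs (union forms the mask).
#' @param contrast Lesion/skin intensity gap in (0, 1].
#' @param hair_strokes Number of occluding hair strokes.
#' @param noise_sigma Additive Gaussian noise sd on the `[0,1]` scale.
#' @param seed Integer seed; identical parameters give a bit-identical
#'   sample.
#' @return Parameter list for [make_synthetic()].
#' @export
synth_params <- function(canvas = c(96L, 96L), n_blobs = 1L, contrast = 0.45,
                         hair_strokes = 0L, noise_sigma = 10 / 255,
                         seed = 1L) {
  stopifnot(n_blobs >= 1L, contrast > 0, contrast <= 1, hair_strokes >= 0L,
            noise_sigma >= 0)
  list(canvas = as.integer(canvas), n_blobs = as.integer(n_blobs),
       contrast = contrast, hair_strokes = as.integer(hair_strokes),
       noise_sigma = noise_sigma, seed = as.integer(seed))
}

# star-convex blob: radius r(theta) = r0 * (1 + sum_j a_j cos(j theta + phi_j))
render_blob <- function(H, W, cy, cx, r0, ecc, rot) {
  amp <- stats::rnorm(4, 0, 0.07)
  phs <- stats::runif(4, 0, 2 * pi)
  hh <- matrix(seq_len(H), H, W) - cy
  ww <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # rotated elliptical coordinates
  u <- cos(rot) * hh + sin(rot) * ww
  v <- -sin(rot) * hh + cos(rot) * ww
  dist <- sqrt((u / 1)^2 + (v / ecc)^2)
  theta <- atan2(v, u)
  rtheta <- r0
  for (j in 1:4) rtheta <- rtheta + r0 * amp[j] * cos((j + 1) * theta + phs[j])
  (dist <= rtheta) * 1
}

#' Generate one synthetic dermoscopy sample
#'
#' @param p Parameters from [synth_params()].
#' @return Sample list (`id`, `image` in 8-bit quantized `[0,1]`, binary
#'   `mask`); the lesion is fully interior to the canvas by construction.
#' @export
make_synthetic <- function(p) {
  H <- p$canvas[1]; W <- p$canvas[2]
  if (H < 64L || W < 64L) {
    stop("canvas must be at least 64 pixels per side, got ", H, "x", W)
  }
  with_seed(p$seed, {
    # skin background: warm base tone with a mild oriented gradient
    base <- c(0.80, 0.62, 0.54) * stats::runif(1, 0.9, 1.05)
    ang <- stats::runif(1, 0, 2 * pi)
    gh <- matrix(seq(-1, 1, length.out = H), H, W)
    gw <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    grad <- 0.05 * (cos(ang) * gh + sin(ang) * gw)
    img <- array(0, dim = c(H, W, 3))
    for (c in 1:3) img[, , c] <- base[c] + grad
    bg <- img

    # lesion blobs, centred well inside the canvas
    mask <- matrix(0, H, W)
    rmin <- 0.08 * min(H, W)
    rmax <- 0.24 * min(H, W)
    for (b in seq_len(p$n_blobs)) {
      r0 <- stats::runif(1, rmin, rmax)
      cy <- stats::runif(1, 0.35 * H, 0.65 * H)
      cx <- stats::runif(1, 0.35 * W, 0.65 * W)
      ecc <- stats::runif(1, 0.6, 1)
      rot <- stats::runif(1, 0, pi)
      mask <- pmax(mask, render_blob(H, W, cy, cx, r0, ecc, rot))
    }

    # fuzzy border: composite the darker lesion tone through a blurred alpha
    alpha <- cpp_gauss_blur(mask, 2.5)
    shade <- c(1, 0.82, 0.72) # lesions skew brown
    for (c in 1:3) {
      lesion_tone <- bg[, , c] * (1 - p$contrast) * shade[c]
      img[, , c] <- bg[, , c] * (1 - alpha) + lesion_tone * alpha
    }

    # hair-like occluders: dark quadratic Bezier strokes, not in the mask
    if (p$hair_strokes > 0L) {
      tt <- seq(0, 1, length.out = 4L * max(H, W))
      for (s in seq_len(p$hair_strokes)) {
        pt <- cbind(stats::runif(3, 1, H), stats::runif(3, 1, W))
        hy <- (1 - tt)^2 * pt[1, 1] + 2 * tt * (1 - tt) * pt[2, 1] + tt^2 * pt[3, 1]
        hx <- (1 - tt)^2 * pt[1, 2] + 2 * tt * (1 - tt) * pt[2, 2] + tt^2 * pt[3, 2]
        iy <- pmin(H, pmax(1, round(hy)))
        ix <- pmin(W, pmax(1, round(hx)))
        dark <- stats::runif(1, 0.05, 0.25)
        for (c in 1:3) {
          plane <- img[, , c]
          plane[cbind(iy, ix)] <- dark
          img[, , c] <- plane
        }
      }
    }

    if (p$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, p$noise_sigma)
    }
    img[] <- pmin(1, pmax(0, img))
    img[] <- round(img * 255) / 255 # 8-bit quantization
    list(id = sprintf("synth_%08d", p$seed), image = img, mask = mask)
  })
}

#' Generate a synthetic dataset
#'
#' Roughly half the samples are "hard" (low lesion/skin contrast or heavy
#' hair occlusion); the rest are easier high-contrast lesions. Blob radii
#' span a wide range so mask areas vary by more than an order of magnitude.
#'
#' @param n Number of samples.
#' @param seed Integer seed for the whole set.
#' @param canvas Canvas size passed to every sample.
#' @param noise_sigma Additive noise level.
#' @return List of `n` samples with distinct ids.
#' @export
make_synthetic_dataset <- function(n, seed = 1L, canvas = c(96L, 96L),
                                   noise_sigma = 10 / 255) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    hard <- rep_len(c(FALSE, TRUE), n)
    lapply(seq_len(n), function(i) {
      if (hard[i]) {
        contrast <- stats::runif(1, 0.08, 0.25)
        hair <- sample(0:5, 1)
      } else {
        contrast <- stats::runif(1, 0.35, 0.7)
        hair <- sample(0:2, 1)
      }
      p <- synth_params(canvas = canvas, n_blobs = sample(1:3, 1),
                        contrast = contrast, hair_strokes = hair,
                        noise_sigma = noise_sigma, seed = seeds[i])
      s <- make_synthetic(p)
      s$id <- sprintf("synth_%03d_%08d", i, seeds[i])
      s
    })
  })
}

#' Write a dataset to ISIC-style folders
#'
#' @param samples List of samples.
#' @param out_dir Output directory; `images/` and `masks/` are created.
#' @return Invisibly, the manifest tibble (id and file paths).
#' @export
write_dataset <- function(samples, out_dir) {
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    ip <- file.path(img_dir, paste0(s$id, ".png"))
    mp <- file.path(msk_dir, paste0(s$id, ".png"))
    png::writePNG(s$image, ip)
    png::writePNG(s$mask, mp)
    tibble::tibble(id = s$id, image_path = ip, mask_path = mp)
  })
  invisible(do.call(rbind, rows))
}
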