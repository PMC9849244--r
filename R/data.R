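# ---------------------------------------------------------------------------
# ISIC-style dataset I/O, the seeded augmentation policy and k-fold
# splitting. A sample is a plain list: id (string stem), image (h x w x 3
# double array in [0,1]) and mask (h x w binary matrix).
# ---------------------------------------------------------------------------

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = ,
                jpeg = jpeg::readJPEG(path),
                stop("unsupported image format '", ext, "' for ", path))
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  img[, , 1:3, drop = FALSE]
}

read_mask_file <- function(path) {
  m <- read_image_file(path)
  m <- m[, , 1]
  # any gray value >= 128/255 counts as lesion
  (m >= 128 / 255) * 1
}

resize_image <- function(img, hw) {
  d <- dim(img)
  if (all(d[1:2] == hw)) return(img)
  x <- img
  dim(x) <- c(d[1], d[2], d[3], 1L)
  out <- cpp_resize_bilinear_fw(x, hw[1], hw[2])
  dim(out) <- c(hw[1], hw[2], d[3])
  out
}

resize_mask <- function(mask, hw) {
  d <- dim(mask)
  if (all(d == hw)) return(mask)
  x <- mask + 0
  dim(x) <- c(d[1], d[2], 1L, 1L)
  out <- cpp_resize_nearest(x, hw[1], hw[2])
  matrix(out, hw[1], hw[2])
}

#' Load an ISIC-style image/mask folder pair
#'
#' Images and masks are matched by file stem; images are bilinearly resized
#' and masks nearest-neighbour resized (then re-thresholded at gray 128) so
#' masks stay strictly binary. Samples are returned in sorted-stem order.
#'
#' @param image_dir Directory of PNG/JPEG images.
#' @param mask_dir Directory of single-channel PNG masks with matching stems.
#' @param resize Target (h, w); use `NULL` to keep native sizes.
#' @return List of samples (`id`, `image`, `mask`).
#' @export
load_dataset <- function(image_dir, mask_dir, resize = c(512L, 512L)) {
  imgs <- sort(list.files(image_dir, pattern = "\\.(png|jpe?g)$",
                          ignore.case = TRUE))
  msks <- sort(list.files(mask_dir, pattern = "\\.(png|jpe?g)$",
                          ignore.case = TRUE))
  if (length(imgs) == 0L) {
    warning("no images found in ", image_dir)
    return(list())
  }
  istem <- tools::file_path_sans_ext(imgs)
  mstem <- tools::file_path_sans_ext(msks)
  orphans <- c(setdiff(istem, mstem), setdiff(mstem, istem))
  if (length(orphans) > 0L) {
    stop("unmatched image/mask stems: ", paste(orphans, collapse = ", "))
  }
  lapply(seq_along(imgs), function(i) {
    img <- read_image_file(file.path(image_dir, imgs[i]))
    msk <- read_mask_file(file.path(mask_dir, msks[match(istem[i], mstem)]))
    if (!identical(dim(img)[1:2], dim(msk))) {
      stop("image and mask sizes differ for stem ", istem[i])
    }
    if (!is.null(resize)) {
      img <- resize_image(img, resize)
      msk <- resize_mask(msk, resize)
    }
    list(id = istem[i], image = img, mask = msk)
  })
}

#' Draw a seeded augmentation plan
#'
#' Each of the four transforms (vertical flip, horizontal flip, rotation,
#' Gaussian noise) fires independently with probability `p`; the rotation
#' angle is uniform on `[-rot_range, rot_range]` degrees.
#'
#' @param seed Integer seed.
#' @param p Per-transform probability.
#' @param rot_range Rotation half-range in degrees.
#' @return List of gates and the drawn angle.
#' @export
draw_augment_plan <- function(seed, p = 0.5, rot_range = 90) {
  with_seed(seed, {
    gates <- stats::runif(4) < p
    list(vflip = gates[1], hflip = gates[2], rotate = gates[3],
         noise = gates[4],
         angle = stats::runif(1, -rot_range, rot_range))
  })
}

rotate_plane <- function(m, angle) cpp_rotate_nearest(m, angle)

#' Augment one sample
#'
#' Geometric transforms (flips, rotation) are applied identically to image
#' and mask; rotation uses nearest-neighbour sampling for both so the pair
#' stays locked and the mask stays binary. Noise perturbs the image only.
#'
#' @param s Sample list (`id`, `image`, `mask`).
#' @param seed Integer seed; the whole augmentation is reproducible from it.
#' @param p Per-transform probability.
#' @param rot_range Rotation half-range in degrees.
#' @param noise_sd Gaussian noise standard deviation on the `[0,1]` scale.
#' @return Augmented sample.
#' @export
augment <- function(s, seed, p = 0.5, rot_range = 90, noise_sd = 10 / 255) {
  plan <- draw_augment_plan(seed, p, rot_range)
  img <- s$image
  msk <- s$mask
  if (plan$vflip) {
    img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  if (plan$hflip) {
    img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (plan$rotate) {
    for (c in 1:3) img[, , c] <- rotate_plane(img[, , c], plan$angle)
    msk <- rotate_plane(msk, plan$angle)
  }
  if (plan$noise) {
    noise <- with_seed(seed + 1L, stats::rnorm(length(img), 0, noise_sd))
    img[] <- pmin(1, pmax(0, img + noise))
  }
  list(id = s$id, image = img, mask = msk)
}

#' Seeded k-fold split
#'
#' Ids are shuffled once and dealt round-robin, so validation folds are
#' disjoint, cover every id and differ in size by at most one.
#'
#' @param ids Character vector of sample ids.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` lists with fields `train` and `val`.
#' @export
kfold_split <- function(ids, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > length(ids)) stop("k = ", k, " exceeds the ", length(ids),
                            " available ids")
  perm <- with_seed(seed, sample(ids))
  fold <- rep_len(seq_len(k), length(ids))
  lapply(seq_len(k), function(f) {
    list(train = sort(perm[fold != f]), val = sort(perm[fold == f]))
  })
}

#' Fold manifest as a tibble
#'
#' @param splits Result of [kfold_split()].
#' @return Tibble with columns `id` and `fold` (the validation fold of each
#'   id).
#' @export
fold_manifest <- function(splits) {
  rows <- lapply(seq_along(splits), function(f) {
    tibble::tibble(id = splits[[f]]$val, fold = f)
  })
  out <- do.call(rbind, rows)
  out[order(out$id), ]
}
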