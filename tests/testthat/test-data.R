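test_that("folder loading matches stems, resizes and binarizes masks", {
  dir <- withr::local_tempdir()
  ds <- make_synthetic_dataset(3, seed = 9, canvas = c(64L, 64L))
  write_dataset(ds, dir)
  loaded <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                         resize = c(96L, 96L))
  expect_length(loaded, 3L)
  for (s in loaded) {
    expect_identical(dim(s$image), c(96L, 96L, 3L))
    expect_identical(dim(s$mask), c(96L, 96L))
    expect_true(all(s$mask %in% c(0, 1)))
  }
  expect_identical(vapply(loaded, `[[`, "", "id"),
                   sort(vapply(ds, `[[`, "", "id")))
  # a gray {0,255}-style mask binarizes at the 128 threshold
  png::writePNG(matrix(c(0, 1, 0.6, 0.4), 2, 2), file.path(dir, "gray.png"))
  m <- ns$read_mask_file(file.path(dir, "gray.png"))
  expect_identical(as.vector(m), c(0, 1, 1, 0))
  # orphan stems are an error listing the culprit
  png::writePNG(ds[[1]]$image, file.path(dir, "images", "orphan.png"))
  expect_error(load_dataset(file.path(dir, "images"), file.path(dir, "masks")),
               "orphan")
  empty <- file.path(dir, "none")
  dir.create(empty)
  expect_warning(out <- load_dataset(empty, empty), "no images")
  expect_length(out, 0L)
})

test_that("augmentation is reproducible and the pair stays locked", {
  s <- make_synthetic(synth_params(canvas = c(64L, 64L), seed = 3L))
  a1 <- augment(s, seed = 123L)
  a2 <- augment(s, seed = 123L)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% c(0, 1)))
  # a sample whose image equals its mask stays equal under the geometric
  # transforms (noise disabled), for many seeds
  m <- s$mask
  twin <- list(id = "t", image = array(rep(m, 3), c(dim(m), 3L)), mask = m)
  for (seed in 1:20) {
    a <- augment(twin, seed = seed, noise_sd = 0)
    plan <- draw_augment_plan(seed)
    if (!plan$noise) {
      for (c in 1:3) expect_identical(a$image[, , c], a$mask + 0)
    }
  }
})

test_that("a double vertical flip is the identity", {
  s <- make_synthetic(synth_params(canvas = c(64L, 64L), seed = 4L))
  # find a seed whose plan is vflip only
  seed <- NULL
  for (cand in 1:500) {
    p <- draw_augment_plan(cand)
    if (p$vflip && !p$hflip && !p$rotate && !p$noise) { seed <- cand; break }
  }
  expect_false(is.null(seed))
  once <- augment(s, seed)
  twice <- augment(once, seed)
  expect_identical(twice$image, s$image)
  expect_identical(twice$mask, s$mask)
})

test_that("each transform fires at its configured rate over 10,000 draws", {
  gates <- vapply(1:10000, function(seed) {
    p <- draw_augment_plan(seed)
    c(p$vflip, p$hflip, p$rotate, p$noise)
  }, logical(4))
  freq <- rowMeans(gates)
  expect_true(all(abs(freq - 0.5) < 0.02))
  angles <- vapply(1:1000, function(s) draw_augment_plan(s)$angle, numeric(1))
  expect_true(all(angles >= -90 & angles <= 90))
})

test_that("k-fold splits are balanced, disjoint, covering and seeded", {
  ids <- sprintf("id%02d", 1:10)
  sp <- kfold_split(ids, 5, seed = 2)
  expect_length(sp, 5L)
  vals <- lapply(sp, `[[`, "val")
  expect_true(all(lengths(vals) == 2L))
  expect_setequal(unlist(vals), ids)
  expect_identical(sum(duplicated(unlist(vals))), 0L)
  for (f in sp) expect_length(intersect(f$train, f$val), 0L)
  expect_identical(kfold_split(ids, 5, seed = 2), sp)
  expect_false(identical(kfold_split(ids, 5, seed = 3), sp))
  expect_error(kfold_split(ids, 11, seed = 1), "exceeds")
  expect_error(kfold_split(ids, 1, seed = 1), "at least 2")
  mf <- fold_manifest(sp)
  expect_identical(nrow(mf), 10L)
  expect_setequal(mf$fold, 1:5)
})
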