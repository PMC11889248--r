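test_that("image generation is bitwise deterministic in (spec, label, seed)", {
  spec <- synthetic_image_spec()
  a <- generate_cell_image(spec, 1, seed = 99)
  b <- generate_cell_image(spec, 1, seed = 99)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$geometry, b$geometry)
  c <- generate_cell_image(spec, 1, seed = 100)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("labels agree with the recorded geometry", {
  spec <- synthetic_image_spec()
  neg <- generate_cell_image(spec, 0, seed = 3)
  expect_equal(neg$geometry$n_micronuclei, 0L)
  pos <- generate_cell_image(spec, 1, seed = 3)
  expect_gte(pos$geometry$n_micronuclei, 1L)
  expect_equal(nrow(pos$geometry$micronuclei), pos$geometry$n_micronuclei)
})

test_that("noise-free, blur-free rendering matches the geometric masks exactly", {
  spec <- synthetic_image_spec(noise_sd = 0, blur_sd = 0)
  for (seed in c(7, 8, 9)) {
    s <- generate_cell_image(spec, 1, seed = seed)
    mask <- nucleus_mask(s$geometry, spec$side)
    # carve out micronucleus disks that could overwrite nucleus pixels
    g <- s$geometry
    side <- spec$side
    xs <- matrix(rep(seq_len(side), each = side), side)
    ys <- matrix(rep(seq_len(side), times = side), side)
    mn_mask <- matrix(FALSE, side, side)
    for (i in seq_len(g$n_micronuclei)) {
      m <- g$micronuclei[i, ]
      mn_mask <- mn_mask | ((xs - m$cx)^2 + (ys - m$cy)^2 <= m$r^2)
    }
    plane <- s$pixels[, , 1]
    expect_true(all(plane[mask & !mn_mask] == g$nucleus$intensity))
    expect_true(all(plane[mn_mask] == g$micronuclei$intensity[1]))
    expect_true(all(plane[!mask & !mn_mask] == g$background))
    # nucleus brighter than background
    expect_gt(mean(plane[mask]), mean(plane[!mask]))
  }
})

test_that("micronuclei stay strictly outside the nucleus and inside the frame", {
  spec <- synthetic_image_spec()
  for (seed in 1:30) {
    g <- generate_cell_image(spec, 1, seed = seed, render = FALSE)$geometry
    for (i in seq_len(g$n_micronuclei)) {
      m <- g$micronuclei[i, ]
      expect_true(m$cx - m$r >= 1 && m$cx + m$r <= spec$side)
      expect_true(m$cy - m$r >= 1 && m$cy + m$r <= spec$side)
      expect_lt(m$r, g$nucleus$b)
      # centre farther from the nucleus centre than the boundary radius
      phi <- atan2(m$cy - g$nucleus$cy, m$cx - g$nucleus$cx)
      psi <- phi - g$nucleus$theta
      rb <- g$nucleus$a * g$nucleus$b /
        sqrt((g$nucleus$b * cos(psi))^2 + (g$nucleus$a * sin(psi))^2)
      d <- sqrt((m$cx - g$nucleus$cx)^2 + (m$cy - g$nucleus$cy)^2)
      expect_gt(d - m$r, rb)
    }
  }
})

test_that("an unsatisfiable placement ring raises a spec error", {
  spec <- synthetic_image_spec(side = 24, nucleus_axis = c(0.45, 0.5),
                               mn_ring = c(2.5, 3))
  expect_error(generate_cell_image(spec, 1, seed = 1), "spec error")
})

test_that("dataset composition, determinism and manifest bookkeeping", {
  ds <- generate_dataset(200, 0.065, synthetic_image_spec(), seed = 5)
  expect_equal(sum(ds$manifest$label == 1), 13L)
  expect_equal(sum(ds$manifest$label == 0), 187L)
  ds2 <- generate_dataset(200, 0.065, synthetic_image_spec(), seed = 5)
  expect_identical(ds$manifest, ds2$manifest)
  ds3 <- generate_dataset(100, 0.5, synthetic_image_spec(), seed = 6)
  expect_equal(as.vector(table(ds3$manifest$label)), c(50L, 50L))
  expect_error(generate_dataset(1, 0.5), "at least 2")
  expect_error(generate_dataset(10, 1.5), "strictly inside")
  # on-disk round trip through PNG
  dir <- file.path(tempdir(), "synthds")
  dir.create(dir, showWarnings = FALSE)
  ds4 <- generate_dataset(4, 0.5, synthetic_image_spec(side = 32), seed = 7,
                          dir = dir)
  expect_true(all(file.exists(ds4$manifest$path)))
  rt <- png::readPNG(ds4$manifest$path[1])
  expect_equal(dim(rt), c(32, 32, 3))
  # PNG quantizes to 8 bits
  expect_lt(max(abs(rt - ds4$samples[[1]]$pixels)), 1 / 255)
})

test_that("a trivial blob-count heuristic separates easy-mode images", {
  ds <- tiny_dataset(120, 0.5, seed = 77, mode = "easy")
  pred <- vapply(ds$samples, blob_count_classifier, 0L)
  expect_gt(balanced_accuracy(ds$manifest$label, pred), 0.9)
})

test_that("nucleus areas follow the spec's sampling distribution", {
  spec <- synthetic_image_spec()
  areas <- vapply(1:1000, function(s)
    with(generate_cell_image(spec, 0, seed = s, render = FALSE)$geometry$nucleus,
         pi * a * b), 0)
  # independent reference draw straight from the stated distribution
  set.seed(123456)
  f <- runif(40000, spec$nucleus_axis[1], spec$nucleus_axis[2]) * spec$side
  r <- runif(40000, spec$nucleus_aspect[1], spec$nucleus_aspect[2])
  ref <- pi * f * f * r
  ks <- suppressWarnings(stats::ks.test(areas, ref))
  expect_gt(ks$p.value, 0.01)
})
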