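test_that("gabor features are zero for empty input and have fixed length", {
  enc <- default_encoder()
  z <- gabor_encode(matrix(0, 50, 50), enc)
  expect_length(z, 100)   # 4 filters x 5 x 5 pooling cells
  expect_equal(z, rep(0, 100))
  expect_length(gabor_encode(matrix(runif(2500), 50), enc), 100)
  expect_error(gabor_encode(matrix(0, 40, 40), enc),
               class = "chord_dimension_error")
})

test_that("a vertical bar excites the vertical-structure filters most", {
  enc <- default_encoder()
  patch <- matrix(0, 50, 50); patch[, 24:27] <- 1
  f <- gabor_encode(patch, enc)
  # per scale: first 25 entries are orientation 0 (vertical structure)
  for (s in 0:1) {
    vert <- sum(f[s * 50 + 1:25]); horiz <- sum(f[s * 50 + 26:50])
    expect_gt(vert, horiz)
  }
  # and the transpose excites the horizontal-structure filters
  f2 <- gabor_encode(t(patch), enc)
  expect_gt(sum(f2[26:50]), sum(f2[1:25]))
})

test_that("separable gabor filtering agrees with a dense convolution oracle", {
  enc <- default_encoder()
  set.seed(8)
  patch <- matrix(runif(2500), 50)
  bank <- enc$gabor[[2]]                 # 10 px scale
  filtered <- bank$env %*% patch %*% t(bank$even)
  # oracle: direct dense 2-D cross-correlation with the outer-product kernel
  taps_env <- bank$env[25, ]; taps_even <- bank$even[25, ]
  r_env <- which(taps_env > 0); r_evn <- which(taps_even != 0)
  K <- outer(taps_env[r_env], taps_even[r_evn])
  off_r <- r_env - 25; off_c <- r_evn - 25
  for (pt in list(c(25, 25), c(10, 40), c(48, 3))) {
    acc <- 0
    for (a in seq_along(off_r)) for (b in seq_along(off_c)) {
      rr <- pt[1] + off_r[a]; cc <- pt[2] + off_c[b]
      if (rr >= 1 && rr <= 50 && cc >= 1 && cc <= 50)
        acc <- acc + K[a, b] * patch[rr, cc]
    }
    expect_equal(filtered[pt[1], pt[2]], acc, tolerance = 1e-10)
  }
})

test_that("roi detection recovers generator placements within three pixels", {
  cfg <- default_cfg(); enc <- default_encoder()
  sc <- fixture_scene(seed = 7, centers = rbind(c(40, 75), c(110, 75)))
  det <- detect_rois(sc, enc, 2)
  ctrs <- do.call(rbind, lapply(det, `[[`, "center"))
  err1 <- min(sqrt(rowSums(sweep(ctrs, 2, c(40, 75))^2)))
  err2 <- min(sqrt(rowSums(sweep(ctrs, 2, c(110, 75))^2)))
  expect_lte(err1, 3); expect_lte(err2, 3)
  # detections come with in-bounds patches of the right size
  for (d in det) expect_equal(dim(d$patch), c(50, 50))
  # bulk check over random scenes
  set.seed(21)
  fam <- cfg$object_categories
  err <- replicate(500, {
    objs <- list(object_spec(sample(fam, 1), sample.int(1e8, 1)),
                 object_spec(sample(fam, 1), sample.int(1e8, 1)))
    disp <- c(sample(52:100, 1), sample(-35:35, 1))
    sp <- chordscene:::.place_with_displacement(objs, disp, cfg, id = "t")
    sc <- make_scene(sp, cfg)
    ctrs <- do.call(rbind, lapply(detect_rois(sc, enc, 2), `[[`, "center"))
    max(min(sqrt(rowSums(sweep(ctrs, 2, sp$centers[1, ])^2))),
        min(sqrt(rowSums(sweep(ctrs, 2, sp$centers[2, ])^2))))
  })
  expect_gte(mean(err <= 3), 0.99)
})

test_that("detection fails cleanly on empty or single-object scenes", {
  enc <- default_encoder()
  expect_error(detect_rois(matrix(0, 150, 150), enc),
               class = "chord_detection_error")
  one <- matrix(0, 150, 150)
  one[51:100, 51:100] <- make_object(object_spec("ellipse", 3))
  det <- detect_rois(one, enc, n_rois = 1)
  expect_equal(length(det), 1)
  expect_lte(sqrt(sum((det[[1]]$center - c(75, 75))^2)), 3)
  expect_error(detect_rois(one, enc, n_rois = 2),
               class = "chord_detection_error")
})

test_that("roi encoding reduces to ten dimensions and keeps nearest prototypes", {
  enc <- default_encoder()
  patch <- make_object(object_spec("ellipse", 99))
  ct <- encode_roi(patch, enc, mode = "ct")
  expect_length(ct, 10)
  expect_length(encode_roi(patch, enc, mode = "raw"), 100)
  # the head of the rod code is the brute-force nearest prototype
  g <- gabor_encode(patch, enc)
  d <- sqrt(colSums((t(enc$shape_prototypes$prototypes) - g)^2))
  expect_equal(which.min(ct), which.min(d))
  expect_equal(order(ct), order(d))
})

test_that("layout prototypes form mirrored grids around an identical key patch", {
  enc <- default_encoder()
  top <- build_layout_prototypes("top", enc)
  bottom <- build_layout_prototypes("bottom", enc)
  expect_equal(nrow(top$offsets), 10)
  expect_equal(unname(as.matrix(top$offsets)), unname(-as.matrix(bottom$offsets)))
  # key patch pixels (centre region, away from all grid offsets) identical
  ctr_win <- 66:85
  key_ref <- top$images[[1]][ctr_win, ctr_win]
  scale <- default_cfg()$layout_render_scale
  for (k in seq_len(10)) for (fx in list(top, bottom)) {
    img <- fx$images[[k]]
    expect_equal(img[ctr_win, ctr_win], key_ref, tolerance = 1e-8)
    # exactly two gaussian patches: bright pixels only near the two centres
    key_c <- c(75.5, 75.5)
    oth_c <- key_c + as.numeric(fx$offsets[k, ]) * scale
    bright <- which(img > 0.5, arr.ind = TRUE)
    d_key <- sqrt(rowSums(sweep(bright, 2, key_c)^2))
    d_oth <- sqrt(rowSums(sweep(bright, 2, oth_c)^2))
    expect_true(all(pmin(d_key, d_oth) < 13))        # no third patch
    expect_true(any(d_key < 3) && any(d_oth < 3))    # both patches present
  }
})

test_that("layout codes are self-zero on the grid and grow away from it", {
  enc <- default_encoder()
  offs <- enc$layout_offsets$top
  for (j in c(1, 5, 10)) {
    code <- encode_layout(c(40, 75), c(40, 75) + offs[j, ], "top", enc)
    expect_length(code, 10)
    expect_equal(code[j], 0)
    expect_true(all(code >= 0))
  }
  # moving away from prototype j along its grid row: entry j non-decreasing
  j <- which(offs[, "row"] == 52 & offs[, "col"] == -25)
  entry <- vapply(seq(52, 100, by = 4), function(r)
    encode_layout(c(30, 75), c(30 + r, 50), "top", enc)[j], numeric(1))
  expect_true(all(diff(entry) >= -1e-9))
  expect_error(encode_layout(c(40, 75), c(40, 400), "top", enc),
               class = "chord_layout_error")
})

test_that("scene representations concatenate 10 + 10 + 10 dimensions", {
  enc <- default_encoder()
  sc <- fixture_scene(seed = 3)
  rep <- encode_scene(sc, "top", enc, mode = "ct")
  expect_length(rep$fix_code, 10)
  expect_length(rep$other_code, 10)
  expect_length(rep$layout_code, 10)
  expect_length(rep_as_row(rep), 30)
  raw <- encode_scene(sc, "top", enc, mode = "raw")
  expect_length(raw$fix_code, 100)
  expect_length(raw$layout_code, 10)
})

test_that("switching fixation swaps the roi components and mirrors the layout", {
  enc <- default_encoder()
  sc <- fixture_scene(seed = 4)
  both <- chordscene:::encode_scene_full(sc, enc)
  expect_equal(both$top$fix_code, both$bottom$other_code)
  expect_equal(both$top$other_code, both$bottom$fix_code)
  # displacement seen from the two fixations is negated
  expect_equal(both$top$centers["other", ] - both$top$centers["key", ],
               -(both$bottom$centers["other", ] - both$bottom$centers["key", ]))
})

test_that("encoding is deterministic and translation leaves the layout code
           unchanged", {
  enc <- default_encoder()
  sc <- fixture_scene(seed = 5, centers = rbind(c(45, 70), c(100, 80)))
  r1 <- encode_scene(sc, "top", enc)
  r2 <- encode_scene(sc, "top", enc)
  expect_identical(r1, r2)
  shifted <- make_transformed_scene(sc$spec, "T", translation = c(12, -9),
                                    config = default_cfg())
  r3 <- encode_scene(shifted, "top", enc)
  expect_equal(r1$layout_code, r3$layout_code)
  expect_equal(r1$fix_code, r3$fix_code)
})
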