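test_that("object rendering is seeded, bounded and non-empty", {
  sp <- object_spec("annulus", 31L)
  p1 <- make_object(sp); p2 <- make_object(sp)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(50, 50))
  expect_gte(min(p1), 0); expect_lte(max(p1), 1); expect_gt(max(p1), 0)
  # pixels sit on the 8-bit grid so PNG round trips are exact
  expect_equal(p1, round(p1 * 255) / 255)
  expect_error(object_spec("dodecahedron", 1), class = "chord_config_error")
})

test_that("families are coherent: within-category distances below between", {
  enc <- default_encoder()
  cfg <- default_cfg()
  fam <- cfg$object_categories[1:6]
  set.seed(17)
  feats <- list()
  for (categ in fam)
    feats[[categ]] <- t(vapply(1:50, function(i)
      gabor_encode(make_object(object_spec(categ, sample.int(1e8, 1))), enc),
      numeric(100)))
  X <- do.call(rbind, feats)
  lab <- rep(fam, each = 50)
  D <- as.matrix(dist(X))
  same <- outer(lab, lab, "==") & upper.tri(D)
  betw <- !outer(lab, lab, "==") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[betw]))
})

test_that("categories are separable in gabor-chorus space (silhouette > 0)", {
  enc <- default_encoder()
  cfg <- default_cfg()
  fam <- cfg$object_categories[1:6]
  set.seed(18)
  codes <- do.call(rbind, lapply(fam, function(categ)
    t(vapply(1:50, function(i)
      encode_roi(make_object(object_spec(categ, sample.int(1e8, 1))), enc),
      numeric(10)))))
  lab <- rep(seq_along(fam), each = 50)
  D <- as.matrix(dist(codes))
  sil <- vapply(seq_len(nrow(D)), function(i) {
    a <- mean(D[i, setdiff(which(lab == lab[i]), i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(D[i, lab == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("scenes place two patches on an otherwise black background", {
  cfg <- default_cfg()
  sc <- fixture_scene(seed = 11, centers = rbind(c(40, 75), c(110, 75)))
  expect_equal(dim(sc$pixels), c(150, 150))
  mask <- matrix(TRUE, 150, 150)
  for (i in 1:2) {
    ctr <- sc$centers[i, ]
    mask[(ctr[1] - 24):(ctr[1] + 25), (ctr[2] - 24):(ctr[2] + 25)] <- FALSE
  }
  expect_equal(sum(sc$pixels[mask]), 0)
  # invalid placements are rejected
  objs <- list(object_spec("ellipse", 1), object_spec("ellipse", 2))
  expect_error(make_scene(scene_spec(objs, rbind(c(10, 75), c(110, 75))), cfg),
               class = "chord_config_error")   # out of bounds
  expect_error(make_scene(scene_spec(objs, rbind(c(60, 75), c(80, 80))), cfg),
               class = "chord_config_error")   # overlapping boxes
})

test_that("displacement series move exactly one object in fixed increments", {
  cfg <- default_cfg()
  objs <- list(object_spec("rectangle", 5), object_spec("triangle", 6))
  base <- scene_spec(objs, rbind(c(40, 60), c(100, 60)), id = "ser")
  ser <- make_displacement_series(base, "horizontal", step = 10, levels = 5,
                                  config = cfg)
  expect_length(ser$scenes, 5)
  expect_equal(ser$displacement, seq(10, 50, by = 10))
  ref <- ser$reference
  top_box <- ref$pixels[16:65, 36:85]
  for (j in 1:5) {
    sc <- ser$scenes[[j]]
    # non-displaced object identical
    expect_identical(sc$pixels[16:65, 36:85], top_box)
    # displaced object is the same patch shifted by j * step columns
    expect_identical(sc$pixels[76:125, 36:85 + j * 10],
                     ref$pixels[76:125, 36:85])
    expect_equal(sc$centers[2, ], ref$centers[2, ] + c(0, j * 10))
  }
  # adjacent scenes differ by a single 10-pixel shift
  expect_identical(ser$scenes[[2]]$pixels[76:125, 56:105],
                   ser$scenes[[1]]$pixels[76:125, 46:95])
  # a series that would leave the canvas is rejected
  wide <- scene_spec(objs, rbind(c(40, 60), c(100, 100)), id = "w")
  expect_error(make_displacement_series(wide, "horizontal", config = cfg),
               class = "chord_config_error")
})

test_that("structural transformations act on placements as announced", {
  cfg <- default_cfg()
  objs <- list(object_spec("ellipse", 7), object_spec("cross", 8))
  base <- scene_spec(objs, rbind(c(40, 70), c(105, 80)), id = "q")
  tr <- make_transformed_scene(base, "T", translation = c(15, -10), config = cfg)
  expect_equal(tr$centers[2, ] - tr$centers[1, ],
               base$centers[2, ] - base$centers[1, ])   # displacement kept
  expect_equal(tr$centers[1, ], base$centers[1, ] + c(15, -10))
  rv <- make_transformed_scene(base, "R", config = cfg)
  expect_equal(rv$centers, base$centers[2:1, ])
  # the object pixels really swap places
  ref <- make_scene(base, cfg)
  expect_identical(rv$pixels[16:65, 46:95], ref$pixels[81:130, 56:105])
  # TR equals translation and reversal in either order
  trv <- make_transformed_scene(base, "TR", translation = c(15, -10),
                                config = cfg)
  translated <- scene_spec(objs, sweep(base$centers, 2, -c(15, -10)), id = "q2")
  other_order <- make_transformed_scene(translated, "R", config = cfg)
  expect_equal(trv$centers, other_order$centers)
  expect_identical(trv$pixels, other_order$pixels)
  expect_error(make_transformed_scene(base, "T", translation = c(40, 0),
                                      config = cfg),
               class = "chord_config_error")
})

test_that("training catalogs are reproducible from the master seed", {
  cfg <- default_cfg()
  c1 <- training_catalog(cfg, seed = 9, n_scenes = 30)
  c2 <- training_catalog(cfg, seed = 9, n_scenes = 30)
  expect_identical(c1$scenes, c2$scenes)
  expect_identical(c1$pool, c2$pool)
  expect_equal(nrow(c1$inventory), 20)
  expect_length(c1$pool, cfg$n_object_pool)
  c3 <- training_catalog(cfg, seed = 10, n_scenes = 30)
  expect_false(identical(c1$scenes, c3$scenes))
})

test_that("condition sets realize the advertised novelty structure", {
  cfg <- default_cfg()
  catalog <- training_catalog(cfg, seed = 9, n_scenes = 40)
  pool_tags <- vapply(catalog$pool, function(o)
    paste(o$category, o$seed), character(1))
  n_set <- make_condition_set("N", 15, catalog, seed = 2)
  for (sc in n_set) {
    novel <- attr(sc, "novel")
    expect_equal(sum(novel), 1)          # exactly one novel object
    cats <- vapply(sc$spec$objects, `[[`, "", "category")
    expect_true(cats[novel] %in% catalog$novel_categories)
    expect_true(cats[!novel] %in% catalog$familiar)
    # the layout comes from the training inventory
    d <- sc$spec$centers[2, ] - sc$spec$centers[1, ]
    expect_true(any(catalog$inventory[, 1] == d[1] &
                      catalog$inventory[, 2] == d[2]))
  }
  nn_set <- make_condition_set("NN", 10, catalog, seed = 3)
  for (sc in nn_set)
    expect_true(all(vapply(sc$spec$objects, `[[`, "", "category") %in%
                      catalog$novel_categories))
  l_set <- make_condition_set("L", 15, catalog, seed = 4)
  for (sc in l_set) {
    d <- sc$spec$centers[2, ] - sc$spec$centers[1, ]
    gap <- min(apply(catalog$inventory, 1, function(v) max(abs(v - d))))
    expect_gte(gap, cfg$novel_layout_margin)
    expect_true(all(vapply(sc$spec$objects, `[[`, "", "category") %in%
                      catalog$familiar))
  }
  # all generated scenes are encodable
  enc <- default_encoder()
  for (sc in c(n_set[1:3], l_set[1:3]))
    expect_length(detect_rois(sc, enc, 2), 2)
  # exemplar-novelty axis: novel objects come from familiar families
  ex_set <- make_condition_set("N", 5, catalog, seed = 5, novelty = "exemplar")
  for (sc in ex_set) {
    novel <- attr(sc, "novel")
    o <- sc$spec$objects[[which(novel)]]
    expect_true(o$category %in% catalog$familiar)
    expect_false(paste(o$category, o$seed) %in% pool_tags)
  }
})
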