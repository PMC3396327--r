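test_that("each two-object scene is stored redundantly under both fixations", {
  enc <- default_encoder()
  mem <- chord_memory(enc)
  sc <- fixture_scene(seed = 61)
  expect_equal(store_scene(mem, sc), 2L)
  expect_equal(memory_size(mem), 2L)
  expect_setequal(vapply(mem$records, `[[`, "", "fixation"),
                  c("top", "bottom"))
  # k scenes -> 2k records
  for (i in 1:4) store_scene(mem, fixture_scene(seed = 70 + i))
  expect_equal(memory_size(mem), 10L)
  # re-storing the same scene id fails
  expect_error(store_scene(mem, fixture_scene(seed = 61)),
               class = "chord_duplicate_error")
})

test_that("dissimilarity sums the three component distances", {
  r1 <- fake_rep(c(1, rep(0, 9)), c(3, rep(0, 9)), c(2, rep(0, 9)))
  r2 <- fake_rep(rep(0, 10), rep(0, 10), rep(0, 10))
  d <- scene_dissimilarity(r1, r2)
  expect_equal(d$value, 6)                      # components 1, 2, 3
  expect_equal(unname(d$components), c(1, 2, 3))
  expect_equal(scene_dissimilarity(r1, r1)$value, 0)
  expect_equal(scene_dissimilarity(r2, r1)$value, d$value)  # symmetry
  expect_error(scene_dissimilarity(r1, fake_rep(1, 1, 1)),
               class = "chord_dimension_error")
  expect_error(
    scene_dissimilarity(r1, fake_rep(rep(0, 10), rep(0, 10), rep(0, 10),
                                     mode = "raw")),
    class = "chord_dimension_error")
})

test_that("dissimilarity is a pseudometric on random representations", {
  set.seed(33)
  rand_rep <- function() fake_rep(rnorm(10), rnorm(10), rnorm(10))
  for (i in 1:30) {
    a <- rand_rep(); b <- rand_rep(); c <- rand_rep()
    dab <- scene_dissimilarity(a, b)$value
    dbc <- scene_dissimilarity(b, c)$value
    dac <- scene_dissimilarity(a, c)$value
    expect_gte(dab, 0)
    expect_equal(dab, scene_dissimilarity(b, a)$value)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("querying a stored scene returns it first with zero dissimilarity", {
  mem <- chord_memory(default_encoder())
  for (s in c(61, 71:74)) store_scene(mem, fixture_scene(seed = s))
  sc <- fixture_scene(seed = 61)
  q <- query_scene(mem, sc, k = 5)
  expect_equal(q$composite, 0)
  top_match <- q$matches[q$matches$fixation == "top" & q$matches$rank == 1, ]
  expect_equal(top_match$scene_id, "fix-61")
  expect_lte(max(table(q$matches$fixation)), 5)
  expect_error(query_scene(chord_memory(default_encoder()), sc),
               class = "chord_empty_memory_error")
})

test_that("replacing one object leaves a single dominant roi term", {
  cfg <- default_cfg(); enc <- default_encoder()
  mem <- chord_memory(enc)
  base <- scene_spec(list(object_spec("ellipse", 881), object_spec("annulus", 882)),
                     rbind(c(40, 75), c(104, 75)), id = "orig")
  store_scene(mem, make_scene(base, cfg))
  for (i in 1:10)
    store_scene(mem, fixture_scene(seed = 90 + i,
                                   centers = rbind(c(40, 65), c(104, 85))))
  probe <- scene_spec(list(object_spec("ellipse", 881), object_spec("grating", 99)),
                      rbind(c(40, 75), c(104, 75)), id = "probe")
  q <- query_scene(mem, make_scene(probe, cfg), k = 3)
  best <- q$matches[q$matches$rank == 1, ]
  expect_true(all(best$scene_id == "orig"))
  # the replaced object contributes the dominant component; under top
  # fixation it is the "other" roi, under bottom fixation the fixated one
  top <- best[best$fixation == "top", ]
  expect_equal(max(top$d_fix, top$d_layout, top$d_other), top$d_other)
  bot <- best[best$fixation == "bottom", ]
  expect_equal(max(bot$d_fix, bot$d_layout, bot$d_other), bot$d_fix)
})

test_that("lsh-backed ranking agrees with a brute-force scan", {
  # Re-identification regime: a query whose representation matches a stored
  # record must find it through the hash tables and rank it exactly as a
  # full scan would.  Under perturbed queries (placement jitter at the
  # detector's own +-1 px scale) the integer ROI crop can shift relative to
  # the object, the key code moves, and the source record can be missed
  # while other candidates still collide, so agreement degrades gracefully
  # rather than falling back; the floor below was frozen from an oracle run
  # (~0.89).
  cfg <- default_cfg()
  catalog <- cached("catalog500", training_catalog(cfg, seed = 4, n_scenes = 500))
  mem <- cached("mem500", {
    m <- chord_memory(chord_encoder(cfg, seed = 4))
    for (sp in catalog$scenes) store_scene(m, make_scene(sp, cfg))
    m
  })
  mats <- chordscene:::.memory_mats(mem)
  brute_best <- function(sc) {
    reps <- chordscene:::encode_scene_full(sc, mem$encoder)
    vapply(c(top = "top", bottom = "bottom"), function(fix) {
      r <- reps[[fix]]
      min(chordscene:::.row_dist(mats$key, r$fix_code) +
            chordscene:::.row_dist(mats$layout, r$layout_code) +
            chordscene:::.row_dist(mats$other, r$other_code))
    }, numeric(1))
  }
  set.seed(31)
  exact <- vapply(sample(500, 60), function(i) {
    sc <- make_scene(catalog$scenes[[i]], cfg)
    q <- query_scene(mem, sc, k = 5)
    all(q$best <= brute_best(sc) + 1e-9)
  }, logical(1))
  expect_gte(mean(exact), 0.95)
  jittered <- c()
  for (i in 1:80) {
    sp <- catalog$scenes[[sample(500, 1)]]
    ctr <- pmin(pmax(sp$centers + matrix(sample(-1:1, 4, TRUE), 2), 25), 125)
    d <- abs(ctr[1, ] - ctr[2, ])
    if (d[1] < 50 && d[2] < 50) next
    sc <- make_scene(scene_spec(sp$objects, ctr, id = paste0("jit", i)), cfg)
    q <- query_scene(mem, sc, k = 5)
    jittered <- c(jittered, all(q$best <= brute_best(sc) + 1e-9))
  }
  expect_gte(mean(jittered), 0.85)
})

test_that("dissimilarity degrades gracefully with the number of novel parts", {
  ex <- criterion_productivity()
  ct <- ex$data[ex$data$mode == "ct", ]
  by_novelty <- vapply(c("familiar", "N", "NN"), function(cond)
    mean(ct$delta[ct$condition == cond]), numeric(1))
  expect_true(all(diff(by_novelty) > 0))   # 0 < 1 < 2 novel constituents
})

test_that("memory contents survive a json-lines round trip", {
  mem <- small_memory()
  path <- tempfile(fileext = ".jsonl")
  dump_memory(mem, path)
  m2 <- load_memory(path, mem$encoder)
  expect_equal(memory_size(m2), memory_size(mem))
  sc <- fixture_scene(seed = 73)
  q1 <- query_scene(mem, sc, k = 3)
  q2 <- query_scene(m2, sc, k = 3)
  expect_equal(q1$composite, q2$composite)
  expect_equal(q1$matches$scene_id, q2$matches$scene_id)
})
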