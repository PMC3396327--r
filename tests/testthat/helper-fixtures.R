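# Shared fixtures.  Expensive objects (encoder, criterion-scale experiment
# runs) are built once per test session and cached here so several test files
# can assert against the same computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

default_cfg <- function() cached("cfg", chord_config())

default_encoder <- function() cached("enc", chord_encoder(default_cfg(), seed = 1L))

# a deterministic two-object scene with known placements
fixture_scene <- function(seed = 7L, centers = rbind(c(40, 75), c(110, 75)),
                          categories = c("ellipse", "rectangle")) {
  sp <- scene_spec(list(object_spec(categories[1], seed),
                        object_spec(categories[2], seed + 1L)),
                   centers, id = sprintf("fix-%d", seed))
  make_scene(sp, default_cfg())
}

# small populated memory shared across memory/hashing tests
small_memory <- function() cached("mem20", {
  enc <- default_encoder()
  mem <- chord_memory(enc)
  set.seed(101)
  cfg <- default_cfg()
  fam <- cfg$object_categories[1:6]
  for (i in 1:20) {
    sp <- scene_spec(list(object_spec(fam[(i - 1) %% 6 + 1], 1000 + i),
                          object_spec(fam[i %% 6 + 1], 2000 + i)),
                     rbind(c(40, 60 + (i %% 3) * 10), c(104, 70 + (i %% 4) * 5)),
                     id = sprintf("mem-%02d", i))
    store_scene(mem, make_scene(sp, cfg))
  }
  mem
})

# criterion-scale productivity run (also used by the graceful-degradation
# property test); computed once
criterion_productivity <- function() cached("prod200", {
  run_productivity(default_cfg(), seed = 1L, n_per_condition = 200,
                   n_train = 2000, mode = c("ct", "raw"))
})

# a fabricated scene representation with given component vectors
fake_rep <- function(fix, other, layout, fixation = "top", mode = "ct") {
  structure(list(fix_code = fix, other_code = other, layout_code = layout,
                 fixation = fixation, mode = mode, scene_id = NULL,
                 centers = NULL),
            class = "scene_rep")
}
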