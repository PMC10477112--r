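test_that("scenes are bit-identical for a fixed spec", {
  a <- generate_scene(tiny_spec(seed = 9L))
  b <- generate_scene(tiny_spec(seed = 9L))
  expect_identical(a$nucleus$voxels, b$nucleus$voxels)
  expect_identical(a$pla$voxels, b$pla$voxels)
  expect_identical(a$truth$dot_centers, b$truth$dot_centers)
  c2 <- generate_scene(tiny_spec(seed = 10L))
  expect_false(identical(a$pla$voxels, c2$pla$voxels))
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_scene(tiny_spec(seed = 5L)))
  expect_identical(rnorm(3), before)
})

test_that("a dot-free noise-free scene is pure background", {
  sp <- tiny_spec(n_pla_dots = 0L, poisson_scale = 0, gaussian_sd = 0, seed = 2L)
  sc <- generate_scene(sp)
  expect_identical(sc$truth$true_pla_area, 0L)
  expect_true(all(sc$pla$voxels == sp$background))
})

test_that("ground-truth areas are the label-volume sums and overlap is nested", {
  sc <- generate_scene(tiny_spec(seed = 4L))
  tr <- sc$truth
  expect_identical(tr$true_nucleus_area, sum(tr$nucleus_label))
  expect_identical(tr$true_pla_area, sum(tr$pla_label))
  expect_identical(tr$true_organelle_area, sum(tr$organelle_label))
  expect_identical(tr$true_overlap_area, sum(tr$pla_label & tr$organelle_label))
  expect_lte(tr$true_overlap_area, min(tr$true_pla_area, tr$true_organelle_area))
})

test_that("all dot centers land in organelle foreground when the fraction is 1", {
  sp <- tiny_spec(fraction_dots_in_organelle = 1, poisson_scale = 0,
                  gaussian_sd = 0, n_pla_dots = 8L, seed = 6L)
  sc <- generate_scene(sp)
  ctr <- sc$truth$dot_centers
  hits <- vapply(seq_len(nrow(ctr)), function(i)
    sc$truth$organelle_label[ctr[i, 1], ctr[i, 2], ctr[i, 3]], logical(1))
  expect_true(all(hits))
})

test_that("dots requested inside an empty organelle field fail loudly", {
  sp <- tiny_spec(n_organelles = 0L, fraction_dots_in_organelle = 0.5, seed = 1L)
  expect_error(generate_scene(sp), "organelle field is empty")
})

test_that("impossible nucleus packing raises a generation error", {
  sp <- scene_spec(shape = c(7L, 24L, 24L), n_nuclei = 12L,
                   nucleus_radii = c(3, 10, 10), n_pla_dots = 0L,
                   n_organelles = 0L, fraction_dots_in_organelle = 0, seed = 1L)
  expect_error(generate_scene(sp), "could not place nucleus")
})

test_that("local-maximum detection on noise-free composites recovers the dot count", {
  n_dots <- 200L
  counts <- vapply(1:8, function(seed) {
    sp <- scene_spec(shape = c(21L, 128L, 128L), n_nuclei = 0L, n_pla_dots = n_dots,
                     n_organelles = 0L, fraction_dots_in_organelle = 0,
                     poisson_scale = 0, gaussian_sd = 0, seed = seed)
    sc <- generate_scene(sp)
    oracle_count_dot_maxima(sc$pla$voxels, sp$background)
  }, numeric(1))
  # merged/edge-cropped spots lose a few maxima; 3*sqrt(n) is the agreed slack
  expect_lt(abs(mean(counts) - n_dots), 3 * sqrt(n_dots))
})

test_that("group experiments write a complete, reproducible manifest", {
  d1 <- tempfile("exp1_"); d2 <- tempfile("exp2_")
  e1 <- generate_group_experiment(tiny_spec(), tiny_spec(n_pla_dots = 20L),
                                  n_images_per_group = 2L, base_seed = 5L,
                                  dir = d1)
  expect_identical(nrow(e1$manifest), 4L)
  expect_identical(sort(unique(e1$manifest$group_label)), c("high", "low"))
  e2 <- generate_group_experiment(tiny_spec(), tiny_spec(n_pla_dots = 20L),
                                  n_images_per_group = 2L, base_seed = 5L,
                                  dir = d2)
  for (f in e1$manifest$file_primary)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  expect_error(generate_group_experiment(tiny_spec(), tiny_spec(),
                                         n_images_per_group = 1L),
               "at least 2")
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(scene_spec(fraction_dots_in_organelle = 1.2), "0, 1")
  expect_error(scene_spec(n_pla_dots = -1), ">= 0")
  expect_error(scene_spec(background = 100, dot_peak = 200, bit_depth = 8),
               "within")
  expect_error(scene_spec(gaussian_sd = -2), ">= 0")
})
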