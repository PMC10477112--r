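make_volume <- function(d, bit_depth = 8L, seed = 1L, name = "pla") {
  set.seed(seed)
  volume_channel(array(sample.int(2^bit_depth, prod(d), replace = TRUE) - 1L, d),
                 channel_name = name, bit_depth = bit_depth)
}

test_that("volume_channel enforces bit depth, shape and integer intensities", {
  expect_error(volume_channel(matrix(0, 2, 2)), "3D")
  expect_error(volume_channel(array(-1, c(1, 2, 2))), "intensities")
  expect_error(volume_channel(array(256, c(1, 2, 2)), bit_depth = 8), "intensities")
  expect_error(volume_channel(array(0.5, c(1, 2, 2))), "whole numbers")
  v <- volume_channel(array(65535, c(1, 2, 2)), bit_depth = 16)
  expect_identical(v$bit_depth, 16L)
})

test_that("TIFF round trip is lossless for 8- and 16-bit volumes", {
  for (bd in c(8L, 16L)) {
    v <- make_volume(c(21L, 12L, 10L), bit_depth = bd, seed = bd)
    f <- tempfile(fileext = ".tif")
    write_tiff_volume(v, f)
    back <- read_tiff_volume(f, channel_name = "pla")
    expect_identical(back$voxels, array(as.integer(v$voxels), dim(v$voxels)))
    expect_identical(back$bit_depth, bd)
  }
})

test_that("stack pairs validate channel roles and shapes", {
  nuc <- make_volume(c(3L, 8L, 8L), name = "nucleus", seed = 1)
  pla <- make_volume(c(3L, 8L, 8L), name = "pla", seed = 2)
  p <- stack_pair(nuc, pla, image_id = "a", group_label = "NPC")
  expect_s3_class(p, "stack_pair")
  short <- make_volume(c(2L, 8L, 8L), name = "pla", seed = 3)
  expect_error(stack_pair(nuc, short, image_id = "b"), "shapes differ")
  expect_error(stack_pair(pla, pla, image_id = "c"), "nucleus or organelle")
})

test_that("paired and interleaved manifest layouts read to identical pairs", {
  d <- tempfile("plaqio_"); dir.create(d)
  nuc <- make_volume(c(4L, 6L, 6L), name = "nucleus", seed = 10)
  pla <- make_volume(c(4L, 6L, 6L), name = "pla", seed = 11)
  write_tiff_volume(nuc, file.path(d, "n.tif"))
  write_tiff_volume(pla, file.path(d, "p.tif"))
  # interleaved: pages alternate nucleus z1, pla z1, nucleus z2, ...
  inter <- lapply(seq_len(4), function(z)
    list(nuc$voxels[z, , ] / 255, pla$voxels[z, , ] / 255))
  tiff::writeTIFF(unlist(inter, recursive = FALSE), file.path(d, "i.tif"),
                  bits.per.sample = 8L)
  man <- data.frame(
    image_id = c("pairA", "intA"), group_label = "NPC",
    layout = c("paired", "interleaved"),
    file_primary = c("n.tif", "i.tif"), file_pla = c("p.tif", "i.tif"),
    primary_channel = "nucleus", stringsAsFactors = FALSE)
  write.csv(man, file.path(d, "manifest.csv"), row.names = FALSE)
  m <- read_manifest(file.path(d, "manifest.csv"))
  p1 <- read_stack_pair(m[1, ])
  p2 <- read_stack_pair(m[2, ])
  expect_identical(p1$primary$voxels, p2$primary$voxels)
  expect_identical(p1$pla$voxels, p2$pla$voxels)
  expect_identical(dim(p1$pla$voxels), c(4L, 6L, 6L))
})

test_that("shape mismatches and unsupported formats are rejected on read", {
  d <- tempfile("plaqbad_"); dir.create(d)
  write_tiff_volume(make_volume(c(3L, 6L, 6L), name = "nucleus", seed = 1),
                    file.path(d, "n.tif"))
  write_tiff_volume(make_volume(c(2L, 6L, 6L), name = "pla", seed = 2),
                    file.path(d, "p.tif"))
  man <- data.frame(image_id = "x", group_label = "g", layout = "paired",
                    file_primary = "n.tif", file_pla = "p.tif",
                    primary_channel = "nucleus", stringsAsFactors = FALSE)
  write.csv(man, file.path(d, "manifest.csv"), row.names = FALSE)
  m <- read_manifest(file.path(d, "manifest.csv"))
  expect_error(read_stack_pair(m[1, ]), "shapes differ")
  # float TIFF is a format error, not a silent conversion
  tiff::writeTIFF(matrix(runif(16), 4, 4), file.path(d, "f.tif"),
                  bits.per.sample = 32L)
  expect_error(read_tiff_volume(file.path(d, "f.tif")), "unsupported sample format")
  expect_error(read_tiff_volume(file.path(d, "absent.tif")), "not found")
})

test_that("manifest validation names missing files and duplicate ids", {
  d <- tempfile("plaqman_"); dir.create(d)
  man <- data.frame(image_id = c("a", "a"), group_label = "g", layout = "paired",
                    file_primary = "nope.tif", file_pla = "nope.tif",
                    primary_channel = "nucleus", stringsAsFactors = FALSE)
  write.csv(man, file.path(d, "manifest.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(d, "manifest.csv")), "unique")
  man$image_id <- c("a", "b")
  write.csv(man, file.path(d, "manifest.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(d, "manifest.csv")), "missing file")
})

test_that("results tables round-trip ratios bit-identically", {
  sc <- generate_scene(tiny_spec(seed = 3L))
  r <- quantify_pla_image(as_stack_pair(sc, "nucleus", image_id = "t",
                                        group_label = "g"),
                          min_size_nucleus = 5L, min_size_pla = 1L)
  df <- results_table(list(r, r, r))
  expect_identical(nrow(df), 3L)
  f <- tempfile(fileext = ".csv")
  write_results_table(df, f)
  back <- read.csv(f)
  expect_identical(back$ratio, rep(r$ratio, 3))
  expect_error(write_results_table(list()), "no results")
})
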