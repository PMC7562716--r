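test_that("read_region honors the level-0 identity and tiling consistency", {
  set.seed(1)
  arr <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  slide <- slide_image(arr, id = "t")
  expect_equal(read_region(slide, c(0, 0), c(64, 64), level = 0), arr)

  left <- read_region(slide, c(0, 16), c(32, 16))
  right <- read_region(slide, c(32, 16), c(32, 16))
  whole <- read_region(slide, c(0, 16), c(64, 16))
  expect_equal(cbind(left[, , 2], right[, , 2]), whole[, , 2])
})

test_that("higher levels equal block-averaged level-0 reads", {
  set.seed(2)
  arr <- array(runif(64 * 48 * 3, 0, 255), c(48, 64, 3))
  slide <- slide_image(round(arr), id = "t")
  lv1 <- read_region(slide, c(0, 0), c(32, 24), level = 1)
  # oracle: average every 2x2 block of the level-0 raster
  for (k in 1:3) {
    oracle <- matrix(0, 24, 32)
    for (r in 1:24) for (c in 1:32)
      oracle[r, c] <- mean(slide$data[(2 * r - 1):(2 * r), (2 * c - 1):(2 * c), k])
    expect_lt(max(abs(lv1[, , k] - oracle)), 1)
  }
})

test_that("out-of-bounds regions fail naming the offending coordinate", {
  slide <- slide_image(array(100, c(32, 32, 3)))
  expect_error(read_region(slide, c(-1, 0), c(8, 8)), "x origin")
  expect_error(read_region(slide, c(0, 30), c(8, 8)), "bottom edge")
  expect_error(read_region(slide, c(0, 0), c(8, 8), level = 9), "level")
})

test_that("slides round-trip through PNG", {
  set.seed(3)
  arr <- array(sample(0:255, 24 * 24 * 3, replace = TRUE), c(24, 24, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_slide(arr, path)
  back <- read_slide(path)
  expect_equal(back$data, arr)
})

test_that("annotations round-trip through ASAP-style XML", {
  polys <- list(square_poly(5, 5, 20), square_poly(30, 10, 8),
                cbind(c(1, 14, 7.5), c(1, 1, 12)))
  ann <- annotation_set(c("normal", "cancer", "gastritis"), polys, "s1")
  path <- withr::local_tempfile(fileext = ".xml")
  write_annotations(ann, path)
  back <- parse_annotations(path)
  expect_equal(back$labels, ann$labels)
  for (i in 1:3) expect_equal(back$polygons[[i]], ann$polygons[[i]])
})

test_that("annotation parsing enforces the vocabulary and vertex count", {
  expect_error(annotation_set("stroma", list(square_poly(0, 0, 5))),
               "normal, gastritis, cancer")
  expect_error(annotation_set("normal", list(cbind(c(0, 1), c(0, 1)))), "n >= 3")

  # empty document parses to an empty set
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<ASAP_Annotations><Annotations/></ASAP_Annotations>", path)
  empty <- parse_annotations(path)
  expect_length(empty$labels, 0)

  # two-vertex polygon in a file is rejected
  writeLines(paste0(
    "<ASAP_Annotations><Annotations>",
    "<Annotation Name='a' Type='Polygon' PartOfGroup='cancer'><Coordinates>",
    "<Coordinate Order='0' X='0' Y='0'/><Coordinate Order='1' X='5' Y='5'/>",
    "</Coordinates></Annotation></Annotations></ASAP_Annotations>"), path)
  expect_error(parse_annotations(path), "at least 3")

  # malformed XML propagates a parse error
  writeLines("<ASAP_Annotations><unclosed>", path)
  expect_error(parse_annotations(path))
})

test_that("rasterization follows the even-odd pixel-center rule", {
  ann <- annotation_set("cancer", list(square_poly(10, 10, 100)), "s")
  mask <- rasterize_annotations(ann, c(128, 128), downsample = 1)
  expect_equal(sum(mask == 3L), 100 * 100)

  # oracle: mgcv::in.out at every pixel center
  skip_if_not_installed("mgcv")
  tri <- cbind(c(3.3, 40.2, 19.6), c(5.1, 8.7, 37.9))
  ann2 <- annotation_set("gastritis", list(tri), "s")
  m2 <- rasterize_annotations(ann2, c(48, 48), downsample = 1)
  centers <- as.matrix(expand.grid(x = (1:48) - 0.5, y = (1:48) - 0.5))
  inside <- mgcv::in.out(rbind(tri, tri[1, ]), centers)
  oracle <- matrix(0L, 48, 48)
  oracle[cbind(centers[inside, 2] + 0.5, centers[inside, 1] + 0.5)] <- 2L
  expect_equal(m2, oracle)
})

test_that("later polygons overwrite earlier ones; none gives background", {
  expect_true(all(rasterize_annotations(annotation_set(), c(20, 20)) == 0L))
  ann <- annotation_set(c("normal", "cancer"),
                        list(square_poly(0, 0, 16), square_poly(8, 8, 10)), "s")
  mask <- rasterize_annotations(ann, c(20, 20), downsample = 1)
  expect_equal(mask[12, 12], 3L)  # overlap carries the later cancer code
  expect_equal(mask[4, 4], 1L)
})

test_that("generator masks survive the XML -> parse -> rasterize round trip", {
  gen <- demo_slide(seed = 5, side = 128)
  path <- withr::local_tempfile(fileext = ".xml")
  write_annotations(gen$annotations, path)
  rast <- rasterize_annotations(parse_annotations(path), c(128, 128), 1)
  for (code in c(1L, 3L)) {
    a <- gen$mask == code
    b <- rast == code
    expect_gte(sum(a & b) / sum(a | b), 0.99)
  }
})
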