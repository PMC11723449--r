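# COCO I/O, letterboxing and augmentation geometry.

make_coco_file <- function() {
  path <- tempfile(fileext = ".json")
  coco <- list(
    images = list(
      list(id = 1, file_name = "a.png", width = 80, height = 60),
      list(id = 5, file_name = "b.png", width = 80, height = 60)),
    annotations = list(
      list(id = 1, image_id = 1, category_id = 10, bbox = c(5, 5, 20, 10)),
      list(id = 2, image_id = 1, category_id = 30, bbox = c(30, 20, 10, 10)),
      list(id = 3, image_id = 5, category_id = 10, bbox = c(0, 0, 40, 30))),
    categories = list(list(id = 10, name = "heron"),
                      list(id = 30, name = "crane")))
  jsonlite::write_json(coco, path, auto_unbox = TRUE)
  path
}

test_that("COCO load preserves counts and remaps categories to [0, C)", {
  ds <- load_coco(make_coco_file())
  expect_equal(nrow(ds$images), 2)
  expect_equal(nrow(ds$annotations), 3)
  expect_equal(sort(ds$categories$category), c(0L, 1L))
  expect_equal(ds$categories$id, c(10, 30))
  expect_true(all(ds$annotations$category %in% c(0L, 1L)))
  # xywh -> half-open corners
  a <- ds$annotations[1, ]
  expect_equal(c(a$x1, a$y1, a$x2, a$y2), c(5, 5, 25, 15))
})

test_that("load -> save -> load round trip is the identity on boxes and labels", {
  ds <- load_coco(make_coco_file())
  out <- tempfile(fileext = ".json")
  save_coco(ds, out)
  ds2 <- load_coco(out)
  expect_equal(ds2$annotations, ds$annotations)
  expect_equal(ds2$categories, ds$categories)
})

test_that("malformed COCO files fail with the offending record", {
  bad1 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(images = list()), bad1, auto_unbox = TRUE)
  expect_error(load_coco(bad1), "missing key")
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    images = list(list(id = 1, file_name = "a.png", width = 8, height = 8)),
    annotations = list(list(id = 9, image_id = 77, category_id = 1,
                            bbox = c(0, 0, 2, 2))),
    categories = list(list(id = 1, name = "x"))), bad2, auto_unbox = TRUE)
  expect_error(load_coco(bad2), "unknown image 77")
})

test_that("letterbox geometry matches hand-computed scale and padding", {
  img <- array(runif(720 * 1280 * 3), dim = c(720, 1280, 3))
  boxes <- data.frame(x1 = 0, y1 = 0, x2 = 100, y2 = 100)
  lb <- letterbox(img, boxes, c(640L, 640L))
  expect_equal(lb$scale, c(0.5, 0.5))
  expect_equal(lb$pad, c(140, 0))
  expect_equal(dim(lb$image), c(640, 640, 3))
  expect_equal(as.numeric(lb$boxes[1, c("x1", "y1", "x2", "y2")]),
               c(0, 140, 50, 190))
  # inverse recovers the original box to <= 0.5 px
  inv <- c((lb$boxes$x1 - lb$pad[2]) / lb$scale[2],
           (lb$boxes$y1 - lb$pad[1]) / lb$scale[1],
           (lb$boxes$x2 - lb$pad[2]) / lb$scale[2],
           (lb$boxes$y2 - lb$pad[1]) / lb$scale[1])
  expect_true(all(abs(inv - c(0, 0, 100, 100)) <= 0.5))
  # padded rows are neutral gray
  expect_equal(unique(as.vector(lb$image[1:140, , ])), 114 / 255)
})

test_that("letterbox at the target size is a no-op", {
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  lb <- letterbox(img, NULL, c(64L, 64L))
  expect_identical(lb$image, img)
  expect_equal(lb$scale, c(1, 1))
  expect_equal(lb$pad, c(0, 0))
  expect_error(letterbox(array(0, dim = c(0, 4, 3)), NULL, c(64L, 64L)),
               "zero-sized")
})

test_that("mosaic with a midpoint center puts one box per quadrant", {
  img <- array(0.5, dim = c(64, 64, 3))
  bx <- data.frame(category = 0L, x1 = 24, y1 = 24, x2 = 40, y2 = 40)
  mz <- mosaic_augment(rep(list(img), 4), rep(list(bx), 4),
                       center = c(32, 32))
  expect_equal(nrow(mz$boxes), 4)
  quad <- paste(mz$boxes$x1 < 32, mz$boxes$y1 < 32)
  expect_equal(length(unique(quad)), 4)  # one per quadrant
  expect_error(mosaic_augment(rep(list(img), 3), rep(list(bx), 3)), "four")
})

test_that("mosaic only removes boxes and is seed-reproducible", {
  set.seed(1)
  imgs <- lapply(1:4, function(i) array(runif(64 * 64 * 3), dim = c(64, 64, 3)))
  bxs <- lapply(1:4, function(i)
    data.frame(category = 0L, x1 = runif(2, 0, 40), y1 = runif(2, 0, 40),
               x2 = runif(2, 41, 64), y2 = runif(2, 41, 64)))
  m1 <- mosaic_augment(imgs, bxs, rng_seed = 5L)
  m2 <- mosaic_augment(imgs, bxs, rng_seed = 5L)
  expect_identical(m1, m2)
  expect_lte(nrow(m1$boxes), sum(vapply(bxs, nrow, integer(1))))
})

test_that("identity affine is a no-op and zoom 2 doubles box sides", {
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  bx <- data.frame(category = 0L, x1 = 28, y1 = 28, x2 = 36, y2 = 36)
  id <- random_affine(img, bx, zoom_range = c(1, 1), translate_range = 0)
  expect_identical(id$image, img)
  expect_equal(id$boxes, bx)
  z2 <- random_affine(img, bx, zoom_range = c(2, 2), translate_range = 0)
  expect_equal(z2$boxes$x2 - z2$boxes$x1, 16)
  expect_equal(z2$boxes$y2 - z2$boxes$y1, 16)
  expect_error(random_affine(img, bx, zoom_range = c(-1, 1)), "zoom")
  expect_error(random_affine(img, bx, translate_range = 1.5), "translate")
  a1 <- random_affine(img, bx, rng_seed = 3L)
  a2 <- random_affine(img, bx, rng_seed = 3L)
  expect_identical(a1, a2)
})

test_that("augmented boxes always stay inside bounds with positive area", {
  set.seed(2)
  img <- array(runif(48 * 48 * 3), dim = c(48, 48, 3))
  for (i in 1:150) {
    bx <- data.frame(category = 0L, x1 = runif(3, 0, 30), y1 = runif(3, 0, 30),
                     x2 = runif(3, 31, 48), y2 = runif(3, 31, 48))
    af <- random_affine(img, bx)
    if (!is.null(af$boxes) && nrow(af$boxes) > 0) {
      expect_true(all(af$boxes$x1 >= 0 & af$boxes$x2 <= 48 &
                        af$boxes$y1 >= 0 & af$boxes$y2 <= 48))
      expect_true(all(af$boxes$x2 > af$boxes$x1 & af$boxes$y2 > af$boxes$y1))
    }
    mz <- mosaic_augment(rep(list(img), 4), rep(list(bx), 4))
    if (!is.null(mz$boxes) && nrow(mz$boxes) > 0) {
      expect_true(all(mz$boxes$x1 >= 0 & mz$boxes$x2 <= 48 &
                        mz$boxes$y1 >= 0 & mz$boxes$y2 <= 48))
      expect_true(all(mz$boxes$x2 > mz$boxes$x1 & mz$boxes$y2 > mz$boxes$y1))
    }
  }
})
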