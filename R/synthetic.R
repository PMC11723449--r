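# Synthetic long-tailed multi-object scene generator.
#
# Emulates the two properties of bird-surveillance data the detector's novel
# parts address: a long-tailed category distribution (category k drawn with
# probability proportional to (k+1)^-imbalance_exponent) and shared local
# appearance motifs across categories. Every sprite is a procedural
# composite: an ellipse body and triangular beak shared by all categories
# (the common motif), plus a category-colored wing patch whose salience
# shrinks as motif_overlap -> 1. Backgrounds are low-frequency noise so that
# objects are not trivially separable. Everything is drawn from an explicit
# seed, and the generator writes a ledger of exact per-category annotated
# pixel sums alongside the COCO JSON.

#' Scene generator specification
#'
#' @param n_categories number of categories (>= 2 recommended so the
#'   imbalance is observable).
#' @param n_images number of images to generate.
#' @param image_size `c(h, w)` in pixels.
#' @param imbalance_exponent power-law exponent a >= 0; category k (0-based)
#'   is drawn with probability proportional to (k+1)^-a. 0 gives a balanced
#'   set.
#' @param objects_per_image integer range `c(min, max)`.
#' @param object_scale sprite size range in px `c(min, max)`; must fit the
#'   image.
#' @param motif_overlap fraction in `[0, 1]` of appearance shared across
#'   categories (1 = categories identical up to pose).
#' @param seed integer seed; the whole dataset is a pure function of the
#'   spec.
#' @export
scene_spec <- function(n_categories = 8L, n_images = 64L,
                       image_size = c(128L, 128L), imbalance_exponent = 1.5,
                       objects_per_image = c(1L, 4L),
                       object_scale = c(16L, 48L), motif_overlap = 0.5,
                       seed = 0L) {
  if (n_categories < 1L) stop("n_categories must be >= 1")
  if (imbalance_exponent < 0) stop("imbalance_exponent must be >= 0")
  if (motif_overlap < 0 || motif_overlap > 1) stop("motif_overlap in [0, 1]")
  if (object_scale[2] > min(image_size)) stop("object_scale exceeds image size")
  list(n_categories = as.integer(n_categories), n_images = as.integer(n_images),
       image_size = as.integer(image_size),
       imbalance_exponent = imbalance_exponent,
       objects_per_image = as.integer(objects_per_image),
       object_scale = as.integer(object_scale), motif_overlap = motif_overlap,
       seed = as.integer(seed))
}

# deterministic category palette (hues spread around the wheel)
category_color <- function(k, n) {
  grDevices::col2rgb(grDevices::hsv((k / max(n, 1) * 0.85 + 0.02) %% 1, 0.9, 0.9))[, 1] / 255
}

#' Render one bird-like sprite
#'
#' @param category 0-based category id.
#' @param scale sprite size (px).
#' @param motif_overlap shared-appearance fraction in `[0, 1]`.
#' @param n_categories palette size.
#' @return list with `sprite` (s x s x 3), `mask` (logical s x s), and
#'   `box` (tight 0-based half-open box around all non-background pixels).
#' @export
render_object <- function(category, scale, motif_overlap = 0.5,
                          n_categories = 8L) {
  s <- as.integer(scale)
  yy <- matrix(seq_len(s), s, s)        # row index
  xx <- matrix(seq_len(s), s, s, byrow = TRUE)
  cyx <- (s + 1) / 2
  # body: ellipse filling ~70% of the tile
  a <- 0.38 * s; b <- 0.26 * s
  body <- ((xx - cyx) / a)^2 + ((yy - cyx) / b)^2 <= 1
  # beak: right-pointing triangle off the body tip
  bx0 <- cyx + 0.30 * s; bx1 <- min(s, cyx + 0.49 * s)
  beak <- xx >= bx0 & xx <= bx1 &
    abs(yy - cyx) <= (bx1 - xx) / (bx1 - bx0) * 0.08 * s
  # wing patch: smaller ellipse, category-specific color
  wa <- 0.18 * s; wb <- 0.12 * s
  wing <- ((xx - (cyx - 0.08 * s)) / wa)^2 + ((yy - (cyx - 0.05 * s)) / wb)^2 <= 1
  mask <- body | beak
  body_col <- c(0.45, 0.35, 0.25)
  beak_col <- c(0.90, 0.60, 0.10)
  ck <- category_color(category, n_categories)
  wing_col <- motif_overlap * c(0.35, 0.30, 0.40) + (1 - motif_overlap) * ck
  sprite <- array(0, dim = c(s, s, 3))
  for (ch in 1:3) {
    plane <- matrix(0, s, s)
    plane[body] <- body_col[ch]
    plane[wing & body] <- wing_col[ch]
    plane[beak] <- beak_col[ch]
    sprite[, , ch] <- plane
  }
  rows <- which(apply(mask, 1, any)); cols <- which(apply(mask, 2, any))
  box <- c(x1 = min(cols) - 1, y1 = min(rows) - 1, x2 = max(cols), y2 = max(rows))
  list(sprite = sprite, mask = mask, box = box)
}

low_frequency_background <- function(h, w) {
  # sum of a few random low-frequency sinusoids plus mild texture noise;
  # a cheap stand-in for water/reed surfaces
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  base <- matrix(0, h, w)
  for (i in 1:3) {
    fy <- stats::runif(1, 0.5, 3); fx <- stats::runif(1, 0.5, 3)
    ph <- stats::runif(2, 0, 2 * pi)
    base <- base + sin(2 * pi * fy * yy + ph[1]) * cos(2 * pi * fx * xx + ph[2])
  }
  base <- (base - min(base)) / max(max(base) - min(base), 1e-9)
  tint <- c(stats::runif(1, 0.2, 0.45), stats::runif(1, 0.35, 0.55),
            stats::runif(1, 0.35, 0.6))
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- 0.25 + 0.35 * base * tint[ch] +
      matrix(stats::rnorm(h * w, sd = 0.02), h, w)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic detection dataset
#'
#' Writes `n_images` PNG scenes, a COCO detection JSON (`annotations.json`)
#' and a ledger JSON (`ledger.json`) with exact per-category annotated pixel
#' sums (sum of box areas) and object counts. Category draw frequencies
#' follow the power law of the scene spec; object placement avoids heavy overlap
#' but not contact. Byte-identical output for identical specs.
#'
#' @param spec a [scene_spec()].
#' @param out_dir output directory (created if needed).
#' @return the dataset, invisibly, as loaded back through [load_coco()],
#'   with the ledger attached as attribute `ledger`.
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  pcat <- (seq_len(spec$n_categories))^(-spec$imbalance_exponent)
  pcat <- pcat / sum(pcat)
  images <- list(); anns <- list(); aid <- 0L
  pixel_sum <- rep(0, spec$n_categories)
  obj_count <- rep(0L, spec$n_categories)
  for (i in seq_len(spec$n_images)) {
    img <- low_frequency_background(h, w)
    nobj <- sample(spec$objects_per_image[1]:spec$objects_per_image[2], 1)
    placed <- matrix(numeric(0), ncol = 4)
    for (k in seq_len(nobj)) {
      cat_k <- sample.int(spec$n_categories, 1, prob = pcat) - 1L
      sc <- sample(spec$object_scale[1]:spec$object_scale[2], 1)
      obj <- render_object(cat_k, sc, spec$motif_overlap, spec$n_categories)
      if (stats::runif(1) < 0.5) {      # horizontal flip = pose variation
        obj$sprite <- obj$sprite[, rev(seq_len(sc)), , drop = FALSE]
        obj$mask <- obj$mask[, rev(seq_len(sc)), drop = FALSE]
        obj$box <- c(x1 = sc - obj$box[["x2"]], y1 = obj$box[["y1"]],
                     x2 = sc - obj$box[["x1"]], y2 = obj$box[["y2"]])
      }
      ok <- FALSE
      for (try in 1:10) {
        oy <- sample.int(h - sc + 1L, 1) - 1L
        ox <- sample.int(w - sc + 1L, 1) - 1L
        bx <- c(ox + obj$box[["x1"]], oy + obj$box[["y1"]],
                ox + obj$box[["x2"]], oy + obj$box[["y2"]])
        if (nrow(placed) == 0L ||
            all(iou_one_many(bx, placed) < 0.3)) { ok <- TRUE; break }
      }
      if (!ok) next
      for (ch in 1:3) {
        plane <- img[oy + seq_len(sc), ox + seq_len(sc), ch]
        plane[obj$mask] <- obj$sprite[, , ch][obj$mask]
        img[oy + seq_len(sc), ox + seq_len(sc), ch] <- plane
      }
      placed <- rbind(placed, bx)
      aid <- aid + 1L
      bw <- bx[3] - bx[1]; bh <- bx[4] - bx[2]
      anns[[aid]] <- list(id = aid, image_id = i, category_id = cat_k + 1L,
                          bbox = c(bx[1], bx[2], bw, bh), area = bw * bh,
                          iscrowd = 0)
      pixel_sum[cat_k + 1L] <- pixel_sum[cat_k + 1L] + bw * bh
      obj_count[cat_k + 1L] <- obj_count[cat_k + 1L] + 1L
    }
    fn <- sprintf("scene_%04d.png", i)
    png::writePNG(img, file.path(out_dir, fn))
    images[[i]] <- list(id = i, file_name = fn, width = w, height = h)
  }
  cats <- lapply(seq_len(spec$n_categories), function(k)
    list(id = k, name = sprintf("species_%02d", k)))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(pixel_sum = pixel_sum, object_count = obj_count,
                            spec = spec),
                       file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  ds <- load_coco(file.path(out_dir, "annotations.json"))
  attr(ds, "ledger") <- list(pixel_sum = pixel_sum, object_count = obj_count)
  invisible(ds)
}
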