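# COCO-format detection I/O and geometric augmentation.
#
# Boxes are handled internally as 0-based half-open pixel rectangles
# (x1, y1, x2, y2); COCO's xywh convention is converted at the boundary.
# Category ids are remapped to contiguous 0-based indices on load; the
# remapping table travels with the dataset (and checkpoints) so predictions
# can be written back under original COCO ids.

#' Load a COCO detection dataset
#'
#' @param json_path path to a COCO detection JSON (`images`, `annotations`,
#'   `categories`).
#' @param image_dir directory holding the image files; defaults to the JSON's
#'   directory.
#' @return a `bsd_dataset`: list with `images` (data.frame id, file, width,
#'   height), `annotations` (data.frame image_id, category 0-based, x1, y1,
#'   x2, y2), `categories` (data.frame id = original COCO id, category =
#'   contiguous index, name), `image_dir`.
#' @export
load_coco <- function(json_path, image_dir = dirname(json_path)) {
  j <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  for (k in c("images", "annotations", "categories"))
    if (is.null(j[[k]])) stop("COCO file missing key: ", k)
  images <- do.call(rbind, lapply(j$images, function(im) {
    for (k in c("id", "file_name", "width", "height"))
      if (is.null(im[[k]])) stop("image record missing ", k,
                                 " (id ", im$id %||% "?", ")")
    data.frame(id = im$id, file = im$file_name, width = im$width,
               height = im$height, stringsAsFactors = FALSE)
  }))
  cat_ids <- sort(vapply(j$categories, function(x) as.numeric(x$id), numeric(1)))
  cat_names <- vapply(j$categories, function(x) x$name %||% as.character(x$id),
                      character(1))[order(vapply(j$categories,
                                                 function(x) as.numeric(x$id), numeric(1)))]
  remap <- data.frame(id = cat_ids, category = seq_along(cat_ids) - 1L,
                      name = cat_names, stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(j$annotations, function(a) {
    if (is.null(a$image_id) || is.null(a$category_id) || is.null(a$bbox))
      stop("annotation record missing fields (id ", a$id %||% "?", ")")
    if (!a$image_id %in% images$id)
      stop("annotation ", a$id %||% "?", " references unknown image ", a$image_id)
    if (!a$category_id %in% remap$id)
      stop("annotation ", a$id %||% "?", " references unknown category ",
           a$category_id)
    b <- as.numeric(a$bbox)
    data.frame(image_id = a$image_id,
               category = remap$category[match(a$category_id, remap$id)],
               x1 = b[1], y1 = b[2], x2 = b[1] + b[3], y2 = b[2] + b[4])
  }))
  if (is.null(ann))
    ann <- data.frame(image_id = numeric(0), category = integer(0),
                      x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0))
  structure(list(images = images, annotations = ann, categories = remap,
                 image_dir = image_dir), class = "bsd_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset back to COCO JSON
#'
#' Inverse of [load_coco()]; boxes are converted back to xywh and categories
#' to their original COCO ids.
#'
#' @param dataset a `bsd_dataset`.
#' @param json_path output path.
#' @export
save_coco <- function(dataset, json_path) {
  imgs <- lapply(seq_len(nrow(dataset$images)), function(i) {
    r <- dataset$images[i, ]
    list(id = r$id, file_name = r$file, width = r$width, height = r$height)
  })
  anns <- lapply(seq_len(nrow(dataset$annotations)), function(i) {
    a <- dataset$annotations[i, ]
    list(id = i, image_id = a$image_id,
         category_id = dataset$categories$id[match(a$category, dataset$categories$category)],
         bbox = c(a$x1, a$y1, a$x2 - a$x1, a$y2 - a$y1),
         area = (a$x2 - a$x1) * (a$y2 - a$y1), iscrowd = 0)
  })
  cats <- lapply(seq_len(nrow(dataset$categories)), function(i) {
    r <- dataset$categories[i, ]
    list(id = r$id, name = r$name)
  })
  jsonlite::write_json(list(images = imgs, annotations = anns, categories = cats),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' Write detections as COCO results JSON
#'
#' @param detections data.frame (image_id, category, confidence, x1..y2).
#' @param categories the dataset's category remapping table.
#' @param json_path output path.
#' @export
save_coco_results <- function(detections, categories, json_path) {
  res <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    list(image_id = d$image_id,
         category_id = categories$id[match(d$category, categories$category)],
         bbox = c(d$x1, d$y1, d$x2 - d$x1, d$y2 - d$y1),
         score = d$confidence)
  })
  jsonlite::write_json(res, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' Load an image of a dataset as an (H, W, 3) array in [0, 1]
#' @param dataset a `bsd_dataset`.
#' @param image_id id from `dataset$images`.
#' @export
load_image <- function(dataset, image_id) {
  r <- dataset$images[dataset$images$id == image_id, ]
  if (nrow(r) == 0L) stop("unknown image id ", image_id)
  img <- png::readPNG(file.path(dataset$image_dir, r$file))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Letterbox an image to a fixed size
#'
#' Aspect-preserving bilinear resize followed by symmetric padding with
#' neutral gray (114/255). The returned transform record allows exact
#' inversion of box coordinates.
#'
#' @param image array (H, W, 3) (or (H, W)).
#' @param boxes optional data.frame with x1, y1, x2, y2 to transform along.
#' @param target `c(h, w)`, both >= 32.
#' @return list with `image`, `boxes`, `scale` (c(sy, sx)), `pad`
#'   (c(top, left)).
#' @export
letterbox <- function(image, boxes = NULL, target = c(640L, 640L)) {
  if (any(target < 32L)) stop("letterbox target must be >= 32")
  d <- dim(image)
  if (d[1] < 1L || d[2] < 1L) stop("zero-sized image")
  r <- min(target[1] / d[1], target[2] / d[2])
  nh <- max(1L, round(d[1] * r)); nw <- max(1L, round(d[2] * r))
  resized <- if (nh == d[1] && nw == d[2]) image else
    EBImage::resize(image, w = nh, h = nw)  # EBImage resizes dim1 -> w, dim2 -> h
  top <- (target[1] - nh) %/% 2L; left <- (target[2] - nw) %/% 2L
  canvas <- array(114 / 255, dim = c(target[1], target[2],
                                     if (length(d) == 3L) d[3] else 1L))
  if (length(d) == 2L) resized <- array(resized, dim = c(nh, nw, 1L))
  canvas[top + seq_len(nh), left + seq_len(nw), ] <- resized
  if (length(d) == 2L) canvas <- canvas[, , 1]
  sy <- nh / d[1]; sx <- nw / d[2]
  out_boxes <- NULL
  if (!is.null(boxes) && nrow(boxes) > 0) {
    out_boxes <- boxes
    out_boxes$x1 <- boxes$x1 * sx + left; out_boxes$x2 <- boxes$x2 * sx + left
    out_boxes$y1 <- boxes$y1 * sy + top; out_boxes$y2 <- boxes$y2 * sy + top
  } else if (!is.null(boxes)) out_boxes <- boxes
  list(image = canvas, boxes = out_boxes, scale = c(sy, sx),
       pad = c(top, left))
}

clip_boxes <- function(boxes, h, w, min_area = 1) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(boxes)
  boxes$x1 <- pmin(pmax(boxes$x1, 0), w); boxes$x2 <- pmin(pmax(boxes$x2, 0), w)
  boxes$y1 <- pmin(pmax(boxes$y1, 0), h); boxes$y2 <- pmin(pmax(boxes$y2, 0), h)
  keep <- (boxes$x2 - boxes$x1) * (boxes$y2 - boxes$y1) >= min_area
  boxes[keep, , drop = FALSE]
}

#' Mosaic augmentation
#'
#' Composites four annotated images into one canvas of the same size around
#' a random center; each source image is anchored at the center corner of
#' its quadrant and cropped to the canvas. Boxes are shifted/clipped and
#' dropped below 1 px^2. Deterministic given the RNG state (or `rng_seed`).
#'
#' @param images list of four arrays (H, W, 3), equal sizes.
#' @param boxes list of four data.frames (category, x1, y1, x2, y2).
#' @param rng_seed optional seed.
#' @param center optional fixed mosaic center `c(cy, cx)` in pixels;
#'   random in the central 40% of the canvas when NULL.
#' @return list `image`, `boxes`.
#' @export
mosaic_augment <- function(images, boxes, rng_seed = NULL, center = NULL) {
  if (length(images) < 4L) stop("mosaic needs four images, got ", length(images))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  d <- dim(images[[1]])
  h <- d[1]; w <- d[2]
  if (is.null(center)) {
    cy <- round(stats::runif(1, 0.3, 0.7) * h)
    cx <- round(stats::runif(1, 0.3, 0.7) * w)
  } else { cy <- center[1]; cx <- center[2] }
  canvas <- array(114 / 255, dim = d)
  out <- list()
  # quadrant q: 1 top-left, 2 top-right, 3 bottom-left, 4 bottom-right
  place <- function(q, img, bx) {
    qh <- if (q %in% c(1, 2)) cy else h - cy
    qw <- if (q %in% c(1, 3)) cx else w - cx
    if (qh < 1 || qw < 1) return(NULL)
    # anchor the image's corner nearest the mosaic center
    src_y <- if (q %in% c(1, 2)) (h - qh + 1):h else 1:qh
    src_x <- if (q %in% c(1, 3)) (w - qw + 1):w else 1:qw
    dst_y <- if (q %in% c(1, 2)) 1:qh else (cy + 1):h
    dst_x <- if (q %in% c(1, 3)) 1:qw else (cx + 1):w
    canvas[dst_y, dst_x, ] <<- img[src_y, src_x, ]
    if (is.null(bx) || nrow(bx) == 0L) return(NULL)
    dy <- dst_y[1] - src_y[1]; dx <- dst_x[1] - src_x[1]
    bx$x1 <- bx$x1 + dx; bx$x2 <- bx$x2 + dx
    bx$y1 <- bx$y1 + dy; bx$y2 <- bx$y2 + dy
    # clip to this quadrant's extent on the canvas
    bx$x1 <- pmax(bx$x1, dst_x[1] - 1); bx$x2 <- pmin(bx$x2, dst_x[length(dst_x)])
    bx$y1 <- pmax(bx$y1, dst_y[1] - 1); bx$y2 <- pmin(bx$y2, dst_y[length(dst_y)])
    bx[bx$x2 > bx$x1 & bx$y2 > bx$y1 &
         (bx$x2 - bx$x1) * (bx$y2 - bx$y1) >= 1, , drop = FALSE]
  }
  for (q in 1:4) out[[q]] <- place(q, images[[q]], boxes[[q]])
  all_boxes <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  list(image = canvas, boxes = all_boxes)
}

#' Random zoom and translation
#'
#' Applies a similarity transform (uniform zoom drawn from `zoom_range`,
#' translation up to `translate_range` of the image size) to pixels and
#' boxes alike; the image is resampled via bilinear resize and pasted at the
#' translated offset, degenerate boxes are dropped.
#'
#' @param image array (H, W, 3).
#' @param boxes data.frame (category, x1, y1, x2, y2) or NULL.
#' @param zoom_range length-2 positive range, default `c(0.5, 1.5)`.
#' @param translate_range max |shift| as a fraction of size in `[0, 1)`,
#'   default 0.1.
#' @param rng_seed optional seed.
#' @return list `image`, `boxes`.
#' @export
random_affine <- function(image, boxes = NULL, zoom_range = c(0.5, 1.5),
                          translate_range = 0.1, rng_seed = NULL) {
  if (length(zoom_range) != 2L || any(zoom_range <= 0))
    stop("zoom_range must be two positive numbers")
  if (translate_range < 0 || translate_range >= 1)
    stop("translate_range must be in [0, 1)")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  d <- dim(image)
  h <- d[1]; w <- d[2]
  z <- stats::runif(1, zoom_range[1], zoom_range[2])
  tx <- round(stats::runif(1, -translate_range, translate_range) * w)
  ty <- round(stats::runif(1, -translate_range, translate_range) * h)
  nh <- max(1L, round(h * z)); nw <- max(1L, round(w * z))
  zy <- nh / h; zx <- nw / w          # realized zoom after rounding
  zoomed <- if (nh == h && nw == w) image else EBImage::resize(image, w = nh, h = nw)
  canvas <- array(114 / 255, dim = d)
  # paste zoomed image centered, then shifted by (ty, tx)
  oy <- (h - nh) %/% 2L + ty; ox <- (w - nw) %/% 2L + tx
  src_y <- max(1L, 1L - oy):min(nh, h - oy)
  src_x <- max(1L, 1L - ox):min(nw, w - ox)
  if (length(src_y) > 0 && length(src_x) > 0 &&
      src_y[1] <= src_y[length(src_y)] && src_x[1] <= src_x[length(src_x)])
    canvas[src_y + oy, src_x + ox, ] <- zoomed[src_y, src_x, ]
  out_boxes <- NULL
  if (!is.null(boxes) && nrow(boxes) > 0) {
    out_boxes <- boxes
    out_boxes$x1 <- boxes$x1 * zx + ox; out_boxes$x2 <- boxes$x2 * zx + ox
    out_boxes$y1 <- boxes$y1 * zy + oy; out_boxes$y2 <- boxes$y2 * zy + oy
    out_boxes <- clip_boxes(out_boxes, h, w)
  } else if (!is.null(boxes)) out_boxes <- boxes
  list(image = canvas, boxes = out_boxes)
}
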