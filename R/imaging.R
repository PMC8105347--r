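#' Read a binary seed mask
#'
#' Masks are 8-bit PNG or TIFF images, one seed per image, foreground
#' (seed) strictly positive. Multi-channel images are reduced to their
#' first channel.
#'
#' @param path PNG or TIFF file.
#' @return Logical matrix, `TRUE` = foreground, in image row order.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop2("unsupported mask format: ", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
}

#' Trace the outline of a seed mask
#'
#' Extracts the closed boundary of the largest connected foreground
#' component as a sub-pixel contour at the 0.5 iso-level (marching
#' squares). Coordinates are 0-based pixel centers in mathematical y-up
#' convention: pixel (row r, col c) of an `nr`-row image sits at
#' (c - 1, nr - r). The outline is returned counterclockwise.
#'
#' Foreground touching the image border is kept but flagged via the
#' `border_touch` attribute (the mask is padded with background before
#' contouring so the boundary still closes).
#'
#' @param mask logical or 0/1 matrix, or a file path accepted by
#'   [read_mask()].
#' @param scale mm per pixel recorded on the outline.
#' @return An [outline()] in pixel units.
#' @export
extract_outline <- function(mask, scale = 1) {
  if (is.character(mask)) mask <- read_mask(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) stop2("empty mask: no foreground pixels")
  nr <- nrow(m); nc <- ncol(m)
  touches <- any(m[1, ] > 0) || any(m[nr, ] > 0) || any(m[, 1] > 0) || any(m[, nc] > 0)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  # orient z so that its first index runs along x (columns) and second along
  # y-up (flipped rows); grid lines at pixel centers, offset by the padding
  z <- t(pad)[, (nr + 2):1]
  cl <- grDevices::contourLines(x = seq_len(nc + 2) - 2, y = seq_len(nr + 2) - 2, z = z,
                                levels = 0.5)
  if (!length(cl)) stop2("no contour found at the 0.5 iso-level")
  areas <- vapply(cl, function(cc) {
    xs <- cc$x; ys <- cc$y
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) / 2)
  }, numeric(1))
  best <- cl[[which.max(areas)]]
  out <- outline(cbind(best$x, best$y), scale = scale, border_touch = touches)
  if (touches) warning("foreground touches the image border; outline flagged", call. = FALSE)
  ensure_ccw(out)
}

#' Bounding-box size of an oriented outline
#'
#' Under the acquisition convention (hilum to the right, broader part at
#' the bottom) seed length is the axis-aligned vertical extent -- the
#' landmark 4--5 axis -- and width the horizontal extent. The box is
#' axis-aligned by convention, so a rotated seed yields rotated extents;
#' this is exactly the behaviour of a rectangular measuring tool on an
#' oriented photograph.
#'
#' @param x an [outline()].
#' @return Named numeric `c(length_mm, width_mm)` (extents times the
#'   outline scale).
#' @export
bounding_box_size <- function(x) {
  p <- unclass(x)
  len <- diff(range(p[, 2])); wid <- diff(range(p[, 1]))
  if (len <= 0 || wid <= 0) stop2("degenerate outline: zero extent")
  s <- outline_scale(x)
  c(length_mm = len * s, width_mm = wid * s)
}

#' Landmark sets
#'
#' Five anchor points per seed image: landmarks 1--3 on the hilum arch and
#' 4 (top) / 5 (bottom) at the length extremes. Landmark 2 serves as the
#' outline start point.
#'
#' @param coords 5 x 2 numeric matrix, rows in landmark order 1..5.
#' @param image_id label of the source image.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, image_id = NA_character_) {
  coords <- as.matrix(coords)
  if (nrow(coords) != 5L || ncol(coords) != 2L)
    stop2("a landmark set has exactly 5 (x, y) points (image ", image_id, ")")
  storage.mode(coords) <- "double"
  structure(coords, image_id = image_id, class = c("landmark_set", "matrix"))
}

#' Read landmark files
#'
#' Two dialects are supported: CSV with columns `image,ldk,x,y` and TPS
#' (`LM=5` blocks with `IMAGE=` records). Coordinates are kept as stored;
#' both dialects are y-up by convention here (synthetic landmark files are
#' written in the same convention as the extracted outlines).
#'
#' @param path file to read.
#' @param dialect `"csv"`, `"tps"`, or `"auto"` (by file extension).
#' @return Named list of [landmark_set()] objects, one per image.
#' @export
read_landmarks <- function(path, dialect = c("auto", "csv", "tps")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "tps") "tps" else "csv"
  }
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("image", "ldk", "x", "y")
    if (!all(need %in% names(df))) stop2("landmark CSV needs columns image,ldk,x,y")
    sets <- lapply(split(df, df$image), function(d) {
      if (nrow(d) != 5L || !setequal(d$ldk, 1:5))
        stop2("image '", d$image[1], "' does not have exactly landmarks 1..5")
      d <- d[order(d$ldk), ]
      landmark_set(cbind(d$x, d$y), image_id = d$image[1])
    })
    return(sets[unique(df$image)])
  }
  # TPS: blocks of "LM=5", 5 coordinate lines, then ID=/IMAGE= records
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines)
  if (!length(starts)) stop2("no LM= records found in TPS file")
  bounds <- c(starts, length(lines) + 1L)
  sets <- list()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:(bounds[b + 1] - 1L)]
    n_lm <- as.integer(sub("^LM=", "", block[1]))
    if (is.na(n_lm) || n_lm != 5L)
      stop2("TPS block ", b, " has LM=", block[1], "; expected 5 landmarks")
    coords <- do.call(rbind, lapply(block[2:(n_lm + 1L)], function(l)
      as.numeric(strsplit(l, "[[:space:]]+")[[1]][1:2])))
    id_line <- grep("^(IMAGE|ID)=", block, value = TRUE)
    id <- if (length(id_line)) sub("^(IMAGE|ID)=", "", id_line[1]) else paste0("tps_", b)
    sets[[id]] <- landmark_set(coords, image_id = id)
  }
  sets
}

#' Write landmarks as CSV (`image,ldk,x,y`)
#' @param sets named list of [landmark_set()] objects.
#' @param path output CSV path.
#' @export
write_landmarks <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(image = attr(s, "image_id"), ldk = 1:5,
               x = unclass(s)[, 1], y = unclass(s)[, 2])))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read or write the descriptor table
#'
#' Per-specimen table with header `id,taxon,length,width,cells`; taxon is
#' a label or `"unknown"`. Lengths are in mm, `cells` is the surface cell
#' count of one seed face.
#' @param path CSV file.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "taxon", "length", "width", "cells")
  if (!all(need %in% names(df)))
    stop2("descriptor table needs columns ", paste(need, collapse = ","))
  df
}

#' @rdname read_descriptors
#' @param df descriptor data frame.
#' @export
write_descriptors <- function(df, path) utils::write.csv(df, path, row.names = FALSE)
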