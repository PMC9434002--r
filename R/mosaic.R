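# Serpentine scan planning and tile-volume stitching.
#
# Grid convention: row 1 is the bottom row, x increases rightward; the
# mosaic array is indexed [Y, X, Z] with Y ascending from the bottom.
# Placement depends only on (row, col); the visit order is acquisition
# metadata.

#' Plan a serpentine (snake) tile scan
#'
#' Covers a `width x height` mm extent with tiles of the given field of
#' view, reversing traversal direction on each row so consecutive tiles
#' are always grid-adjacent.
#'
#' @param width_mm,height_mm Scanned extent (each <= 100 mm).
#' @param tile_fov Tile field of view `c(x, y)` in mm (scalar recycled).
#' @param overlap Overlap between adjacent tiles (mm, >= 0, < tile fov).
#' @param origin Starting corner: `"lower-right"` (default, matching
#'   specimen placement at the lower-right cassette corner),
#'   `"lower-left"`, `"upper-left"`, or `"upper-right"`.
#' @return An object of class `scan_plan`: `rows`, `cols`, `tile_fov`,
#'   `overlap`, `origin`, `order` (data.frame of `row`, `col`, `x_mm`,
#'   `y_mm` in serpentine visit sequence; 1-based, row 1 = bottom),
#'   `width_mm`, `height_mm`.
#' @export
plan_snake_scan <- function(width_mm, height_mm, tile_fov = c(5, 5),
                            overlap = 0,
                            origin = c("lower-right", "lower-left",
                                       "upper-left", "upper-right")) {
  origin <- match.arg(origin)
  if (width_mm <= 0 || height_mm <= 0) stop("extent must be > 0")
  if (width_mm > 100 || height_mm > 100)
    stop("extent exceeds the 100 mm x 100 mm stage range")
  if (length(tile_fov) == 1) tile_fov <- rep(tile_fov, 2)
  stride <- tile_fov - overlap
  if (any(stride <= 0)) stop("overlap must be smaller than the tile FoV")
  if (overlap < 0) stop("overlap must be >= 0")
  cols <- max(1L, as.integer(ceiling(width_mm / stride[1])))
  rows <- max(1L, as.integer(ceiling(height_mm / stride[2])))

  row_seq <- if (grepl("^lower", origin)) seq_len(rows) else rev(seq_len(rows))
  start_right <- grepl("right$", origin)
  ord <- NULL
  for (i in seq_along(row_seq)) {
    cs <- seq_len(cols)
    # reverse on alternate rows; the first traversal runs away from the
    # origin corner's side
    rev_this <- xor(start_right, (i - 1) %% 2 == 1)
    if (rev_this) cs <- rev(cs)
    ord <- rbind(ord, data.frame(row = row_seq[i], col = cs))
  }
  ord$x_mm <- (ord$col - 1) * stride[1]
  ord$y_mm <- (ord$row - 1) * stride[2]
  structure(list(rows = rows, cols = cols, tile_fov = tile_fov,
                 overlap = overlap, origin = origin, order = ord,
                 width_mm = width_mm, height_mm = height_mm),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf(
    "scan plan: %d x %d tiles (%g x %g mm FoV, %g mm overlap), origin %s\n",
    x$rows, x$cols, x$tile_fov[1], x$tile_fov[2], x$overlap, x$origin))
  invisible(x)
}

#' Stitch reconstructed tile volumes into a mosaic
#'
#' Places each tile at its (row, col) grid position. With zero overlap
#' tiles abut with no blending; with positive overlap, `policy`
#' `"crop"` trims half the overlap from each inner tile edge and
#' `"average"` averages contributions in the overlap zones.
#'
#' @param volumes List of `oct_volume`s (one per plan cell, any order;
#'   matched by `tile_index`).
#' @param plan The [plan_snake_scan()] the tiles were acquired under.
#' @param policy Overlap policy, `"crop"` (default) or `"average"`.
#' @return An object of class `mosaic_volume`: `magnitude[Y, X, Z]`,
#'   `pitch`, `provenance_map[Y, X]` (linear tile id `(row-1)*cols + col`
#'   per lateral position), `plan`.
#' @export
stitch_tiles <- function(volumes, plan, policy = c("crop", "average")) {
  policy <- match.arg(policy)
  stopifnot(inherits(plan, "scan_plan"))
  key <- vapply(volumes, function(v) paste(v$tile_index, collapse = "_"), "")
  want <- paste(plan$order$row, plan$order$col, sep = "_")
  missing <- setdiff(want, key)
  if (length(missing))
    stop("missing tile(s) at (row,col): ",
         paste(gsub("_", ",", missing), collapse = "; "))
  d0 <- dim(volumes[[1]]$magnitude)
  p0 <- volumes[[1]]$pitch
  for (v in volumes) {
    if (!identical(dim(v$magnitude), d0)) stop("tile shape mismatch")
    if (abs(v$pitch$x_mm - p0$x_mm) > 1e-12 ||
        abs(v$pitch$y_mm - p0$y_mm) > 1e-12)
      stop("tile pitch mismatch")
  }
  B <- d0[1]; A <- d0[2]; Z <- d0[3]
  ox <- as.integer(round(plan$overlap / p0$x_mm))
  oy <- as.integer(round(plan$overlap / p0$y_mm))
  if (ox >= A || oy >= B) stop("overlap larger than a tile")

  if (plan$overlap == 0 || policy == "crop") {
    # trims: half the overlap from each inner edge (outer edges kept)
    txl <- floor(ox / 2); txr <- ox - txl
    tyl <- floor(oy / 2); tyr <- oy - tyl
    xs <- A - ox; ys <- B - oy            # interior tile extent
    X <- plan$cols * A - (plan$cols - 1) * ox
    Y <- plan$rows * B - (plan$rows - 1) * oy
    out <- array(0, dim = c(Y, X, Z))
    prov <- matrix(0L, Y, X)
    for (v in volumes) {
      r <- v$tile_index[1]; c <- v$tile_index[2]
      a_lo <- if (c == 1) 1 else txl + 1
      a_hi <- if (c == plan$cols) A else A - txr
      b_lo <- if (r == 1) 1 else tyl + 1
      b_hi <- if (r == plan$rows) B else B - tyr
      x0 <- (c - 1) * (A - ox)
      y0 <- (r - 1) * (B - oy)
      yi <- y0 + b_lo:b_hi
      xi <- x0 + a_lo:a_hi
      out[yi, xi, ] <- v$magnitude[b_lo:b_hi, a_lo:a_hi, ]
      prov[yi, xi] <- (r - 1L) * plan$cols + c
    }
  } else {                                # average
    X <- plan$cols * A - (plan$cols - 1) * ox
    Y <- plan$rows * B - (plan$rows - 1) * oy
    out <- array(0, dim = c(Y, X, Z))
    wt <- matrix(0, Y, X)
    prov <- matrix(0L, Y, X)
    for (v in volumes) {
      r <- v$tile_index[1]; c <- v$tile_index[2]
      xi <- (c - 1) * (A - ox) + seq_len(A)
      yi <- (r - 1) * (B - oy) + seq_len(B)
      out[yi, xi, ] <- out[yi, xi, ] + v$magnitude
      wt[yi, xi] <- wt[yi, xi] + 1
      prov[yi, xi] <- (r - 1L) * plan$cols + c
    }
    out <- sweep(out, c(1, 2), wt, "/")
  }
  structure(list(magnitude = out,
                 pitch = list(x_mm = p0$x_mm, y_mm = p0$y_mm,
                              z_um = p0$z_um),
                 provenance_map = prov, plan = plan,
                 provenance = list(policy = if (plan$overlap == 0) "abut"
                                   else policy)),
            class = "mosaic_volume")
}

#' @export
print.mosaic_volume <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("mosaic volume [%d x %d x %d] from %d x %d tiles (%s)\n",
              d[1], d[2], d[3], x$plan$rows, x$plan$cols,
              x$provenance$policy))
  invisible(x)
}

#' Split a volume into a tile grid (inverse of zero-overlap stitching)
#'
#' Partitions a `[Y, X, Z]` array into `rows x cols` equal tiles and wraps
#' each as an `oct_volume` with the matching `tile_index`, so that
#' [stitch_tiles()] with a zero-overlap plan reproduces the input exactly.
#'
#' @param arr Numeric array `[Y, X, Z]`; Y and X must be divisible by
#'   `rows` and `cols`.
#' @param rows,cols Grid shape.
#' @param pitch Voxel pitch list (`x_mm`, `y_mm`, `z_um`).
#' @return List of `oct_volume`s in row-major order.
#' @export
split_into_tiles <- function(arr, rows, cols,
                             pitch = list(x_mm = 1, y_mm = 1, z_um = 1)) {
  d <- dim(arr)
  if (d[1] %% rows != 0 || d[2] %% cols != 0)
    stop("array extent not divisible by the grid shape")
  B <- d[1] %/% rows; A <- d[2] %/% cols
  tiles <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    sub <- arr[(r - 1) * B + seq_len(B), (c - 1) * A + seq_len(A), ,
               drop = FALSE]
    tiles[[length(tiles) + 1]] <- structure(
      list(magnitude = sub, pitch = pitch, tile_index = c(r, c),
           stage_xy = c((c - 1) * A * pitch$x_mm, (r - 1) * B * pitch$y_mm),
           provenance = list(split = TRUE)),
      class = "oct_volume")
  }
  tiles
}
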