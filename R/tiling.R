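#' Split a raster into square tiles
#'
#' A normalized 1536 x 1536 frame splits into a 6 x 6 grid of
#' 256 x 256-pixel tiles (10 x 10 cm each); network training and
#' prediction operate on these tiles. Tiles are disjoint, cover the
#' raster exactly, and are ordered row-major (left to right, then top to
#' bottom) -- the canonical "original order" used for reassembly.
#'
#' @param raster Matrix or `H x W x C` array, or a [trench_image()] /
#'   [root_mask()]. Both spatial dimensions must be divisible by
#'   `tile_px`.
#' @param tile_px Tile edge in pixels (default 256).
#' @return A `tile_grid`: list with `tiles` (row-major list of rasters),
#'   `tile_px`, `grid` (rows, cols) and `dims` of the source.
#' @export
split_tiles <- function(raster, tile_px = 256L) {
  px <- as_pixels(raster)
  d <- dim(px)
  H <- d[1]; W <- d[2]
  if (H %% tile_px != 0L || W %% tile_px != 0L)
    stop(sprintf("raster %d x %d is not divisible into %d-px tiles", H, W, tile_px))
  gr <- H %/% tile_px; gc <- W %/% tile_px
  tiles <- vector("list", gr * gc)
  k <- 1L
  for (tr in seq_len(gr)) {
    rows <- ((tr - 1L) * tile_px + 1L):(tr * tile_px)
    for (tc in seq_len(gc)) {
      cols <- ((tc - 1L) * tile_px + 1L):(tc * tile_px)
      tiles[[k]] <- if (length(d) == 3L) px[rows, cols, , drop = FALSE]
                    else px[rows, cols, drop = FALSE]
      k <- k + 1L
    }
  }
  structure(list(tiles = tiles, tile_px = as.integer(tile_px),
                 grid = c(gr, gc), dims = d),
            class = "tile_grid")
}

#' Reassemble tiles into the source raster
#'
#' Inverse of [split_tiles()]: `assemble_tiles(split_tiles(x))` is
#' bit-identical to `x`.
#'
#' @param grid A `tile_grid`, or a plain row-major list of equally sized
#'   tiles together with `grid_dim`.
#' @param grid_dim Grid shape `c(rows, cols)` when `grid` is a bare list.
#' @return The reassembled raster.
#' @export
assemble_tiles <- function(grid, grid_dim = NULL) {
  if (inherits(grid, "tile_grid")) {
    tiles <- grid$tiles; gd <- grid$grid
  } else {
    tiles <- grid; gd <- grid_dim
    if (is.null(gd)) stop("grid_dim is required for a bare tile list")
  }
  if (length(tiles) != gd[1] * gd[2])
    stop(sprintf("expected %d tiles, got %d", gd[1] * gd[2], length(tiles)))
  d1 <- dim(tiles[[1]])
  for (t in tiles)
    if (!identical(dim(t), d1)) stop("inconsistent tile shapes")
  tp_r <- d1[1]; tp_c <- d1[2]
  has_ch <- length(d1) == 3L
  out <- if (has_ch) array(0, c(gd[1] * tp_r, gd[2] * tp_c, d1[3]))
         else matrix(tiles[[1]][1] * 0, gd[1] * tp_r, gd[2] * tp_c)
  k <- 1L
  for (tr in seq_len(gd[1])) {
    rows <- ((tr - 1L) * tp_r + 1L):(tr * tp_r)
    for (tc in seq_len(gd[2])) {
      cols <- ((tc - 1L) * tp_c + 1L):(tc * tp_c)
      if (has_ch) out[rows, cols, ] <- tiles[[k]]
      else out[rows, cols] <- tiles[[k]]
      k <- k + 1L
    }
  }
  if (!has_ch && is.integer(tiles[[1]])) storage.mode(out) <- "integer"
  out
}
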