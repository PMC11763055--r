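#' Direction displacements
#'
#' The eight unit displacements a moving object can take between frame t and
#' frame t+1, enumerated as the 3x3 neighbours of a pixel in reading order
#' (row 0 at top), skipping the centre: 1 = up-left, 2 = up, 3 = up-right,
#' 4 = left, 5 = right, 6 = down-left, 7 = down, 8 = down-right.
#'
#' @return An 8x2 integer matrix of (row, col) offsets, one row per direction.
#' @export
direction_displacements <- function() {
  m <- rbind(
    c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, -1L), c(0L, 1L),
    c(1L, -1L), c(1L, 0L), c(1L, 1L)
  )
  dimnames(m) <- list(NULL, c("drow", "dcol"))
  m
}

# Receptive-field slot index (1..9, reading order over the 3x3 field,
# slot 5 = centre) that a given direction's displaced pixel occupies.
.slot_of_direction <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)

.all_configs <- c("DL", "DR", "LD", "LL", "LR", "RD", "RL", "RR")

.category_of <- c(D = "dark", L = "constant", R = "random")

#' Declarative description of a synthetic moving-object dataset
#'
#' Describes what [generate_dataset()] should simulate: frame geometry, the
#' object--background configurations, object sizes, the number of image pairs
#' per motion direction, and the random seed. The benchmark defaults are
#' 32x32 RGB frames, all eight configurations, object sizes
#' {1, 2, 4, 8, 16, 32, 64, 128} and 500 pairs per direction per size, i.e.
#' 4000 pairs per configuration and size.
#'
#' Configuration labels pair an object category with a background category:
#' first letter = object, second = background, with D = dark (all channels 0),
#' L = light (one constant random RGB triplet, each channel uniform on
#' 1..255), R = random (every pixel and channel independent uniform on
#' 0..255). DD is meaningless (invisible object) and rejected.
#'
#' @param image_height,image_width Frame dimensions in pixels.
#' @param configurations Character vector, subset of
#'   `c("DL","DR","LD","LL","LR","RD","RL","RR")`.
#' @param object_sizes Integer vector of object pixel counts.
#' @param pairs_per_direction Pairs generated per direction, size and
#'   configuration.
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `avs_dataset_spec`.
#' @export
dataset_spec <- function(image_height = 32L, image_width = 32L,
                         configurations = .all_configs,
                         object_sizes = c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L),
                         pairs_per_direction = 500L,
                         seed = 1L) {
  image_height <- as.integer(image_height)
  image_width <- as.integer(image_width)
  if (image_height < 3L || image_width < 3L)
    stop("frames must be at least 3x3 pixels")
  configurations <- as.character(configurations)
  if (length(configurations) == 0L) stop("configurations must be non-empty")
  if ("DD" %in% configurations)
    stop("configuration DD (dark object on dark background) is not allowed")
  bad <- setdiff(configurations, .all_configs)
  if (length(bad) > 0L)
    stop("unknown configuration(s): ", paste(bad, collapse = ", "))
  object_sizes <- as.integer(object_sizes)
  interior <- (image_height - 2L) * (image_width - 2L)
  if (any(object_sizes < 1L) || any(object_sizes > interior))
    stop("object sizes must lie in [1, ", interior,
         "] so the object plus any unit shift fits in-grid")
  pairs_per_direction <- as.integer(pairs_per_direction)
  if (pairs_per_direction < 1L) stop("pairs_per_direction must be >= 1")
  structure(
    list(image_height = image_height, image_width = image_width,
         configurations = configurations, object_sizes = object_sizes,
         pairs_per_direction = pairs_per_direction, seed = as.integer(seed)),
    class = "avs_dataset_spec"
  )
}

#' Grow a connected object mask
#'
#' Grows a 4-connected region of exactly `size` cells by seeded random
#' accretion: the start cell is uniform over the eligible area, then a uniform
#' random unfilled 4-neighbour of the region is added until the target size is
#' reached. Cells keep a one-pixel margin to every grid edge so that any of
#' the eight unit shifts stays in bounds.
#'
#' Uses the current R random-number state; callers seed via [set.seed()].
#'
#' @param size Number of object pixels.
#' @param image_height,image_width Grid dimensions.
#' @return A `size`x2 integer matrix of 1-based (row, col) positions.
#' @export
grow_object_mask <- function(size, image_height, image_width) {
  size <- as.integer(size)
  h <- as.integer(image_height); w <- as.integer(image_width)
  if (h < 3L || w < 3L) stop("grid too small for a margin of one pixel")
  interior <- (h - 2L) * (w - 2L)
  if (size < 1L || size > interior)
    stop("object size ", size, " impossible on a ", h, "x", w,
         " grid with a one-pixel margin (max ", interior, ")")
  # occupancy over the interior lattice rows 2..h-1, cols 2..w-1
  occ <- matrix(FALSE, h, w)
  # sample.int indexing avoids sample()'s length-1 "convenience" expansion
  start_r <- (2:(h - 1L))[sample.int(h - 2L, 1L)]
  start_c <- (2:(w - 1L))[sample.int(w - 2L, 1L)]
  occ[start_r, start_c] <- TRUE
  cells <- matrix(c(start_r, start_c), 1L, 2L)
  if (size > 1L) {
    nb <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    # frontier as a matrix of candidate cells (may contain duplicates; we
    # filter on occupancy at draw time)
    frontier <- matrix(integer(0), 0L, 2L)
    add_frontier <- function(r, c) {
      cand <- cbind(r + nb[, 1L], c + nb[, 2L])
      keep <- cand[, 1L] >= 2L & cand[, 1L] <= h - 1L &
        cand[, 2L] >= 2L & cand[, 2L] <= w - 1L
      rbind(frontier, cand[keep, , drop = FALSE])
    }
    frontier <- add_frontier(start_r, start_c)
    while (nrow(cells) < size) {
      free <- !occ[frontier]
      frontier <- frontier[free, , drop = FALSE]
      frontier <- frontier[!duplicated(frontier), , drop = FALSE]
      k <- sample.int(nrow(frontier), 1L)
      r <- frontier[k, 1L]; c <- frontier[k, 2L]
      occ[r, c] <- TRUE
      cells <- rbind(cells, c(r, c))
      frontier <- frontier[-k, , drop = FALSE]
      frontier <- add_frontier(r, c)
    }
  }
  colnames(cells) <- c("row", "col")
  cells
}

#' Sample region colours by category
#'
#' Draws per-cell RGB triplets for one of the three benchmark colour
#' categories: `"dark"` sets every value to 0; `"constant"` draws one triplet
#' (each channel uniform on 1..255) shared by all cells; `"random"` draws
#' every cell and channel independently uniform on 0..255.
#'
#' @param category One of `"dark"`, `"constant"`, `"random"`.
#' @param n_cells Number of cells to colour.
#' @return An `n_cells`x3 integer matrix of intensities in 0..255.
#' @export
sample_region_colors <- function(category, n_cells) {
  n_cells <- as.integer(n_cells)
  switch(category,
    dark = matrix(0L, n_cells, 3L),
    constant = matrix(rep(sample(1:255, 3L, replace = TRUE), each = n_cells),
                      n_cells, 3L),
    random = matrix(sample(0:255, 3L * n_cells, replace = TRUE), n_cells, 3L),
    stop("unknown colour category: ", category)
  )
}

#' Render a two-frame motion pair
#'
#' Paints the static background, places the object at `mask` in frame t and at
#' the shifted mask in frame t+1 (vacated cells revert to the background), and
#' records the direction label.
#'
#' @param mask `n`x2 matrix of object (row, col) positions at time t.
#' @param object_colors `n`x3 matrix of object RGB intensities.
#' @param background `h`x`w`x3 array of background RGB intensities.
#' @param direction Integer direction label in 1..8 (see
#'   [direction_displacements()]).
#' @param config,object_size Metadata recorded on the pair.
#' @return An object of class `avs_frame_pair` with fields `frame_t`,
#'   `frame_t1` (h x w x 3 integer arrays), `direction`, `config`,
#'   `object_size` and `mask`.
#' @export
render_motion_pair <- function(mask, object_colors, background, direction,
                               config = NA_character_, object_size = nrow(mask)) {
  h <- dim(background)[1L]; w <- dim(background)[2L]
  d <- direction_displacements()[direction, ]
  shifted <- cbind(mask[, 1L] + d[1L], mask[, 2L] + d[2L])
  if (any(shifted[, 1L] < 1L | shifted[, 1L] > h |
          shifted[, 2L] < 1L | shifted[, 2L] > w))
    stop("unit shift in direction ", direction, " leaves the grid")
  frame_t <- background
  frame_t1 <- background
  for (ch in 1:3) {
    frame_t[cbind(mask, ch)] <- object_colors[, ch]
    frame_t1[cbind(shifted, ch)] <- object_colors[, ch]
  }
  structure(
    list(frame_t = frame_t, frame_t1 = frame_t1,
         direction = as.integer(direction), config = config,
         object_size = as.integer(object_size), mask = mask),
    class = "avs_frame_pair"
  )
}

.render_background <- function(category, h, w) {
  cols <- sample_region_colors(category, h * w)
  array(cols, dim = c(h, w, 3L))
}

#' Generate a synthetic moving-object dataset
#'
#' For every configuration, object size and direction in the spec, grows a
#' connected object, colours object and background by their categories, and
#' renders `pairs_per_direction` frame pairs in which the object translates by
#' one pixel while the background stays static. When both object and
#' background are the "constant" category and happen to draw the identical
#' triplet (an invisible object), the background triplet is redrawn.
#' Generation is deterministic given `spec$seed`.
#'
#' @param spec An [dataset_spec()] object.
#' @return An object of class `avs_dataset`: a list with `pairs` (list of
#'   [render_motion_pair()] results) and `manifest` (a data.frame with columns
#'   id, config, object_size, direction).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "avs_dataset_spec"))
  set.seed(spec$seed)
  h <- spec$image_height; w <- spec$image_width
  pairs <- vector("list",
                  length(spec$configurations) * length(spec$object_sizes) *
                    8L * spec$pairs_per_direction)
  k <- 0L
  for (config in spec$configurations) {
    obj_cat <- .category_of[[substr(config, 1L, 1L)]]
    bg_cat <- .category_of[[substr(config, 2L, 2L)]]
    for (size in spec$object_sizes) {
      for (m in 1:8) {
        for (rep in seq_len(spec$pairs_per_direction)) {
          mask <- grow_object_mask(size, h, w)
          obj_cols <- sample_region_colors(obj_cat, size)
          bg <- .render_background(bg_cat, h, w)
          if (obj_cat == "constant" && bg_cat == "constant") {
            while (all(bg[1L, 1L, ] == obj_cols[1L, ]))
              bg <- .render_background(bg_cat, h, w)
          }
          k <- k + 1L
          pairs[[k]] <- render_motion_pair(mask, obj_cols, bg, m,
                                           config = config, object_size = size)
        }
      }
    }
  }
  manifest <- data.frame(
    id = seq_len(k),
    config = vapply(pairs, `[[`, character(1L), "config"),
    object_size = vapply(pairs, `[[`, integer(1L), "object_size"),
    direction = vapply(pairs, `[[`, integer(1L), "direction")
  )
  structure(list(pairs = pairs, manifest = manifest, spec = spec),
            class = "avs_dataset")
}

#' @export
print.avs_dataset <- function(x, ...) {
  cat("avs_dataset:", length(x$pairs), "frame pairs,",
      x$spec$image_height, "x", x$spec$image_width, "px\n")
  cat("  configurations:", paste(unique(x$manifest$config), collapse = " "), "\n")
  cat("  object sizes:", paste(sort(unique(x$manifest$object_size)),
                               collapse = " "), "\n")
  invisible(x)
}

#' Write / read a dataset as PNG frames plus a CSV manifest
#'
#' `write_dataset()` stores each frame as a lossless 8-bit RGB PNG and a
#' manifest CSV with columns id, config, object_size, direction, frame_t_path,
#' frame_t1_path. `read_dataset()` reverses it; the round trip reproduces
#' intensity grids bit-exactly and labels exactly.
#'
#' @param dataset An `avs_dataset`.
#' @param directory Target directory (created if missing).
#' @return `write_dataset()` the manifest path, invisibly; `read_dataset()` an
#'   `avs_dataset` (without the `mask` field, which is not persisted).
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "avs_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$pairs)
  ft <- file.path(directory, sprintf("pair%05d_t.png", seq_len(n)))
  ft1 <- file.path(directory, sprintf("pair%05d_t1.png", seq_len(n)))
  for (i in seq_len(n)) {
    png::writePNG(dataset$pairs[[i]]$frame_t / 255, ft[i])
    png::writePNG(dataset$pairs[[i]]$frame_t1 / 255, ft1[i])
  }
  manifest <- dataset$manifest
  manifest$frame_t_path <- basename(ft)
  manifest$frame_t1_path <- basename(ft1)
  path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(directory) {
  path <- file.path(directory, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under ", directory)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "config", "object_size", "direction",
            "frame_t_path", "frame_t1_path")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0L)
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  read_frame <- function(p, row_id) {
    full <- file.path(directory, p)
    if (!file.exists(full))
      stop("manifest row id=", row_id, ": missing frame file ", p)
    img <- png::readPNG(full)
    if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
      stop("manifest row id=", row_id, ": ", p, " is not an RGB image")
    array(as.integer(round(img * 255)), dim = dim(img))
  }
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    structure(
      list(frame_t = read_frame(manifest$frame_t_path[i], manifest$id[i]),
           frame_t1 = read_frame(manifest$frame_t1_path[i], manifest$id[i]),
           direction = as.integer(manifest$direction[i]),
           config = manifest$config[i],
           object_size = as.integer(manifest$object_size[i]),
           mask = NULL),
      class = "avs_frame_pair")
  })
  h <- dim(pairs[[1L]]$frame_t)[1L]; w <- dim(pairs[[1L]]$frame_t)[2L]
  spec <- dataset_spec(h, w,
                       configurations = unique(manifest$config),
                       object_sizes = sort(unique(manifest$object_size)),
                       pairs_per_direction = 1L)
  structure(list(pairs = pairs,
                 manifest = manifest[, need],
                 spec = spec),
            class = "avs_dataset")
}
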