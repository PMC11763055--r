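test_that("object masks are 4-connected, sized exactly, and keep the margin", {
  for (case in list(c(1L, 5L, 5L), c(5L, 5L, 5L), c(16L, 12L, 9L),
                    c(128L, 32L, 32L))) {
    set.seed(sum(case))
    mask <- grow_object_mask(case[1L], case[2L], case[3L])
    expect_equal(nrow(mask), case[1L])
    expect_equal(flood_fill_count(mask), case[1L])
    expect_true(all(mask[, 1L] >= 2L & mask[, 1L] <= case[2L] - 1L))
    expect_true(all(mask[, 2L] >= 2L & mask[, 2L] <= case[3L] - 1L))
    expect_false(any(duplicated(mask)))
  }
})

test_that("impossible mask sizes are rejected", {
  expect_error(grow_object_mask(0, 8, 8), "size")
  expect_error(grow_object_mask(37, 8, 8), "impossible")
  expect_error(grow_object_mask(1, 2, 8), "margin")
})

test_that("colour categories follow their sampling laws", {
  set.seed(1)
  expect_equal(sample_region_colors("dark", 10), matrix(0L, 10, 3))
  cc <- sample_region_colors("constant", 10)
  expect_true(all(cc >= 1L & cc <= 255L))
  expect_equal(nrow(unique(cc)), 1L)
  rr <- sample_region_colors("random", 10000)
  se <- sqrt((256^2 - 1) / 12 / 10000)  # sd of a discrete uniform mean
  expect_true(all(abs(colMeans(rr) - 127.5) < 3 * se))
  expect_error(sample_region_colors("bright", 3), "unknown")
})

test_that("rendering translates the object and leaves the background static", {
  bg <- array(7L, c(6, 6, 3))
  pair <- render_motion_pair(matrix(c(3L, 3L), 1), matrix(255L, 1, 3), bg, 2L)
  expect_equal(pair$frame_t[3, 3, ], c(255L, 255L, 255L))
  expect_equal(pair$frame_t1[2, 3, ], c(255L, 255L, 255L))
  expect_equal(pair$frame_t1[3, 3, ], c(7L, 7L, 7L))  # vacated cell reverts
  moved <- rbind(c(3L, 3L), c(2L, 3L))
  untouched <- pair$frame_t
  for (k in 1:2) untouched[moved[k, 1L], moved[k, 2L], ] <- NA
  untouched1 <- pair$frame_t1
  for (k in 1:2) untouched1[moved[k, 1L], moved[k, 2L], ] <- NA
  expect_identical(untouched, untouched1)
  # a shift off the grid errors
  expect_error(
    render_motion_pair(matrix(c(1L, 3L), 1), matrix(255L, 1, 3), bg, 2L),
    "leaves the grid")
})

test_that("dataset counts and determinism follow the spec of the generator", {
  sp <- dataset_spec(12, 12, configurations = c("DL", "RR"),
                     object_sizes = c(2L, 4L), pairs_per_direction = 2L,
                     seed = 9)
  ds <- generate_dataset(sp)
  expect_length(ds$pairs, 2 * 2 * 8 * 2)
  expect_equal(nrow(ds$manifest), length(ds$pairs))
  expect_equal(as.vector(table(ds$manifest$direction)), rep(8L, 8))
  ds2 <- generate_dataset(sp)
  expect_identical(ds$pairs, ds2$pairs)
})

test_that("spec validation rejects DD, empty configs and oversize objects", {
  expect_error(dataset_spec(configurations = character(0)), "non-empty")
  expect_error(dataset_spec(configurations = "DD"), "DD")
  expect_error(dataset_spec(configurations = "XY"), "unknown")
  expect_error(dataset_spec(8, 8, object_sizes = 999), "object sizes")
  expect_error(dataset_spec(pairs_per_direction = 0), "pairs_per_direction")
})

test_that("generated labels are recoverable by exhaustive shift matching", {
  sp <- dataset_spec(10, 10, configurations = c("DL", "LD"),
                     object_sizes = 6L, pairs_per_direction = 2L, seed = 21)
  ds <- generate_dataset(sp)
  disp <- direction_displacements()
  for (pair in ds$pairs) {
    matches <- vapply(1:8, function(m) {
      sh <- cbind(pair$mask[, 1L] + disp[m, 1L], pair$mask[, 2L] + disp[m, 2L])
      if (any(sh < 1L | sh[, 1L] > 10L | sh[, 2L] > 10L)) return(FALSE)
      all(vapply(1:3, function(ch)
        all(pair$frame_t1[cbind(sh, ch)] == pair$frame_t[cbind(pair$mask, ch)]),
        logical(1L)))
    }, logical(1L))
    expect_true(matches[pair$direction])
  }
})

test_that("generated pairs satisfy the frame-pair invariants across seeds", {
  for (seed in c(3, 14)) {
    sp <- dataset_spec(10, 10, configurations = c("LL", "RD"),
                       object_sizes = c(1L, 5L), pairs_per_direction = 1L,
                       seed = seed)
    ds <- generate_dataset(sp)
    disp <- direction_displacements()
    for (pair in ds$pairs) {
      expect_true(all(pair$frame_t >= 0L & pair$frame_t <= 255L))
      expect_equal(nrow(pair$mask), pair$object_size)
      expect_equal(flood_fill_count(pair$mask), pair$object_size)
      d <- disp[pair$direction, ]
      sh <- cbind(pair$mask[, 1L] + d[1L], pair$mask[, 2L] + d[2L])
      expect_true(all(sh >= 1L & sh <= 10L))
      # pixels outside mask and shifted mask are identical across frames
      touched <- rbind(pair$mask, sh)
      f1 <- pair$frame_t; f2 <- pair$frame_t1
      for (k in seq_len(nrow(touched)))
        f1[touched[k, 1L], touched[k, 2L], ] <-
          f2[touched[k, 1L], touched[k, 2L], ] <- NA
      expect_identical(f1, f2)
      if (pair$config == "LL") {
        # resampling guarantees a visible object
        obj <- pair$frame_t[cbind(pair$mask[1L, 1L], pair$mask[1L, 2L], 1:3)]
        far <- which(is.na(f1[, , 1L]) == FALSE, arr.ind = TRUE)[1L, ]
        expect_false(all(obj == pair$frame_t[cbind(far[1L], far[2L], 1:3)]))
      }
    }
  }
})

test_that("PNG + manifest round trip reproduces frames and labels exactly", {
  sp <- dataset_spec(8, 8, configurations = "RL", object_sizes = 3L,
                     pairs_per_direction = 1L, seed = 4)
  ds <- generate_dataset(sp)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_equal(nrow(utils::read.csv(file.path(dir, "manifest.csv"))),
               length(ds$pairs))
  back <- read_dataset(dir)
  expect_length(back$pairs, length(ds$pairs))
  for (i in seq_along(ds$pairs)) {
    expect_identical(back$pairs[[i]]$frame_t, ds$pairs[[i]]$frame_t)
    expect_identical(back$pairs[[i]]$frame_t1, ds$pairs[[i]]$frame_t1)
    expect_identical(back$pairs[[i]]$direction, ds$pairs[[i]]$direction)
  }
  # corrupt manifest: missing column
  m <- utils::read.csv(file.path(dir, "manifest.csv"))
  utils::write.csv(m[, setdiff(names(m), "direction")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "missing column")
})
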