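test_that("bit packing matches the bit-level oracle and documented examples", {
  frame <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
                  nrow = 1, byrow = TRUE)
  expect_identical(pack_bits(frame), as.raw(c(0x81, 0x00)))  # padded to even
  zeros <- matrix(FALSE, 3, 3)
  expect_identical(pack_bits(zeros), as.raw(c(0, 0)))  # 9 bits -> 2 bytes
  set.seed(2)
  for (i in 1:10) {
    dims <- c(sample(1:5, 1), sample(1:9, 1), sample(1:9, 1))
    x <- array(stats::runif(prod(dims)) > 0.5, dims)
    bits <- unlist(lapply(seq_len(dims[1]), function(f) as.vector(t(x[f, , ]))))
    expect_identical(pack_bits(x), oracle_pack_bits(bits))
    expect_identical(unpack_bits(pack_bits(x), dims[1], dims[2], dims[3]), x)
  }
  expect_error(unpack_bits(as.raw(c(0, 0)), 2, 7, 3), "framing")
  expect_error(pack_bits(matrix(1, 2, 2)), "logical")
})

test_that("a 16x16 single-segment binary frame packs to 32 bytes", {
  ct <- make_ct(n_slices = 1)
  mask <- array(FALSE, c(1, 16, 16)); mask[1, 1:4, 1:4] <- TRUE
  seg <- encode_segmentation(mask, ct, list(tumor_description()),
                             segmentation_params("BINARY"))
  expect_identical(length(ds_get(seg, "PixelData")), 32L)  # ceil(256/8)
})

test_that("fractional quantization is round-half-up of p * max", {
  ct <- make_ct(n_slices = 1)
  probs <- array(0.5, c(1, 16, 16))
  seg <- encode_segmentation(probs, ct, list(tumor_description()),
                             segmentation_params("FRACTIONAL", "PROBABILITY"))
  vals <- unique(as.integer(ds_get(seg, "PixelData")))
  expect_identical(vals, 128L)  # floor(0.5*255 + 0.5)
  # quantization oracle across the full probability grid
  p <- seq(0, 1, by = 1 / 512)
  expect_identical(dcmannot:::quantize_fractional(p, 255L),
                   as.integer(floor(p * 255 + 0.5)))
})

test_that("label maps encode one frame per present segment", {
  ct <- make_ct(n_slices = 1)
  lab <- array(0L, c(1, 16, 16))
  lab[1, 2:4, 2:4] <- 1L
  lab[1, 9:12, 9:12] <- 2L
  seg <- encode_segmentation(lab, ct,
                             list(tumor_description(1, "tumor"),
                                  tumor_description(2, "nodule")),
                             segmentation_params("BINARY"))
  expect_identical(ds_get(seg, "NumberOfFrames"), 2L)
  expect_identical(n_errors(validate_sop(seg, "segmentation")), 0L)
})

test_that("encoder rejects inconsistent inputs", {
  ct <- make_ct(n_slices = 1)
  probs <- array(0.5, c(1, 16, 16))
  expect_error(encode_segmentation(probs, ct, list(tumor_description()),
                                   segmentation_params("BINARY")),
               "FRACTIONAL")
  bad <- array(1.5, c(1, 16, 16))
  expect_error(encode_segmentation(bad, ct, list(tumor_description()),
                                   segmentation_params("FRACTIONAL", "PROBABILITY")),
               "\\[0, 1\\]")
  lab <- array(3L, c(1, 16, 16))
  expect_error(encode_segmentation(lab, ct, list(tumor_description()),
                                   segmentation_params("BINARY")),
               "descriptions")
  empty <- array(FALSE, c(1, 16, 16))
  expect_error(encode_segmentation(empty, ct, list(tumor_description()),
                                   segmentation_params("BINARY")),
               "omit_empty_frames")
  # disabling omission makes the all-background object legal
  seg <- encode_segmentation(empty, ct, list(tumor_description()),
                             segmentation_params("BINARY",
                                                 omit_empty_frames = FALSE))
  expect_identical(ds_get(seg, "NumberOfFrames"), 1L)
  expect_error(segmentation_params("FRACTIONAL"), "fractional_type")
  expect_error(segmentation_params("BINARY", max_fractional_value = 0))
})

test_that("segment filtering intersects label, codes and tracking UIDs", {
  ct <- make_ct(n_slices = 1)
  lab <- array(0L, c(1, 16, 16))
  lab[1, 1:2, 1:2] <- 1L; lab[1, 5:6, 5:6] <- 2L; lab[1, 10:11, 10:11] <- 3L
  uid3 <- "2.25.4242"
  descs <- list(
    segment_description(1, "tumor-a", sct("MorphologicallyAbnormalStructure"),
                        sct("Tumor"), "AUTOMATIC", list(name = "m")),
    segment_description(2, "normal", sct("BodyStructure"),
                        sct("Normal"), "AUTOMATIC", list(name = "m")),
    segment_description(3, "tumor-b", sct("MorphologicallyAbnormalStructure"),
                        sct("Tumor"), "AUTOMATIC", list(name = "m"),
                        tracking_id = "T3", tracking_uid = uid3))
  seg <- encode_segmentation(lab, ct, descs, segmentation_params("BINARY"))
  expect_identical(find_segments(seg), c(1L, 2L, 3L))
  expect_identical(find_segments(seg, property_type = sct("Tumor")), c(1L, 3L))
  expect_identical(find_segments(seg, property_type = sct("Tumor"),
                                 label = "tumor-b"), 3L)
  expect_identical(find_segments(seg, tracking_uid = uid3), 3L)
  expect_identical(find_segments(seg, label = "does-not-exist"), integer(0))
})

test_that("binary round-trip through a file is bit-exact, sparse included", {
  set.seed(31)
  for (i in 1:6) {
    n_slices <- sample(2:4, 1)
    n_seg <- sample(1:3, 1)
    ct <- make_ct(n_slices = n_slices, seed = i)
    mask <- array(FALSE, c(n_slices, 16, 16, n_seg))
    # leave at least one (frame, segment) plane fully empty: sparse case
    for (k in seq_len(n_seg)) {
      for (f in seq_len(n_slices)) {
        if (f == 1 && k == 1) next  # planted empty plane
        if (stats::runif(1) < 0.3) next
        r <- sort(sample(1:16, 2)); c_ <- sort(sample(1:16, 2))
        mask[f, r[1]:r[2], c_[1]:c_[2], k] <- TRUE
      }
    }
    if (!any(mask)) mask[2, 3, 3, 1] <- TRUE
    descs <- lapply(seq_len(n_seg), function(k) tumor_description(k, paste0("s", k)))
    seg <- encode_segmentation(mask, ct, descs, segmentation_params("BINARY"))
    path <- withr::local_tempfile(fileext = ".dcm")
    write_dicom(seg, path)
    seg2 <- read_dicom(path)
    out <- reconstruct_mask(seg2, source_uids(ct))
    expect_identical(array(out > 0, dim(mask)), mask)
  }
})

test_that("omitted background frames reconstruct as zeros", {
  ct <- make_ct(n_slices = 3)
  mask <- array(FALSE, c(3, 16, 16))
  mask[1, 2:4, 2:4] <- TRUE
  mask[3, 8:10, 8:10] <- TRUE  # frame 2 fully background -> omitted
  seg <- encode_segmentation(mask, ct, list(tumor_description()),
                             segmentation_params("BINARY"))
  expect_identical(ds_get(seg, "NumberOfFrames"), 2L)
  out <- reconstruct_mask(seg, source_uids(ct))
  expect_true(all(out[2, , , 1] == 0))
  expect_identical(array(out > 0, dim(mask)), mask)
})

test_that("fractional round-trip error is bounded by the quantization step", {
  set.seed(17)
  ct <- make_ct(n_slices = 2)
  probs <- array(stats::runif(2 * 16 * 16), c(2, 16, 16))
  seg <- encode_segmentation(probs, ct, list(tumor_description()),
                             segmentation_params("FRACTIONAL", "PROBABILITY"))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(seg, path)
  out <- reconstruct_mask(read_dicom(path), source_uids(ct),
                          rescale_fractional = TRUE)
  expect_lte(max(abs(out[, , , 1] - probs)), 1 / (2 * 255))
})

test_that("reconstruction is invariant to stored frame order", {
  set.seed(8)
  ct <- make_ct(n_slices = 3)
  mask <- array(stats::runif(3 * 16 * 16 * 2) > 0.6, c(3, 16, 16, 2))
  mask[1, 1, 1, 1] <- TRUE
  seg <- encode_segmentation(mask, ct,
                             list(tumor_description(1, "a"),
                                  tumor_description(2, "b")),
                             segmentation_params("BINARY"))
  ref <- reconstruct_mask(seg, source_uids(ct))
  # shuffle stored frames together with their per-frame metadata
  n <- as.integer(ds_get(seg, "NumberOfFrames"))
  perm <- sample(n)
  frames <- dcmannot:::decode_stored_frames(seg)
  pfg <- ds_get(seg, "PerFrameFunctionalGroupsSequence")
  shuffled <- array(FALSE, dim(frames))
  for (j in seq_len(n)) shuffled[j, , ] <- frames[perm[j], , ] > 0
  seg2 <- ds_set(seg, "PerFrameFunctionalGroupsSequence", pfg[perm])
  seg2 <- ds_set(seg2, "PixelData", pack_bits(shuffled), vr = "OB")
  expect_identical(reconstruct_mask(seg2, source_uids(ct)), ref)
})

test_that("label-map combination matches a per-pixel membership oracle", {
  set.seed(12)
  ct <- make_ct(n_slices = 3, rows = 4, cols = 4)
  for (i in 1:10) {
    mask <- array(stats::runif(3 * 4 * 4 * 3) > 0.5, c(3, 4, 4, 3))
    # make planes disjoint so combination is well-defined
    mask[, , , 2] <- mask[, , , 2] & !mask[, , , 1]
    mask[, , , 3] <- mask[, , , 3] & !(mask[, , , 1] | mask[, , , 2])
    if (!any(mask)) mask[1, 1, 1, 1] <- TRUE
    descs <- lapply(1:3, function(k) tumor_description(k, paste0("s", k)))
    seg <- encode_segmentation(mask, ct, descs, segmentation_params("BINARY"))
    lab <- reconstruct_mask(seg, source_uids(ct), combine = TRUE)
    # oracle: label of a pixel is the segment whose plane contains it
    oracle <- array(0L, c(3, 4, 4))
    for (k in 1:3) oracle[mask[, , , k]] <- k
    expect_identical(lab, oracle)
  }
})

test_that("overlapping segments only combine when explicitly allowed", {
  ct <- make_ct(n_slices = 1, rows = 8, cols = 8)
  mask <- array(FALSE, c(1, 8, 8, 2))
  mask[1, 2:4, 2:4, 1] <- TRUE
  mask[1, 4:6, 4:6, 2] <- TRUE  # overlap at (4,4)
  seg <- encode_segmentation(mask, ct,
                             list(tumor_description(1, "a"),
                                  tumor_description(2, "b")),
                             segmentation_params("BINARY"))
  expect_error(reconstruct_mask(seg, source_uids(ct), combine = TRUE),
               "overlap")
  lab <- reconstruct_mask(seg, source_uids(ct), combine = TRUE,
                          allow_overlap = TRUE)
  expect_identical(lab[1, 4, 4], 2L)  # highest segment number wins
  expect_error(reconstruct_mask(seg, source_uids(ct), segment_numbers = 9),
               "unknown segment")
})
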