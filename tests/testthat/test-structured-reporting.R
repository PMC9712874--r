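test_that("measurement report trees have the documented TID 1500 shape", {
  # empty report: valid tree with an empty measurements container
  empty <- build_measurement_report(observation_context(), sct("Imaging"),
                                    list())
  expect_identical(empty$template, "1500")
  meas <- find_content_items(empty, name = dcm("ImagingMeasurements"),
                             value_type = "CONTAINER")
  expect_length(meas, 1)
  expect_length(meas[[1]]$item$children, 0)

  ct <- make_ct(n_slices = 1)
  geom <- geometry_from_dataset(ct[[1]])
  for_uid <- ds_get(ct[[1]], "FrameOfReferenceUID")
  ring <- pixel_to_reference(rbind(c(1, 1), c(5, 1), c(5, 5), c(1, 5), c(1, 1)),
                             geom)
  grp <- measurement_group(
    "T-001", generate_uid(), sct("Tumor"),
    region = item_scoord3d(dcm("ImageRegion"), "POLYGON", ring, for_uid),
    measurements = list(measurement(sct("Area"), polygon_area_mm2(ring),
                                    ucum("SquareMillimeter"))))
  tree <- build_measurement_report(observation_context(observer_name = "Doe^A"),
                                   sct("Imaging"), list(grp))
  expect_identical(tree$template, "1500")
  gitems <- find_content_items(tree, name = dcm("MeasurementGroup"),
                               value_type = "CONTAINER")
  expect_length(gitems, 1)
  g <- gitems[[1]]$item
  expect_length(find_content_items(g, value_type = "NUM"), 1)
  expect_gte(length(find_content_items(g, value_type = "CODE")), 1)
  expect_length(find_content_items(g, value_type = "SCOORD3D"), 1)
  # determinism: identical inputs give identical encodings
  tree2 <- build_measurement_report(observation_context(observer_name = "Doe^A"),
                                    sct("Imaging"), list(grp))
  expect_identical(dcmannot:::serialize_dataset(dcmannot:::item_to_ds(tree)),
                   dcmannot:::serialize_dataset(dcmannot:::item_to_ds(tree2)))
})

test_that("group construction enforces region/kind consistency", {
  ring2d <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(0, 0))
  sc2 <- item_scoord(dcm("ImageRegion"), "POLYLINE", ring2d, "1.2.3", "1.2.3.4")
  sc3 <- item_scoord3d(dcm("ImageRegion"), "POINT", matrix(c(1, 2, 3), 1),
                       "2.25.99")
  expect_error(measurement_group("T", generate_uid(), sct("Tumor"),
                                 region = list(sc2, sc3), kind = "volumetric"),
               "mix 2D")
  expect_error(measurement_group("T", generate_uid(), sct("Tumor"),
                                 region = sc3, kind = "image"),
               "no region")
  expect_error(measurement_group("T", generate_uid(), sct("Tumor"),
                                 region = NULL, kind = "planar"),
               "require a region")
  expect_error(measurement_group("T", generate_uid(), sct("Tumor"),
                                 region = list(sc3, sc3), kind = "planar"),
               "single region")
})

test_that("SCOORD3D geometry rules are enforced at construction", {
  fuid <- "2.25.77"
  open_ring <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_error(item_scoord3d(dcm("ImageRegion"), "POLYGON", open_ring, fuid),
               "closed")
  nonplanar <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1), c(0, 1, 0), c(0, 0, 0))
  expect_error(item_scoord3d(dcm("ImageRegion"), "POLYGON", nonplanar, fuid),
               "non-planar")
  expect_error(item_scoord3d(dcm("ImageRegion"), "ELLIPSE",
                             matrix(1, 3, 3), fuid), "4 points")
  expect_error(item_scoord3d(dcm("ImageRegion"), "ELLIPSOID",
                             matrix(1, 4, 3), fuid), "6 points")
  expect_error(item_scoord3d(dcm("ImageRegion"), "POINT",
                             matrix(1, 2, 3), fuid), "1 point")
})

test_that("SCOORD3D is rejected in non-3D comprehensive documents", {
  ct <- make_ct(n_slices = 1)
  ctx <- harvest_context(ct); ev <- build_evidence(ct)
  for_uid <- ds_get(ct[[1]], "FrameOfReferenceUID")
  grp <- measurement_group(
    "T-001", generate_uid(), sct("Tumor"),
    region = item_scoord3d(dcm("ImageRegion"), "POINT",
                           matrix(c(1, 2, 3), 1), for_uid))
  tree <- build_measurement_report(observation_context(), sct("Imaging"),
                                   list(grp))
  expect_error(create_sr_document(tree, ev, ctx, kind = "comprehensive"),
               "SCOORD3D")
  doc3d <- create_sr_document(tree, ev, ctx, kind = "comprehensive_3d")
  expect_identical(n_errors(validate_sop(doc3d, "comprehensive_3d_sr")), 0L)
  # the same dataset validated against the non-3D schema must fail on the
  # value type
  rep <- validate_sop(doc3d, "comprehensive_sr")
  expect_gte(n_errors(rep), 1L)
  expect_true(any(rep$rule == "value-type" | grepl("ValueType", rep$path)))

  # 2D-only tree is valid as plain comprehensive
  grp2d <- measurement_group(
    "T-002", generate_uid(), sct("Tumor"),
    region = item_scoord(dcm("ImageRegion"), "POINT", matrix(c(4, 5), 1),
                         ds_get(ct[[1]], "SOPClassUID"),
                         ds_get(ct[[1]], "SOPInstanceUID")))
  tree2d <- build_measurement_report(observation_context(), sct("Imaging"),
                                     list(grp2d))
  doc2d <- create_sr_document(tree2d, ev, ctx, kind = "comprehensive")
  expect_identical(n_errors(validate_sop(doc2d, "comprehensive_sr")), 0L)
})

test_that("find_content_items agrees with a naive recursive scan", {
  set.seed(77)
  filters <- list(
    list(),
    list(value_type = "NUM"),
    list(value_type = "CODE"),
    list(name = sct("Tumor")),
    list(name = sct("Area"), value_type = "NUM"),
    list(relationship = "CONTAINS", value_type = "TEXT"))
  for (i in 1:15) {
    tree <- random_tree(sample(10:50, 1))
    for (f in filters) {
      got <- do.call(find_content_items, c(list(tree), f))
      want <- do.call(oracle_scan_items, c(list(tree), f))
      expect_identical(length(got), length(want))
      for (j in seq_along(got)) {
        expect_identical(got[[j]]$item$value_type, want[[j]]$value_type)
        expect_identical(got[[j]]$item$name$value, want[[j]]$name$value)
      }
    }
    # no filters, recursive: every node except the root is returned
    expect_identical(length(find_content_items(tree)),
                     as.integer(count_tree_nodes(tree) - 1))
    # paths address the items they report
    hits <- find_content_items(tree)
    for (h in hits[seq_len(min(5, length(hits)))]) {
      node <- tree
      for (ix in h$path) node <- node$children[[ix]]
      expect_identical(node$value_type, h$item$value_type)
    }
  }
})

test_that("non-recursive search stays at depth one", {
  inner <- item_container(dcm("MeasurementGroup"), children = list(
    item_text(dcm("TrackingIdentifier"), "deep")))
  tree <- item_container(dcm("ImagingMeasurementReport"), children = list(
    item_text(dcm("TrackingIdentifier"), "shallow"),
    inner), relationship = NULL, template = "1500")
  all_text <- find_content_items(tree, value_type = "TEXT", recursive = TRUE)
  top_text <- find_content_items(tree, value_type = "TEXT", recursive = FALSE)
  expect_length(all_text, 2)
  expect_length(top_text, 1)
  expect_identical(top_text[[1]]$item$value, "shallow")
})

test_that("document write/read preserves the full content tree", {
  set.seed(55)
  ct <- make_ct(n_slices = 2)
  ctx <- harvest_context(ct); ev <- build_evidence(ct)
  geom <- geometry_from_dataset(ct[[1]])
  for_uid <- ds_get(ct[[1]], "FrameOfReferenceUID")
  groups <- lapply(1:3, function(i) random_group(geom, for_uid, i))
  tree <- build_measurement_report(observation_context(observer_name = "Doe^A"),
                                   sct("Imaging"), groups)
  doc <- create_sr_document(tree, ev, ctx, "comprehensive_3d")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(doc, path)
  tree2 <- sr_document_tree(read_dicom(path))
  expect_identical(tree2$template, "1500")
  expect_identical(count_tree_nodes(tree2), count_tree_nodes(tree))
  # evidence survives per study/series
  ev2 <- ds_get(read_dicom(path), "CurrentRequestedProcedureEvidenceSequence")
  expect_length(ev2, 1)
  expect_identical(ds_get(ev2[[1]], "StudyInstanceUID"), ctx$study$StudyInstanceUID)
})

test_that("planted groups, measurements and evaluations are recoverable", {
  ct <- make_ct(n_slices = 1)
  ctx <- harvest_context(ct); ev <- build_evidence(ct)
  geom <- geometry_from_dataset(ct[[1]])
  for_uid <- ds_get(ct[[1]], "FrameOfReferenceUID")
  mk_group <- function(id, finding, site) {
    ring <- pixel_to_reference(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0, 0)),
                               geom)
    measurement_group(
      id, generate_uid(), finding, finding_sites = list(site),
      region = item_scoord3d(dcm("ImageRegion"), "POLYGON", ring, for_uid),
      measurements = list(
        measurement(sct("Area"), 4.25, ucum("SquareMillimeter")),
        measurement(sct("Diameter"), 2.5, ucum("Millimeter"))),
      evaluations = list(
        item_code(coded_concept("EV", "99TEST", "synthetic evaluation"),
                  sct("Normal"))))
  }
  groups <- list(mk_group("G1", sct("Tumor"), sct("Lung")),
                 mk_group("G2", sct("Tumor"), sct("Lung")),
                 mk_group("G3", sct("Normal"), sct("Lung")))
  doc <- create_sr_document(
    build_measurement_report(observation_context(), sct("Imaging"), groups),
    ev, ctx, "comprehensive_3d")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(doc, path)
  back <- read_dicom(path)

  expect_length(get_measurement_groups(back), 3)
  tum <- get_measurement_groups(back, finding_type = sct("Tumor"))
  expect_length(tum, 2)
  expect_identical(vapply(tum, `[[`, character(1), "tracking_id"),
                   c("G1", "G2"))
  g3uid <- groups[[3]]$tracking_uid
  expect_length(get_measurement_groups(back, tracking_uid = g3uid), 1)
  expect_length(get_measurement_groups(back, finding_site = sct("Nodule")), 0)
  expect_length(get_measurement_groups(back, graphic_type = "POLYGON"), 3)
  expect_length(get_measurement_groups(back, graphic_type = "ELLIPSE"), 0)

  g1 <- tum[[1]]
  area <- get_measurements(g1, name = sct("Area"))
  expect_length(area, 1)
  expect_identical(area[[1]]$value, 4.25)
  expect_identical(area[[1]]$unit$value, "mm2")
  expect_length(get_measurements(g1), 2)
  expect_length(get_qualitative_evaluations(g1), 1)
  expect_true(concept_eq(get_qualitative_evaluations(g1)[[1]]$value,
                         sct("Normal")))
  expect_length(get_qualitative_evaluations(
    g1, name = coded_concept("OTHER", "99TEST", "unused")), 0)
  # structure error on a non-1500 root
  bad_root <- item_container(dcm("ImagingMeasurements"), children = list(),
                             relationship = NULL)
  expect_error(get_measurement_groups(bad_root), "1500")
})
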