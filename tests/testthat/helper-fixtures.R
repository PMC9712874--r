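# Shared fixtures and independent oracles for the test suite.

sct <- function(kw) registry_lookup("SCT", kw)
dcm <- function(kw) registry_lookup("DCM", kw)
ucum <- function(kw) registry_lookup("UCUM", kw)

make_ct <- function(n_slices = 3, rows = 16, cols = 16, seed = 1,
                    orientation = "axial") {
  generate_ct_series(ct_series_spec(n_slices = n_slices, rows = rows,
                                    cols = cols, orientation = orientation,
                                    seed = seed))
}

tumor_description <- function(n = 1, label = "tumor") {
  segment_description(n, label, sct("MorphologicallyAbnormalStructure"),
                      sct("Tumor"), "AUTOMATIC", list(name = "model"))
}

source_uids <- function(sources) {
  vapply(sources, ds_get, character(1), keyword = "SOPInstanceUID")
}

# --- independent oracles -------------------------------------------------

# bit-level packing oracle: arithmetic over powers of two, no packBits
oracle_pack_bits <- function(bits) {
  if (length(bits) %% 8 != 0) bits <- c(bits, rep(FALSE, 8 - length(bits) %% 8))
  n_bytes <- length(bits) / 8
  vals <- vapply(seq_len(n_bytes), function(b) {
    sum(as.integer(bits[(8 * (b - 1) + 1):(8 * b)]) * 2^(0:7))
  }, numeric(1))
  out <- as.raw(vals)
  if (length(out) %% 2 == 1) out <- c(out, as.raw(0L))
  out
}

# connected components by iterative dilation over logical matrices
# (independent of the BFS labeling in the package)
oracle_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  }
  remaining <- mask
  comps <- list()
  while (any(remaining)) {
    seedpix <- which(remaining)[1]
    region <- matrix(FALSE, nr, nc)
    region[seedpix] <- TRUE
    repeat {
      grown <- region
      for (o in offs) grown <- grown | shift(region, o[1], o[2])
      grown <- grown & mask
      if (identical(grown, region)) break
      region <- grown
    }
    comps[[length(comps) + 1]] <- region
    remaining <- remaining & !region
  }
  comps
}

oracle_boxes <- function(mask, connectivity = 8) {
  comps <- oracle_components(mask, connectivity)
  boxes <- lapply(comps, function(region) {
    px <- which(region, arr.ind = TRUE)
    c(min(px[, 2]) - 1, min(px[, 1]) - 1, max(px[, 2]) - 1, max(px[, 1]) - 1)
  })
  boxes[order(vapply(boxes, `[`, numeric(1), 2),
              vapply(boxes, `[`, numeric(1), 1))]
}

# naive recursive scan over an sr_item tree (no path bookkeeping shortcuts)
oracle_scan_items <- function(item, name = NULL, value_type = NULL,
                              relationship = NULL) {
  hits <- list()
  if (item$value_type == "CONTAINER") {
    for (ch in item$children) {
      ok <- TRUE
      if (!is.null(name)) {
        ok <- ok && ch$name$value == name$value && ch$name$scheme == name$scheme
      }
      if (!is.null(value_type)) ok <- ok && ch$value_type == value_type
      if (!is.null(relationship)) ok <- ok && identical(ch$relationship, relationship)
      if (ok) hits <- c(hits, list(ch))
      hits <- c(hits, oracle_scan_items(ch, name, value_type, relationship))
    }
  }
  hits
}

# random SR content tree of at most about n nodes
random_tree <- function(n_target = 30) {
  concepts <- list(sct("Tumor"), sct("Lung"), dcm("Finding"), sct("Area"),
                   sct("Normal"))
  counter <- 0
  make_node <- function(depth) {
    counter <<- counter + 1
    kind <- if (depth < 3 && counter < n_target && stats::runif(1) < 0.35) {
      "CONTAINER"
    } else {
      sample(c("TEXT", "CODE", "NUM"), 1)
    }
    nm <- concepts[[sample(length(concepts), 1)]]
    switch(kind,
      CONTAINER = {
        kids <- lapply(seq_len(sample(1:4, 1)), function(i) make_node(depth + 1))
        item_container(nm, children = kids)
      },
      TEXT = item_text(nm, paste0("t", counter)),
      CODE = item_code(nm, concepts[[sample(length(concepts), 1)]]),
      NUM = item_num(nm, round(stats::runif(1) * 100, 3), ucum("Millimeter"))
    )
  }
  kids <- lapply(seq_len(sample(2:5, 1)), function(i) make_node(1))
  item_container(dcm("ImagingMeasurementReport"), children = kids,
                 relationship = NULL, template = "1500")
}

count_tree_nodes <- function(item) {
  if (item$value_type != "CONTAINER") return(1)
  1 + sum(vapply(item$children, count_tree_nodes, numeric(1)))
}

# random measurement group over a CT geometry; values chosen to be exactly
# representable after file round-trip (float32 graphic data, %.8g numerics)
random_group <- function(geom, for_uid, i) {
  finding <- list(sct("Tumor"), sct("Normal"), sct("Nodule"))[[sample(3, 1)]]
  c0 <- sample(0:8, 1); r0 <- sample(0:8, 1)
  w <- sample(1:6, 1); h <- sample(1:6, 1)
  ring_px <- rbind(c(c0, r0), c(c0 + w, r0), c(c0 + w, r0 + h),
                   c(c0, r0 + h), c(c0, r0))
  region <- item_scoord3d(dcm("ImageRegion"), "POLYGON",
                          pixel_to_reference(ring_px, geom), for_uid)
  n_meas <- sample(0:3, 1)
  meas <- lapply(seq_len(n_meas), function(j) {
    nm <- list(sct("Area"), sct("Diameter"), sct("Volume"))[[j]]
    un <- list(ucum("SquareMillimeter"), ucum("Millimeter"),
               ucum("SquareMillimeter"))[[j]]
    measurement(nm, sample(1:100000, 1) / 1000, un)
  })
  n_eval <- sample(0:2, 1)
  evals <- lapply(seq_len(n_eval), function(j) {
    item_code(coded_concept(paste0("E", j), "99TEST", "synthetic evaluation"),
              list(sct("Normal"), sct("Tumor"))[[sample(2, 1)]])
  })
  n_sites <- sample(0:2, 1)
  sites <- lapply(seq_len(n_sites), function(j) sct("Lung"))
  measurement_group(
    tracking_id = sprintf("T-%03d", i), tracking_uid = generate_uid(),
    finding_type = finding, finding_sites = sites, region = region,
    measurements = meas, evaluations = evals, kind = "planar")
}

concept_eq <- function(a, b) {
  suppressWarnings(concepts_equal(a, b))
}
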