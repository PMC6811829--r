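# Soma/bouton detection, PV classification, neuropil annuli.

test_that("correlation growing recovers a single flickering disc", {
  cfg <- tiny_config()
  n <- 200L
  cell <- list(ground_truth_cell(c(24, 24), 6))
  tr <- matrix(100 + 30 * (stats::rbinom(n, 1, 0.2) *
                             stats::runif(n, 0.5, 1)), ncol = 1)
  r <- render_session(cell, tr, cfg, neuropil_level = 0)
  movie <- r$movie + array(stats::rnorm(length(r$movie), 0, 0.5),
                           dim = dim(r$movie))
  rois <- detect_somata(movie, min_area_px = 20)
  expect_length(rois, 1L)
  truth <- capipe:::px_index(r$masks[[1]], 48L)
  det <- capipe:::px_index(rois[[1]]$pixels, 48L)
  expect_gte(length(intersect(det, truth)) / length(truth), 0.8)
})

test_that("constant movies yield no ROIs", {
  movie <- array(7, c(20, 20, 120))
  expect_length(detect_somata(movie, min_area_px = 4), 0L)
  expect_error(detect_somata(array(1, c(10, 10, 50))), "100 frames")
})

test_that("detected ROIs are disjoint and 4-connected on the fixture", {
  rois <- imaging_fixture_rois()
  expect_gte(length(rois), 15L)
  all_px <- do.call(rbind, lapply(rois, function(r) r$pixels))
  idx <- capipe:::px_index(all_px, 140L)
  expect_equal(anyDuplicated(idx), 0L)
  # 4-connectivity: every ROI is one connected component
  for (r in rois) {
    lab <- matrix(0L, 140, 140)
    lab[capipe:::px_index(r$pixels, 140L)] <- 1L
    cc <- EBImage::bwlabel(EBImage::Image(lab))
    expect_equal(max(EBImage::imageData(cc)), 1)
  }
})

test_that("bouton detection finds puncta within area bounds", {
  img <- matrix(0, 60, 60)
  centers <- cbind(seq(5, 50, 5), seq(5, 50, 5))
  for (i in seq_len(10)) {
    img[centers[i, 1], centers[i, 2]] <- 10
    img[centers[i, 1] + 1, centers[i, 2]] <- 8
  }
  rois <- detect_boutons(img, intensity_percentile = 98, max_area_px = 5)
  expect_length(rois, 10L)
  expect_true(all(vapply(rois, function(r) r$kind, "") == "bouton"))
  # uniform image: nothing
  expect_length(detect_boutons(matrix(1, 30, 30)), 0L)
  # components above max_area are excluded
  img2 <- img; img2[20:40, 30:50] <- 10
  rois2 <- detect_boutons(img2, intensity_percentile = 80, max_area_px = 5)
  expect_true(all(vapply(rois2, function(r) nrow(r$pixels), 1L) <= 5L))
})

test_that("PV classification is morphology-robust and monotone", {
  rois <- imaging_fixture_rois()
  ses <- imaging_fixture()
  # zero red image: everyone putative pyramidal
  r0 <- classify_pv(matrix(0, 140, 140), rois)
  expect_true(all(vapply(r0, function(r) r$cell_type, "") ==
                    "putative_pyramidal"))
  # a thin 1-px red process crossing an ROI is removed by erosion
  red <- matrix(0, 140, 140)
  red[rois[[1]]$pixels[1, 1], ] <- 1
  r1 <- classify_pv(red, rois, erosion_radius_px = 2)
  expect_true(all(vapply(r1, function(r) r$cell_type, "") ==
                    "putative_pyramidal"))
  # monotone: raising the threshold never adds pv labels
  pv_at <- function(thr) {
    which(vapply(classify_pv(ses$red, rois, red_threshold = thr),
                 function(r) r$cell_type, "") == "pv")
  }
  lo <- pv_at(0.3); mid <- pv_at(0.5); hi <- pv_at(0.8)
  expect_true(all(mid %in% lo))
  expect_true(all(hi %in% mid))
})

test_that("neuropil annuli respect the radius and exclusion rules", {
  field <- c(100L, 100L)
  disc <- capipe:::disc_pixels(c(50, 50), 5, field)
  roi <- structure(list(id = 1L, pixels = disc$rc, kind = "soma",
                        cell_type = "unknown", quality = NA_real_),
                   class = "roi_mask")
  ann <- build_annulus(roi, list(roi), radius_um = 30, pixel_size_um = 1,
                       field_px = field)
  # pixel-counting oracle: pixels within 30 px of the disc, minus the disc
  g <- as.matrix(expand.grid(row = 1:100, col = 1:100))
  d_to_roi <- apply(g, 1, function(p) {
    min(sqrt((disc$rc[, 1] - p[1])^2 + (disc$rc[, 2] - p[2])^2))
  })
  in_roi <- capipe:::px_index(g, 100L) %in% capipe:::px_index(disc$rc, 100L)
  expect_equal(nrow(ann$pixels), sum(d_to_roi <= 30 & !in_roi))

  # adjacent ROI pixels are excluded from each other's annulus
  disc2 <- capipe:::disc_pixels(c(50, 70), 5, field)
  roi2 <- structure(list(id = 2L, pixels = disc2$rc, kind = "soma",
                         cell_type = "unknown", quality = NA_real_),
                    class = "roi_mask")
  both <- list(roi, roi2)
  a1 <- build_annulus(roi, both, field_px = field)
  expect_length(intersect(capipe:::px_index(a1$pixels, 100L),
                          capipe:::px_index(disc2$rc, 100L)), 0L)

  # corner ROI: clipped but valid
  disc3 <- capipe:::disc_pixels(c(3, 3), 2.5, field)
  roi3 <- structure(list(id = 3L, pixels = disc3$rc, kind = "soma",
                         cell_type = "unknown", quality = NA_real_),
                    class = "roi_mask")
  a3 <- build_annulus(roi3, list(roi3), field_px = field)
  expect_gt(nrow(a3$pixels), 0L)
  expect_true(all(a3$pixels >= 1L))
})
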