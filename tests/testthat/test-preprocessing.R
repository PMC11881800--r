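test_that("delta OD follows the log-ratio definition", {
  f <- make_clean_recording(seed = 1)
  rec <- f$rec
  # constant intensity equal to its reference gives OD 0
  rec0 <- rec
  rec0$intensities[] <- 123.4
  expect_true(all(intensity_to_od(rec0)$delta_od == 0))
  # phi = ref / e gives OD exactly 1 (first-sample reference)
  rec1 <- rec
  rec1$intensities[] <- 50
  rec1$intensities[1, 10] <- 50 / exp(1)
  od1 <- intensity_to_od(rec1, reference = "first")
  expect_equal(od1$delta_od[1, 10], 1, tolerance = 1e-12)
  # first-sample reference: exact log-ratio oracle
  odf <- intensity_to_od(rec, reference = "first")
  oracle <- log(rec$intensities[, 1] / rec$intensities[, 25])
  expect_equal(odf$delta_od[, 25], oracle, tolerance = 1e-12)
  # nonpositive intensity -> domain error naming location
  recb <- rec
  recb$intensities[3, 7] <- -1
  expect_error(intensity_to_od(recb), "channel row 3, sample 7",
               class = "tpdc_domain_error")
})

test_that("the DPF model matches its closed form", {
  expect_identical(dpf(0), 4.99)
  expect_equal(dpf(1), 4.99 + 0.067)
  expect_equal(dpf(10), 4.99 + 0.067 * 10^0.814, tolerance = 1e-12)
  expect_error(dpf(-1), class = "tpdc_parameter_error")
})

test_that("Beer-Lambert inversion round-trips the forward model to machine precision", {
  f <- make_clean_recording(seed = 2)
  od <- intensity_to_od(f$rec)
  hb <- od_to_hemoglobin(od)
  ctr <- function(M) sweep(M, 1, rowMeans(M))
  expect_equal(ctr(hb$hbo), ctr(f$rec$truth_hbo), tolerance = 1e-10)
  expect_equal(ctr(hb$hbr), ctr(f$rec$truth_hbr), tolerance = 1e-10)
  # missing wavelength partner -> pairing error
  broken <- od
  broken$channels <- broken$channels[-2, ]
  broken$delta_od <- broken$delta_od[-2, ]
  expect_error(od_to_hemoglobin(broken), class = "tpdc_pairing_error")
})

test_that("detrending removes lines exactly and is idempotent", {
  f <- make_clean_recording(n_samples = 200, seed = 3)
  hb <- od_to_hemoglobin(intensity_to_od(f$rec))
  tt <- seq_len(200)
  hb$hbo[1, ] <- 2 + 0.01 * tt                      # pure line
  hb$hbo[2, ] <- 1 - 0.02 * tt + sin(2 * pi * tt / 40)
  out <- suppressWarnings(detrend_center(hb))
  expect_lt(max(abs(out$hbo[1, ])), 1e-10)
  oracle <- detrend_oracle(1 - 0.02 * tt + sin(2 * pi * tt / 40))
  expect_lt(sqrt(mean((out$hbo[2, ] - oracle)^2)), 1e-8)
  # per-channel mean is numerically zero; second pass changes nothing
  expect_lt(max(abs(rowMeans(out$hbo))), 1e-10)
  out2 <- suppressWarnings(detrend_center(out))
  expect_equal(out2$hbo, out$hbo, tolerance = 1e-10)
})

test_that("systemic regression removes shared components", {
  f <- make_clean_recording(n_samples = 300, seed = 4)
  hb <- od_to_hemoglobin(intensity_to_od(f$rec))
  g <- sin(2 * pi * seq_len(300) / 50)
  # identical signal everywhere collapses to zero
  hb$hbo <- matrix(rep(g, each = nrow(hb$hbo)), nrow(hb$hbo))
  hb$hbr <- hb$hbo
  out <- remove_systemic(hb, estimator = "mean")
  expect_lt(max(abs(out$hbo)), 1e-10)
  # shared component + independent signals: residuals orthogonal to it
  set.seed(4)
  hb$hbo <- matrix(rnorm(nrow(hb$hbo) * 300), nrow(hb$hbo)) +
    outer(runif(nrow(hb$hbo), 0.5, 1.5), g)
  out <- remove_systemic(hb, estimator = "mean")
  gm <- colMeans(matrix(rep(g, each = nrow(hb$hbo)), nrow(hb$hbo)))
  ip <- apply(out$hbo, 1, function(r) {
    gg <- colMeans(hb$hbo)
    sum(r * (gg - mean(gg)))
  })
  expect_lt(max(abs(ip)), 1e-8)
  # zero input stays zero
  hb$hbo[] <- 0; hb$hbr[] <- 0
  expect_true(all(remove_systemic(hb, estimator = "mean")$hbo == 0))
})

test_that("ROI pooling retains 40 channels with the canonical per-ROI counts", {
  f <- make_clean_recording(seed = 5)
  hb <- od_to_hemoglobin(intensity_to_od(f$rec))
  rois <- pool_rois(hb)
  expect_equal(attr(rois, "n_channels_retained"), 40L)
  counts <- table(default_roi_map()$roi)[roi_labels()]
  expect_equal(unname(c(counts)), c(8L, 6L, 8L, 6L, 4L, 4L, 4L))
  expect_equal(sort(names(rois)), c("left", "right"))
  expect_equal(nrow(rois$left$series), 7)
  # identical member channels: ROI equals the channel
  map <- default_roi_map()
  members <- map$channel[map$roi == "IFG" & map$hemisphere == "left"]
  rows <- match(members, hb$pairs$channel)
  hb$hbo[rows, ] <- matrix(rep(hb$hbo[rows[1], ], length(rows)),
                           length(rows), byrow = TRUE)
  rois2 <- pool_rois(hb)
  expect_equal(rois2$left$series["IFG", ], hb$hbo[rows[1], ], tolerance = 1e-12)
  # cancellation: x and -x average to zero
  map2 <- map[map$hemisphere == "left" & map$roi == "SMG", ]
  rows2 <- match(map2$channel, hb$pairs$channel)
  hb$hbo[rows2[2], ] <- -hb$hbo[rows2[1], ]
  expect_lt(max(abs(pool_rois(hb)$left$series["SMG", ])), 1e-12)
  # empty ROI -> mapping error
  badmap <- map[map$roi != "ANG", ]
  expect_error(pool_rois(hb, badmap), class = "tpdc_mapping_error")
})

test_that("no stage shortens or reorders the time axis", {
  f <- make_clean_recording(n_samples = 256, seed = 6, noise = 0.2,
                            artifacts = artifact_spec())
  od <- intensity_to_od(f$rec)
  expect_equal(ncol(od$delta_od), 256)
  odc <- correct_motion(od)
  expect_equal(ncol(odc$delta_od), 256)
  hb <- detrend_center(od_to_hemoglobin(odc))
  expect_equal(ncol(hb$hbo), 256)
  rois <- pool_rois(remove_systemic(hb))
  expect_equal(ncol(rois$left$series), 256)
})

test_that("full preprocessing recovers the latent dynamics under default artifacts", {
  net <- generate_network(edge_density = 0.15, seed = 1)
  sim <- simulate_roi_timeseries(net, 3281, seed = 1)   # 7 min at 7.8125 Hz
  lat <- apply(sim$series, 2, detrend_oracle)
  rec <- synthesize_raw_recording(sim, seed = 11)
  rois <- suppressWarnings(preprocess_recording(rec))
  r <- vapply(roi_labels(), function(x)
    cor(rois$left$series[x, ], lat[, x]), numeric(1))
  expect_gt(mean(r), 0.95)
  expect_gt(min(r), 0.85)
})
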