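test_that("configuration defaults, overrides, and files behave", {
  cfg <- default_config()
  expect_equal(cfg$alpha, 2)
  expect_equal(cfg$log_size, 13L)
  expect_error(default_config(list(bogus_key = 1)), "unknown config key")
  expect_message(default_config(list(alpha = 1), notify = TRUE), "defaulted")
  t1 <- preset_config("vfc_mgrl")
  expect_equal(t1$vfc_r, 1)
  expect_equal(t1$iterations, 100L)
  tg <- preset_config("gvf")
  expect_equal(tg$alpha, 0.8)
  d <- withr::local_tempdir()
  f <- file.path(d, "cfg.yaml")
  save_config(default_config(list(alpha = 1.5)), f)
  expect_equal(suppressMessages(load_config(f))$alpha, 1.5)
})

test_that("a single-frame track equals standalone segmentation", {
  sc <- test_scene(seed = 13)
  roi <- scene_roi(sc$scene)
  cfg <- preset_config("vfc_mgrl")
  tr <- track(list(sc$image), roi, cfg)
  sg <- segment(sc$image, roi, cfg)
  expect_equal(tr$records[[1]]$contour, sg$contour)
  expect_identical(tr$records[[1]]$mask, sg$mask)
  expect_length(tr$records, 1L)
})

test_that("tracking a short drifting sequence follows the cell", {
  sp <- sequence_spec(scene = scene_spec(seed = 2), n_frames = 5,
                      drift = c(1, 0.5), walk_scale = 0.004)
  seqq <- make_cell_sequence(sp)
  tr <- track(seqq$frames, seqq$roi, preset_config("vfc_mgrl"))
  expect_length(tr$records, 5L)
  ev <- evaluate_run(tr, seqq$masks)
  expect_gt(min(ev$per_frame$jaccard), 0.85)
  # temporal smoothness: tracked centroid step near the true drift
  cen <- t(vapply(tr$records, function(r) contour_centroid(r$contour), numeric(2)))
  steps <- sqrt(rowSums(diff(cen)^2))
  expect_lt(max(steps), sqrt(1 + 0.25) + 2)
  # determinism down to the serialized contours
  tr2 <- track(seqq$frames, seqq$roi, preset_config("vfc_mgrl"))
  d <- withr::local_tempdir()
  write_contours(lapply(tr$records, `[[`, "contour"), file.path(d, "a.csv"))
  write_contours(lapply(tr2$records, `[[`, "contour"), file.path(d, "b.csv"))
  expect_identical(readLines(file.path(d, "a.csv")),
                   readLines(file.path(d, "b.csv")))
})

test_that("summaries expose morphology per frame", {
  sq <- rbind(c(3, 3), c(13, 3), c(13, 13), c(3, 13))
  fake <- structure(list(records = list(list(
    frame = 1L, contour = sq, contour_roi = sq,
    mask = contour_to_mask(sq, c(20, 20)), iterations = 10L,
    converged = TRUE, reinitialized = FALSE, failed = FALSE)),
    roi = rect_roi(1, 1, 20, 20), config = default_config(),
    force_field = "vfc_mgrl", frame_interval = 0.04),
    class = "track_result")
  s <- summarize_track(fake)
  expect_equal(s$area, 100)
  expect_equal(s$perimeter, 40)
  expect_equal(s$time_s, 0)
  expect_equal(s$centroid_x, 8)
  expect_error(summarize_track(structure(list(records = list()),
                                         class = "track_result")), "empty")
})

test_that("run outputs are written in standard formats", {
  sc <- test_scene(seed = 13)
  roi <- scene_roi(sc$scene)
  sg <- segment(sc$image, roi, preset_config("vfc_mgrl"))
  d <- withr::local_tempdir()
  write_run(sg, d, frames = list(sc$image))
  expect_true(file.exists(file.path(d, "contours.csv")))
  expect_true(file.exists(file.path(d, "mask_0001.png")))
  expect_true(file.exists(file.path(d, "overlay_0001.png")))
  log <- jsonlite::read_json(file.path(d, "run_log.json"))
  expect_equal(log$frames, 1L)
  expect_equal(log$config$alpha, 2)
})
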