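# Training-loop contracts that run in seconds; the longer end-to-end
# behaviour lives in test-acceptance.R.

make_batch <- function(seqq, t = 3) {
  list(target = seqq[[t]]$frame,
       sources = list(seqq[[t - 1]]$frame, seqq[[t + 1]]$frame),
       K = seqq[[t]]$K)
}

test_that("a training step returns a finite positive loss and updates weights", {
  seqq <- fixture_overlay()
  cfg <- train_config(seed = 3, lr = 1e-3)
  nets <- endo_networks("tiny", seed = 3)
  w_before <- nets$depth$enc1$w$v
  rep <- train_step(make_batch(seqq), nets, cfg)
  expect_s3_class(rep, "endo_loss_report")
  expect_true(is.finite(rep$total) && rep$total > 0)
  expect_true(all(vapply(rep$per_term, is.finite, logical(1))))
  expect_false(identical(nets$depth$enc1$w$v, w_before))
})

test_that("with the static auto-mask off, mu equals mu2 inside the step", {
  seqq <- fixture_overlay()
  cfg <- train_config(seed = 3, use_automask = FALSE)
  nets <- endo_networks("tiny", seed = 3)
  rep <- train_step(make_batch(seqq), nets, cfg)
  mk <- attr(rep, "masks")
  expect_true(all(mk$mu1 == 1))
  expect_identical(mk$mu, mk$mu2)
})

test_that("repeated steps on one fixed triplet overfit it", {
  seqq <- fixture_overlay()
  cfg <- train_config(seed = 4, lr = 2e-3, use_inpainting = FALSE)
  nets <- endo_networks("tiny", seed = 4)
  batch <- make_batch(seqq)
  opt <- NULL
  first <- NULL
  set.seed(4)
  for (i in 1:50) {
    rep <- train_step(batch, nets, cfg, opt)
    opt <- attr(rep, "opt")
    if (i == 1) first <- rep$total
  }
  expect_lt(rep$total, first)
})

test_that("same-seed fits produce identical loss logs; checkpoints round-trip bitwise", {
  seqq <- render_sequence(scene_spec(resolution = 32L, n_frames = 5L))
  cfg <- train_config(seed = 11, epochs = 2, max_steps = 6, lr = 1e-3,
                      use_inpainting = FALSE)
  m1 <- depth_fit(seqq, cfg)
  m2 <- depth_fit(seqq, cfg)
  expect_identical(m1$log, m2$log)
  # checkpoint: save -> load -> infer is bitwise identical
  ck <- tempfile(fileext = ".rds")
  save_model(m1, ck)
  m3 <- load_model(ck)
  fr <- seqq[[3]]$frame
  i1 <- infer_frame(fr, m1)
  i3 <- infer_frame(fr, m3)
  expect_identical(i1$D$values, i3$D$values)
  expect_identical(i1$A, i3$A)
  expect_identical(i1$M_binary, i3$M_binary)
})

test_that("the model object provides the standard S3 surface", {
  seqq <- render_sequence(scene_spec(resolution = 32L, n_frames = 4L))
  cfg <- train_config(seed = 12, epochs = 1, max_steps = 3, use_inpainting = FALSE)
  m <- depth_fit(seqq, cfg)
  expect_s3_class(m, "endo_model")
  expect_output(print(m), "endo_model")
  expect_output(summary(m), "depth")
  inf <- predict(m, seqq[[2]]$frame)
  expect_s3_class(inf, "endo_inference")
  lst <- predict(m, list(seqq[[2]]$frame, seqq[[3]]$frame))
  expect_equal(length(lst), 2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("masks and cached I_rem stay outside the gradient", {
  # structural check: the per-step mask stack is plain numeric (detached)
  seqq <- fixture_overlay()
  cfg <- train_config(seed = 5)
  nets <- endo_networks("tiny", seed = 5)
  rep <- train_step(make_batch(seqq), nets, cfg)
  mk <- attr(rep, "masks")
  expect_true(is.numeric(mk$mu) && is.matrix(mk$mu))
  expect_true(is.numeric(rep$per_pixel_r))
})
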