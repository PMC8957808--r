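test_that("a trial resets voltages, keeps weights, and records every step", {
  spec <- build_basic_model()
  ph <- phase("baseline", 1, c(conspecific = 1, context1 = 1))
  st <- socialfear:::new_state(spec)
  st$V[] <- 5  # stale voltages must not leak into the next trial
  out1 <- run_trial(spec, ph, st)
  out2 <- run_trial(spec, ph)
  expect_identical(out1$trace, out2$trace)
  expect_equal(dim(out1$trace), c(16, 500))
  expect_true(all(out1$trace >= 0 & out1$trace <= 1))
})

test_that("the default protocol has the published three-phase structure", {
  proto <- default_protocol()
  expect_equal(vapply(proto$phases, function(p) p$name, character(1)),
               c("baseline", "conditioning", "extinction"))
  expect_equal(vapply(proto$phases, function(p) p$n_trials, integer(1)),
               c(1L, 3L, 11L))
  expect_equal(proto$phases[[2]]$inputs,
               c(conspecific = 1, context1 = 1, defeat = 1))
  expect_equal(proto$sim$trial_length, 500L)

  res <- run_protocol(build_basic_model(), proto)
  expect_equal(dim(res$traces)[3], 15)
  expect_equal(dim(res$weights)[3], 15)
  expect_identical(res$meta$phase,
                   rep(c("baseline", "conditioning", "extinction"),
                       c(1, 3, 11)))
})

test_that("repeated runs are bit-identical (the model is deterministic)", {
  spec <- build_basic_model()
  r1 <- run_protocol(spec)
  r2 <- run_protocol(spec)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$weights, r2$weights)
})

test_that("silencing clamps the firing rate to zero at every step", {
  spec <- build_basic_model()
  out <- run_trial(spec, phase("conditioning", 1,
                               c(conspecific = 1, context1 = 1, defeat = 1)),
                   manipulations = list(
                     manipulation("silence_unit", "Hyp1")))
  expect_true(all(out$trace["Hyp1", ] == 0))
})

test_that("block/scale act on the effective weight and never mutate stored weights", {
  spec <- build_basic_model()
  manip <- manipulation("scale_connection", c("Pyr2", "dPag1"),
                        magnitude = 0.25, phases = "extinction")
  res <- run_protocol(spec, manipulations = list(manip))
  ctrl <- run_protocol(spec)
  # Pyr2->dPag1 is non-plastic: stored value identical throughout
  for (k in seq_len(15))
    expect_identical(res$weights["dPag1", "Pyr2", k],
                     ctrl$weights["dPag1", "Pyr2", k])
  # but the dynamics differ inside the window
  ext1 <- which(res$meta$phase == "extinction")[1]
  expect_gt(avoidance_index(res)[ext1], avoidance_index(ctrl)[ext1])
  # removing the manipulation restores behaviour exactly
  expect_identical(run_protocol(spec)$traces, ctrl$traces)
})

test_that("outside its window a manipulation has no effect on the trajectory", {
  spec <- build_basic_model()
  manip <- manipulation("silence_unit", "Pyr2",
                        phases = "extinction", trials = 3)
  res <- run_protocol(spec, manipulations = list(manip))
  ctrl <- run_protocol(spec)
  first_ext3 <- which(res$meta$phase == "extinction")[3]
  before <- seq_len(first_ext3 - 1)
  expect_identical(res$traces[, , before], ctrl$traces[, , before])
  expect_false(identical(res$traces[, , first_ext3],
                         ctrl$traces[, , first_ext3]))

  # a step-windowed manipulation leaves the pre-window steps untouched
  manip2 <- manipulation("stimulate_unit", "Pv", magnitude = 1,
                         phases = "baseline", steps = c(201, 500))
  res2 <- run_protocol(spec, manipulations = list(manip2))
  expect_identical(res2$traces[, 1:200, 1], ctrl$traces[, 1:200, 1])
  expect_false(identical(res2$traces[, 201:500, 1],
                         ctrl$traces[, 201:500, 1]))
})

test_that("phases compose: one protocol equals chained calls sharing state", {
  spec <- build_basic_model()
  full <- run_protocol(spec, protocol_spec(list(
    phase("baseline", 1, c(conspecific = 1, context1 = 1)),
    phase("conditioning", 3, c(conspecific = 1, context1 = 1, defeat = 1))
  )))
  first <- run_protocol(spec, protocol_spec(list(
    phase("baseline", 1, c(conspecific = 1, context1 = 1)))))
  second <- run_protocol(spec, protocol_spec(list(
    phase("conditioning", 3, c(conspecific = 1, context1 = 1, defeat = 1)))),
    state = first$final_state)
  expect_identical(full$traces[, , 2:4], second$traces)
  expect_identical(full$final_state$W, second$final_state$W)
})

test_that("manipulations targeting unknown units or edges fail before integration", {
  spec <- build_basic_model()
  expect_error(run_protocol(spec, manipulations = list(
    manipulation("silence_unit", "NoSuchUnit"))), "unknown unit")
  expect_error(run_protocol(spec, manipulations = list(
    manipulation("block_connection", c("MeA", "dPag1")))), "no connection")
  expect_error(manipulation("scale_connection", c("LS", "Hyp1"),
                            magnitude = -1), ">= 0")
})

test_that("the MDT stimulation block encodes the HFS/LFS contracts", {
  spec <- build_basic_model()
  hfs <- mdt_stimulation_block(spec, "HFS")
  lfs <- mdt_stimulation_block(spec, "LFS")
  expect_equal(hfs$phase$name, "stimulation")
  expect_gt(hfs$amplitude, lfs$amplitude)
  # a grossly mis-set amplitude fails the calibration check
  expect_error(mdt_stimulation_block(spec, "HFS", amplitude = 0.05),
               "calibration")

  # stimulation with plasticity globally frozen leaves extinction unchanged
  frozen <- append(hfs$manipulations,
                   list(manipulation("freeze_plasticity", "all",
                                     phases = "stimulation")))
  proto <- default_protocol()
  proto_stim <- protocol_spec(append(proto$phases, list(hfs$phase),
                                     after = 2), proto$sim)
  res <- run_protocol(spec, proto_stim, frozen)
  ctrl <- run_protocol(spec, proto)
  expect_identical(trials_to_extinction(res), trials_to_extinction(ctrl))
})
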