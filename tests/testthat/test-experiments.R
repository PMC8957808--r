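# Shared control run for this file (the default protocol on the main model).
ctrl <- run_protocol(build_basic_model())

test_that("avoidance_index is the trial-mean dPag1 rate", {
  tr <- matrix(0, 2, 10, dimnames = list(c("dPag1", "x"), NULL))
  expect_identical(avoidance_index(tr), 0)
  tr["dPag1", ] <- 0.6
  expect_equal(avoidance_index(tr), 0.6)
  expect_error(avoidance_index(tr[2, , drop = FALSE]), "dPag1")
  # baseline trial of the shipped model stays below the avoidance threshold
  expect_lt(avoidance_index(ctrl)[1], 0.1)
})

test_that("classification is a pure function of the two responsiveness flags", {
  fake <- ctrl
  set_unit <- function(res, unit, first, last) {
    ext <- which(res$meta$phase == "extinction")
    res$traces[unit, , ext[1]] <- first
    res$traces[unit, , ext[length(ext)]] <- last
    res
  }
  fake <- set_unit(fake, "MeA", 0.5, 0.01)
  expect_identical(classify_unit(fake, "MeA")$class, "fear")
  fake <- set_unit(fake, "MeA", 0.01, 0.5)
  expect_identical(classify_unit(fake, "MeA")$class, "extinction")
  fake <- set_unit(fake, "MeA", 0.5, 0.5)
  expect_identical(classify_unit(fake, "MeA")$class, "persistent")
  fake <- set_unit(fake, "MeA", 0.01, 0.01)
  expect_identical(classify_unit(fake, "MeA")$class, "none")
  expect_error(classify_unit(ctrl, "NoSuchUnit"), "unit")
  # totality: every unit receives exactly one class
  cls <- classify_units(ctrl)
  expect_equal(nrow(cls), 16)
  expect_true(all(cls$class %in% c("fear", "extinction", "persistent",
                                   "none")))
})

test_that("unknown experiment names list the valid ones", {
  expect_error(reproduce_experiment("nope"), "silva_vmhvl_inhibition")
  expect_error(run_prediction("nope"), "vmhvl_plasticity_block")
})

test_that("every reproduction passes on the shipped main model", {
  for (nm in c("silva_vmhvl_inhibition", "franklin_pyr2_block",
               "xu_pv_stimulation", "xu_som_inhibition",
               "krzywkowski_context")) {
    rep <- reproduce_experiment(nm, control = ctrl)
    expect_true(rep$pass, label = nm)
  }
})

test_that("reproduction reports carry their control metrics", {
  rep <- reproduce_experiment("silva_vmhvl_inhibition", control = ctrl)
  expect_lt(rep$metrics$dpag_manipulated, rep$metrics$dpag_control)
  rep <- reproduce_experiment("xu_pv_stimulation", control = ctrl)
  expect_lt(rep$metrics$trials_to_extinction,
            rep$metrics$trials_to_extinction_control)
})

test_that("every prediction passes on the shipped models", {
  for (nm in c("vmhvl_plasticity_block", "lpbn_block", "pyr2_stimulation",
               "mdt_hfs", "mdt_lfs")) {
    pred <- run_prediction(nm, control = ctrl)
    expect_true(pred$pass, label = nm)
  }
  expect_error(run_prediction("ls_scaling"), "alternative model")
  pred <- run_prediction("ls_scaling", spec = build_alternative_model(),
                         reductions = c(0, 5, 10))
  expect_true(pred$pass)
})

test_that("the LS sweep at zero reduction matches the unmanipulated control", {
  sw <- ls_scaling_sweep(build_alternative_model(), reductions = c(0, 2))
  expect_identical(sw$trials_to_extinction[sw$reduction == 0],
                   attr(sw, "control"))
})

test_that("the qualitative checklist passes on the shipped configuration", {
  flags <- qualitative_criteria()
  expect_true(all(flags))
  expect_setequal(names(flags), c(
    "baseline_quiet", "conditioning_avoidance", "extinction_completes",
    "vmhvl_weights_stable", "silva_vmhvl_inhibition", "franklin_pyr2_block",
    "xu_pv_stimulation", "xu_som_inhibition", "krzywkowski_context"))
})

test_that("breaking the circuit breaks the checklist", {
  # without the prefrontal brake the baseline is no longer quiet
  no_brake <- set_weight(build_basic_model(), "Pyr2", "dPag1", 0)
  flags <- qualitative_criteria(no_brake, include_weight_stability = FALSE)
  expect_false(flags["baseline_quiet"])
  # without plasticity no fear memory forms: the learned context
  # specificity (and the manipulation-induced accelerations) disappear
  frozen <- build_basic_model()
  frozen$plasticity$enabled <- FALSE
  flags <- qualitative_criteria(frozen, include_weight_stability = FALSE)
  expect_false(flags["krzywkowski_context"])
  expect_false(all(flags))
})

test_that("sensitivity_sweep reports tolerated ranges around the shipped value", {
  sens <- sensitivity_sweep(build_basic_model(),
                            edges = data.frame(pre = c("MDT", "Som3"),
                                               post = c("Pyr1", "Pyr1")),
                            scales = c(0.9, 1, 1.1))
  expect_equal(nrow(sens), 2)
  grid <- attr(sens, "grid")
  expect_true(all(grid[, "1"]))  # the shipped configuration passes
  expect_true(all(sens$lo_pct <= 0 & sens$hi_pct >= 0))
  expect_error(sensitivity_sweep(build_basic_model(), scales = c(0.5, 2)),
               "1.0")
})
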