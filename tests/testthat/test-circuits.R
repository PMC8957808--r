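test_that("the basic circuit has the published architecture", {
  net <- build_basic_model()
  expect_equal(nrow(net$units), 16)
  expect_length(validate_spec(net), 0)

  co <- net$connections
  # dPag1 receives exactly two afferents: excitatory Hyp1, inhibitory Pyr2
  aff <- co[co$post == "dPag1", ]
  expect_setequal(aff$pre, c("Hyp1", "Pyr2"))
  expect_gt(aff$weight[aff$pre == "Hyp1"], 0)
  expect_lt(aff$weight[aff$pre == "Pyr2"], 0)

  # double-inhibition circuit onto Pyr1: Som1 -| Pv -| Pyr1
  expect_lt(co$weight[co$pre == "Som1" & co$post == "Pv"], 0)
  expect_lt(co$weight[co$pre == "Pv" & co$post == "Pyr1"], 0)

  # winner-take-all loops through the hypothalamic interneurons
  expect_lt(co$weight[co$pre == "HypIN1" & co$post == "Hyp1"], 0)
  expect_lt(co$weight[co$pre == "HypIN2" & co$post == "Hyp2"], 0)

  # plastic edge roster: VMHvl afferents plus MDT efferents
  plastic <- paste0(co$pre, "->", co$post)[co$plastic]
  expect_setequal(plastic, c(
    "MeA->Hyp1", "MeA->Hyp2", "Hip1->Hyp1", "Hip1->Hyp2",
    "Hip2->Hyp1", "Hip2->Hyp2", "MDT->Pyr1", "MDT->Pyr2", "MDT->Pv"))
  # GABAergic outgoing connections are never plastic
  gaba <- net$units$name[net$units$sign == "-"]
  expect_false(any(co$plastic & co$pre %in% gaba))
})

test_that("contexts are symmetric before learning", {
  co <- build_basic_model()$connections
  w <- function(pre, post) co$weight[co$pre == pre & co$post == post]
  expect_identical(w("Hip1", "Hyp1"), w("Hip2", "Hyp1"))
  expect_identical(w("Hip1", "Hyp2"), w("Hip2", "Hyp2"))
})

test_that("the alternative circuit adds exactly the LS unit and its links", {
  alt <- build_alternative_model()
  expect_equal(nrow(alt$units), 17)
  expect_length(validate_spec(alt), 0)
  expect_true("LS" %in% alt$units$name)
  expect_identical(alt$units$sign[alt$units$name == "LS"], "-")

  basic <- build_basic_model()
  expect_setequal(setdiff(alt$units$name, basic$units$name), "LS")
  lab <- function(s) paste0(s$connections$pre, "->", s$connections$post)
  expect_setequal(setdiff(lab(alt), lab(basic)), "LS->Hyp1")

  # Hyp1 gains exactly one new afferent and it is inhibitory
  new_aff <- alt$connections[alt$connections$pre == "LS", ]
  expect_equal(nrow(new_aff), 1)
  expect_lt(new_aff$weight, 0)
  # LS is driven by the conspecific channel
  expect_true("LS" %in% alt$input_channels$conspecific$unit)
})

test_that("validate_spec reports constructed violations", {
  net <- build_basic_model()

  bad <- net
  bad$connections$weight[bad$connections$pre == "Pv" &
                           bad$connections$post == "Pyr1"] <- +0.5
  v <- validate_spec(bad)
  expect_length(v, 1)
  expect_match(v, "Pv->Pyr1")

  bad <- net
  bad$connections$w_min[bad$connections$pre == "MeA" &
                          bad$connections$post == "Hyp1"] <- NA
  expect_match(validate_spec(bad), "lacks clip bounds")

  bad <- net
  bad$connections$pre[1] <- "NoSuchUnit"
  expect_match(validate_spec(bad), "unknown unit", all = FALSE)

  bad <- net
  bad$connections$pre[1] <- bad$connections$post[1]
  expect_match(validate_spec(bad), "self-connection", all = FALSE)
})

test_that("mutual inhibition implements a winner-take-all", {
  spec <- build_basic_model()
  spec$plasticity$enabled <- FALSE
  probe <- function(sp, a1, a2) {
    out <- run_trial(sp, phase("probe", 1, numeric(0)),
                     manipulations = list(
                       manipulation("stimulate_unit", "Hyp1", a1),
                       manipulation("stimulate_unit", "Hyp2", a2)))
    rowMeans(out$trace[, 400:500])
  }
  r <- probe(spec, 1.0, 0.6)
  expect_gt(r["Hyp1"], r["Hyp2"])
  # the gap widens as the interneuron weights strengthen
  stronger <- set_weight(set_weight(spec, "HypIN1", "Hyp1", -1.8),
                         "HypIN2", "Hyp2", -1.8)
  r2 <- probe(stronger, 1.0, 0.6)
  expect_gt(r2["Hyp1"] - r2["Hyp2"], r["Hyp1"] - r["Hyp2"])
})

test_that("the threat and interaction populations are antagonistic", {
  res <- run_protocol(build_basic_model())
  h1 <- trial_means(res, "Hyp1")
  h2 <- trial_means(res, "Hyp2")
  expect_lt(cor(h1, h2), 0)
})

test_that("silencing the LS blocks VMHvl depotentiation during extinction", {
  alt <- build_alternative_model()
  control <- run_protocol(alt)
  blocked <- run_protocol(alt, manipulations = list(
    manipulation("scale_connection", c("LS", "Hyp1"), magnitude = 0,
                 phases = "extinction")))
  last_cond <- max(control$meta$trial[control$meta$phase == "conditioning"])
  last_ext <- max(control$meta$trial[control$meta$phase == "extinction"])
  drop_ctrl <- control$weights["Hyp1", "MeA", last_cond] -
    control$weights["Hyp1", "MeA", last_ext]
  drop_blocked <- blocked$weights["Hyp1", "MeA", last_cond] -
    blocked$weights["Hyp1", "MeA", last_ext]
  expect_gt(drop_ctrl, 0.05)          # control depotentiates
  expect_lt(abs(drop_blocked), 1e-6)  # without LS the memory is locked in
})
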