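test_that("variant rosters match the published species lists", {
  me <- build_model("enhanced")
  expect_equal(nrow(me$species), 18)
  expect_setequal(
    me$species$class[me$species$name %in% c("TGFB3", "SOX9")], "protein")
  expect_equal(sum(me$species$class == "miRNA"), 3)
  expect_equal(sum(me$species$class == "drug"), 2)
  expect_equal(sum(me$species$class == "phenotype"), 1)
  mi <- build_model("initial")
  expect_equal(nrow(mi$species), 11)
  expect_false("TGFB3" %in% mi$species$name)
})

test_that("every species has at least one source and one sink reaction", {
  for (variant in c("initial", "enhanced")) {
    m <- build_model(variant)
    expect_silent(validate_model(m))
    produced <- consumed <- character(0)
    for (r in m$reactions) {
      if (r$type %in% c("source", "activation", "sat_activation",
                        "inhibited_source"))
        produced <- c(produced, r$target)
      if (r$type == "inhibited_conversion") {
        produced <- c(produced, r$product)
        consumed <- c(consumed, r$reactant)
      }
      if (r$type %in% c("sink", "mirna_decay"))
        consumed <- c(consumed, r$target)
    }
    expect_length(setdiff(m$species$name, produced), 0)
    expect_length(setdiff(m$species$name, consumed), 0)
  }
})

test_that("build_model rejects missing and negative parameters", {
  p <- default_params("enhanced")
  expect_error(build_model("enhanced", params = p[-match("kphos", names(p))]),
               "missing parameter")
  p2 <- p; p2["kphos"] <- -1
  expect_error(build_model("enhanced", params = p2), "negative parameter")
})

test_that("without TGFB3 stimulus the system settles to a basal steady state", {
  p <- default_params("enhanced")
  p["src_TGFB3"] <- 0
  y0 <- default_initials("enhanced")
  y0["TGFB3"] <- 0
  m <- build_model("enhanced", params = p, initial = y0, horizon = 1000)
  eq <- simulate_model(m, times = c(0, 500))$states[2, ]
  m2 <- build_model("enhanced", params = p, initial = eq, horizon = 100)
  tr <- simulate_model(m2, times = c(0, 50))
  expect_lt(max(abs(tr$states[2, ] - eq) / pmax(eq, 1e-8)), 1e-4)
})

test_that("raising a miRNA never raises its direct target's steady state", {
  fzd6 <- vapply(c(0.05, 0.1, 0.3, 0.6, 1.2), function(s) {
    p <- default_params("enhanced")
    p["src_miR199a5p"] <- s
    m <- build_model("enhanced", params = p, horizon = 1000)
    simulate_model(m, times = c(0, 400))$states[2, "FZD6"]
  }, 0)
  expect_true(all(diff(fzd6) <= 1e-10))
})

test_that("trajectories stay non-negative across a random parameter grid", {
  set.seed(42)
  for (i in 1:8) {
    p <- default_params("enhanced")
    p <- p * exp(stats::rnorm(length(p), sd = 0.5))
    p[c("src_hpmiR199a5p", "src_hpmiR199b5p")] <- 0
    m <- apply_inhibition(build_model("enhanced", params = p), "both")
    tr <- simulate_model(m, times = seq(0, 14, by = 0.5))
    expect_gte(min(tr$states), -1e-9)
  }
})

test_that("inhibition lowers chondrogenic outputs and raises miR-199 targets at day 7", {
  for (variant in c("initial", "enhanced")) {
    ctrl <- simulate_model(build_model(variant), times = c(0, 7, 14))
    inh <- simulate_model(apply_inhibition(build_model(variant), "both"),
                          times = c(0, 7, 14))
    for (s in c("ACAN_mRNA", "COL2A1_mRNA", "GAG"))
      expect_lte(inh$states[2, s], ctrl$states[2, s])
    for (s in c("FZD6", "ITGA3", "CAV1"))
      expect_gte(inh$states[2, s], ctrl$states[2, s])
  }
})

test_that("after release the inhibited trajectory converges back to control", {
  ctrl <- simulate_model(build_model("enhanced"), times = c(0, 4.5, 14))
  inh <- simulate_model(apply_inhibition(build_model("enhanced"), "both"),
                        times = c(0, 4.5, 14))
  biom <- c("ACAN_mRNA", "COL2A1_mRNA", "GAG", "FZD6", "ITGA3", "CAV1")
  d_off <- sqrt(sum((inh$states[2, biom] - ctrl$states[2, biom])^2))
  d_14 <- sqrt(sum((inh$states[3, biom] - ctrl$states[3, biom])^2))
  expect_lt(d_14, d_off)
})

test_that("apply_inhibition defaults and guards follow the event contract", {
  expect_equal(apply_inhibition(build_model("enhanced"),
                                "miR-199b-5p")$events[[1]]$t_off, 4.5)
  expect_equal(apply_inhibition(build_model("initial"),
                                "miR-199a-5p")$events[[1]]$t_off, 7)
  expect_error(apply_inhibition(build_model("enhanced"), "miR-199a-5p",
                                eps = 1), "eps")
  m0 <- apply_inhibition(build_model("enhanced"), "miR-199a-5p", eps = 0)
  t <- seq(0, 14, by = 1)
  expect_equal(simulate_model(m0, times = t)$states[, "ACAN_mRNA"],
               simulate_model(build_model("enhanced"),
                              times = t)$states[, "ACAN_mRNA"],
               tolerance = 1e-8)
})
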