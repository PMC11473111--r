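test_that("generators are deterministic under a fixed seed", {
  tr <- ground_truth(data.frame(mirna = "mir_001", gene = "gene_0001"),
                     noise_sd = 0.1, seed = 11)
  a <- generate_timecourse(tr, n_genes = 30, n_mirnas = 5)
  b <- generate_timecourse(tr, n_genes = 30, n_mirnas = 5)
  expect_identical(a, b)
  pa <- generate_prediction_tables(tr, n_decoys = 10)
  pb <- generate_prediction_tables(tr, n_decoys = 10)
  expect_identical(pa, pb)
  m <- build_model("enhanced")
  qa <- generate_qpcr_experiment(m, tr, replicates = 3)
  qb <- generate_qpcr_experiment(m, tr, replicates = 3)
  expect_identical(qa, qb)
})

test_that("generators never disturb the caller's RNG stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(generate_timecourse(ground_truth(seed = 1), 10, 2))
  expect_identical(stats::runif(1), before)
})

test_that("planted pairs are perfectly anticorrelated at zero noise", {
  tr <- ground_truth(data.frame(mirna = "mir_001", gene = "gene_0001"),
                     noise_sd = 0, seed = 2)
  tc <- generate_timecourse(tr, n_genes = 20, n_mirnas = 3)
  mp <- tc$mirna_de$log2fc[tc$mirna_de$id == "mir_001"]
  gp <- tc$mrna_de$log2fc[tc$mrna_de$id == "gene_0001"]
  expect_equal(stats::cor(mp, gp), -1)
  expect_equal(gp, -mp)
})

test_that("planted pathway enrichment forces member significance at chosen timepoints", {
  members <- sprintf("gene_%04d", 1:10)
  tr <- ground_truth(pathway_memberships = list(pw = members),
                     enriched_timepoints = list(pw = c("D1", "D3", "D6")),
                     noise_sd = 0, seed = 3)
  tc <- generate_timecourse(tr, n_genes = 50, n_mirnas = 2)
  de <- tc$mrna_de
  planted <- de[de$id %in% members & de$timepoint %in% c("D1", "D3", "D6"), ]
  expect_true(all(planted$adj_p < 0.05))
})

test_that("generator guards reject invalid requests", {
  tr <- ground_truth(data.frame(mirna = "mir_099", gene = "gene_0001"))
  expect_error(generate_timecourse(tr, n_genes = 10, n_mirnas = 2),
               "missing entity")
  expect_error(generate_qpcr_experiment(build_model("enhanced"),
                                        ground_truth(), replicates = 0),
               "replicates")
  expect_error(generate_qpcr_experiment(build_model("enhanced"),
                                        ground_truth(),
                                        analytes = "NOT_A_SPECIES"),
               "unknown analyte")
})

test_that("prediction tables plant votes >= 2 for true pairs and <= 1 for decoys", {
  ti <- data.frame(mirna = sprintf("mir_%03d", 1:5),
                   gene = sprintf("gene_%04d", 1:5))
  tr <- ground_truth(ti, seed = 4)
  preds <- generate_prediction_tables(tr, n_decoys = 30)
  votes <- tapply(preds$source, paste(preds$mirna, preds$gene),
                  function(x) length(unique(x)))
  truekey <- paste(ti$mirna, ti$gene)
  expect_true(all(votes[truekey] >= 2))
  expect_true(all(votes[setdiff(names(votes), truekey)] <= 1))
  expect_true(all(preds$score > 0))
  # n_decoys = 0: every listed pair is a true pair
  p0 <- generate_prediction_tables(tr, n_decoys = 0)
  expect_true(all(paste(p0$mirna, p0$gene) %in% truekey))
})

test_that("zero-noise qPCR values equal the deterministic simulated ratios", {
  m <- build_model("enhanced")
  q <- generate_qpcr_experiment(m, ground_truth(noise_sd = 0, seed = 1),
                                conditions = "inh-199b", replicates = 4)
  days <- sort(unique(q$qpcr$day))
  ctrl <- simulate_model(m, times = days)
  inh <- simulate_model(chondromir:::.condition_model(m, "inh-199b"),
                        times = days)
  for (an in unique(q$qpcr$analyte)) {
    sub <- q$qpcr[q$qpcr$analyte == an & q$qpcr$condition == "inh-199b", ]
    expected <- 100 * inh$states[match(sub$day, days), an] /
      ctrl$states[match(sub$day, days), an]
    expect_equal(sub$pct_control, unname(expected), tolerance = 1e-10)
    subc <- q$qpcr[q$qpcr$analyte == an & q$qpcr$condition == "control", ]
    expect_equal(subc$pct_control, rep(100, nrow(subc)))
  }
  # replicates within a zero-noise cell are identical
  expect_equal(stats::sd(q$qpcr$pct_control[1:4]), 0)
})

test_that("control means are exactly 100% per analyte and day by construction", {
  q <- generate_qpcr_experiment(build_model("enhanced"),
                                ground_truth(noise_sd = 0.2, seed = 6))$qpcr
  ctrl <- q[q$condition == "control", ]
  means <- tapply(ctrl$pct_control, paste(ctrl$analyte, ctrl$day), mean)
  expect_equal(as.vector(means), rep(100, length(means)))
})

test_that("day-0 samples precede the event: control and inhibition coincide at zero noise", {
  q <- generate_qpcr_experiment(build_model("enhanced"),
                                ground_truth(noise_sd = 0, seed = 1),
                                conditions = "inh-199a", replicates = 2)$qpcr
  d0 <- q[q$day == 0, ]
  for (an in unique(d0$analyte))
    expect_equal(unique(d0$pct_control[d0$analyte == an]), 100)
})

test_that("noisy replicate means stay near the deterministic values (3 SE, delta method)", {
  m <- build_model("enhanced")
  det <- generate_qpcr_experiment(m, ground_truth(noise_sd = 0, seed = 1),
                                  conditions = "inh-199a", replicates = 1)
  detq <- det$qpcr[det$qpcr$condition == "inh-199a", ]
  fails <- 0; tot <- 0
  for (s in 1:5) {
    q <- generate_qpcr_experiment(m, ground_truth(noise_sd = 0.1, seed = s),
                                  conditions = "inh-199a")$qpcr
    for (an in unique(q$analyte)) for (d in unique(q$day)) {
      x <- q$pct_control[q$condition == "inh-199a" & q$analyte == an &
                           q$day == d]
      ctrl <- q$pct_control[q$condition == "control" & q$analyte == an &
                              q$day == d]
      n <- length(x)
      se <- mean(x) * sqrt(stats::var(x) / mean(x)^2 / n +
                             stats::var(ctrl) / mean(ctrl)^2 / n)
      dv <- detq$pct_control[detq$analyte == an & detq$day == d]
      tot <- tot + 1
      if (abs(mean(x) - dv) > 3 * se) fails <- fails + 1
    }
  }
  expect_lt(fails / tot, 0.15)
})

test_that("tabular and GMT writers round-trip through files", {
  st <- small_study()
  d <- withr::local_tempdir()
  f <- file.path(d, "mrna.tsv")
  write_de_table(st$mrna_de, f)
  expect_equal(read_de_table(f), st$mrna_de, tolerance = 1e-12)
  fp <- file.path(d, "preds.csv")
  write_predictions(st$predictions, fp)
  expect_equal(read_predictions(fp), st$predictions, tolerance = 1e-12)
  fq <- file.path(d, "qpcr.tsv")
  write_qpcr(st$qpcr, fq)
  expect_equal(read_qpcr(fq), st$qpcr, tolerance = 1e-12)
  fg <- file.path(d, "sets.gmt")
  write_gmt(st$pathways, fg)
  expect_equal(read_gmt(fg), st$pathways)
})
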