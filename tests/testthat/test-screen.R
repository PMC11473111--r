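test_that("significance filtration uses a strict adjusted-p threshold", {
  de <- data.frame(id = c("g1", "g2", "g3", "g1"),
                   timepoint = c("D1", "D1", "D1", "D3"),
                   log2fc = 1, adj_p = c(0.049, 0.05, 1, 0.2))
  sets <- filter_significant(de, 0.05)
  expect_equal(sets$D1, "g1")      # 0.049 in, 0.05 (boundary) out
  expect_length(sets$D3, 0)
  all_ns <- transform(de, adj_p = 1)
  expect_true(all(lengths(filter_significant(all_ns, 0.05)) == 0))
  empty <- de[0, ]
  expect_length(filter_significant(empty, 0.05), 0)
})

test_that("ORA matches the exhaustive hypergeometric oracle on an N<=60 grid", {
  set.seed(7)
  cases <- 0
  for (N in c(10, 20, 35, 50, 60)) {
    bg <- sprintf("g%03d", 1:N)
    for (rep in 1:8) {
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      kr <- max(0, n - (N - K)):min(K, n)
      k <- kr[sample.int(length(kr), 1)]
      pathway <- list(pw = bg[seq_len(K)])
      selected <- c(bg[seq_len(k)],
                    if (n > k) bg[K + seq_len(n - k)])
      res <- ora(selected, pathway, bg)
      expect_equal(res$k, k)
      expect_lt(abs(res$p - hyper_tail_oracle(k, K, N, n)), 1e-12)
      cases <- cases + 1
    }
  }
  expect_gte(cases, 40)
})

test_that("ORA extreme cases and input guards behave", {
  bg <- sprintf("g%02d", 1:20)
  # full enrichment: k = n = K
  res <- ora(bg[1:5], list(pw = bg[1:5]), bg)
  expect_equal(res$p, 1 / choose(20, 5))
  # zero overlap: upper tail from 0 is 1
  res0 <- ora(bg[6:10], list(pw = bg[1:5]), bg)
  expect_equal(res0$p, 1)
  expect_error(ora(c("zzz"), list(pw = bg[1:5]), bg), "subset")
  expect_message(ora(bg[1:5], list(pw = "not_in_background"), bg), "skipped")
})

test_that("BH adjustment is monotone and never below the raw p", {
  bg <- sprintf("g%03d", 1:60)
  pw <- lapply(1:10, function(i) bg[seq(i, i + 20)])
  names(pw) <- paste0("pw", 1:10)
  res <- ora(bg[seq(1, 40, by = 2)], pw, bg)
  expect_true(all(res$adj_p >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$adj_p[ord]) >= -1e-15))
})

test_that("recurrent pathway selection counts distinct significant timepoints", {
  res <- data.frame(
    pathway = c("A", "A", "A", "B", "B", "C"),
    timepoint = c("D1", "D3", "D6", "D1", "D3", "D1"),
    adj_p = c(0.01, 0.02, 0.04, 0.01, 0.01, 0.2))
  expect_equal(recurrent_pathways(res, 0.05, 3), "A")
  expect_setequal(recurrent_pathways(res, 0.05, 1), c("A", "B"))
  expect_length(recurrent_pathways(res, 0.05, 4), 0)
})

test_that("interaction screen applies strict anticorrelation and vote thresholds", {
  mirna_de <- de_row("mir1", 1:5)
  mrna_de <- rbind(de_row("gA", -(1:5)), de_row("gB", c(2, 1, 3, 1, 2)),
                   de_row("gC", rep(1, 5)))
  preds <- data.frame(
    mirna = "mir1", gene = c("gA", "gA", "gB", "gB", "gC", "gC"),
    source = c("s1", "s2", "s1", "s2", "s1", "s2"), score = 90)
  sc <- screen_interactions(mirna_de, mrna_de, preds)
  expect_true(sc$passed[sc$gene == "gA"])
  expect_equal(sc$pearson_r[sc$gene == "gA"], -1)
  expect_false(sc$passed[sc$gene == "gB"])
  # zero-variance profile: undefined correlation, recorded reason
  expect_true(is.na(sc$pearson_r[sc$gene == "gC"]))
  expect_equal(sc$reason[sc$gene == "gC"], "zero-variance profile")

  # r exactly -0.75 fails the strict threshold; construct y with
  # cor(x, y) = -0.75 exactly via Gram-Schmidt
  x <- c(1, 2, 3, 4, 5)
  e <- c(1, -1, 0, 1, -1); e <- e - mean(e)
  e <- e - sum(e * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  y <- -0.75 * (x - mean(x)) / sqrt(sum((x - mean(x))^2)) +
    sqrt(1 - 0.75^2) * e / sqrt(sum(e^2))
  expect_equal(stats::cor(x, y), -0.75)
  sc2 <- screen_interactions(de_row("mir1", x), de_row("gD", y),
                             data.frame(mirna = "mir1", gene = "gD",
                                        source = c("s1", "s2"), score = 1))
  expect_false(sc2$passed)

  # strong anticorrelation but a single vote fails
  sc3 <- screen_interactions(de_row("mir1", x), de_row("gE", -x),
                             data.frame(mirna = "mir1", gene = "gE",
                                        source = "s1", score = 1))
  expect_equal(sc3$votes, 1L)
  expect_false(sc3$passed)

  # duplicate rows within one source still count one vote
  sc4 <- screen_interactions(de_row("mir1", x), de_row("gE", -x),
                             data.frame(mirna = "mir1", gene = "gE",
                                        source = c("s1", "s1", "s2"),
                                        score = 1))
  expect_equal(sc4$votes, 2L)
  expect_true(sc4$passed)
})

test_that("interaction screen is invariant to input row order", {
  st <- small_study()
  sc1 <- screen_interactions(st$mirna_de, st$mrna_de, st$predictions)
  set.seed(1)
  sc2 <- suppressMessages(screen_interactions(
    st$mirna_de[sample(nrow(st$mirna_de)), ],
    st$mrna_de[sample(nrow(st$mrna_de)), ],
    st$predictions[sample(nrow(st$predictions)), ]))
  expect_equal(sc1, sc2)
})

test_that("zero-noise planted pairs are recovered exactly", {
  st <- small_study(noise_sd = 0, seed = 5)
  sc <- screen_interactions(st$mirna_de, st$mrna_de, st$predictions)
  hits <- sort(paste(sc$mirna, sc$gene)[sc$passed])
  planted <- sort(paste(st$truth$true_interactions$mirna,
                        st$truth$true_interactions$gene))
  expect_equal(hits, planted)
})

test_that("profile scaling standardizes with the n-1 denominator and flags +1 peaks", {
  sc <- scale_profiles(de_row("g", c(0, 0, 0, 0, 5)))
  expect_equal(max(sc[, 2:6]), 4 / sqrt(5))  # hand computation: (5-1)/sd, sd = sqrt(5)
  expect_true(sc$highlighted)

  expect_warning(sc2 <- scale_profiles(de_row("g", rep(2, 5))), "constant")
  expect_equal(unlist(sc2[, 2:6], use.names = FALSE), rep(0, 5))
  expect_false(sc2$highlighted)

  set.seed(2)
  for (i in 1:5) {
    prof <- stats::rnorm(5, sd = i)
    sc3 <- scale_profiles(de_row("g", prof))
    v <- unlist(sc3[, 2:6], use.names = FALSE)
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(stats::sd(v), 1, tolerance = 1e-9)
  }

  # purely negative excursions are not highlighted (signed rule)
  sc4 <- scale_profiles(de_row("g", c(0, 0, 0, 0, -5)))
  expect_false(sc4$highlighted)
})
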