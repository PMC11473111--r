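test_that("rank aggregation scores follow the table-size-anchored points rule", {
  # top rank in all three sources of size 100 -> 300 points
  genes <- sprintf("g%03d", 1:100)
  preds <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(s)
    data.frame(mirna = "mir", gene = genes, source = s,
               score = 100:1)))
  agg <- aggregate_targets(preds, "mir")
  expect_equal(agg$score[agg$gene == "g001"], 300)
  expect_equal(agg$n_sources[agg$gene == "g001"], 3L)

  # two sources of size 10, ranked 1 and 10 -> 10 + 1 = 11
  p2 <- rbind(
    data.frame(mirna = "mir", gene = sprintf("a%02d", 1:10), source = "s1",
               score = 10:1),
    data.frame(mirna = "mir", gene = c(sprintf("b%02d", 1:9), "a01"),
               source = "s2", score = 10:1))
  agg2 <- aggregate_targets(p2, "mir")
  expect_equal(agg2$score[agg2$gene == "a01"], 11)

  # gene absent everywhere is not emitted
  expect_false("zzz" %in% agg2$gene)
  expect_equal(nrow(aggregate_targets(preds, "other_mir")), 0)
})

test_that("aggregate score is monotone in a single source's evidence", {
  base <- data.frame(mirna = "mir", gene = c("a", "b", "c"), source = "s1",
                     score = c(3, 2, 1))
  low <- aggregate_targets(base, "mir")
  base$score[base$gene == "b"] <- 5   # b climbs the ranking
  high <- aggregate_targets(base, "mir")
  expect_gt(high$score[high$gene == "b"], low$score[low$gene == "b"])
})

test_that("candidate selection applies the score, upregulation and trajectory rules", {
  agg <- data.frame(mirna = "mir",
                    gene = c("keep", "lowscore", "exact50", "down",
                             "negtail", "missing"),
                    score = c(80, 20, 50, 80, 80, 80), n_sources = 2)
  inhib <- data.frame(id = c("keep", "lowscore", "exact50", "down",
                             "negtail", "missing"),
                      day = c(1, 1, 0, 0, 1, 1),
                      log2fc = c(1, 1, 1, -2, 1, 1),
                      adj_p = 0.01)
  tc <- rbind(de_row("keep", c(1, 1, 1, 1, 0.5)),
              de_row("lowscore", rep(1, 5)),
              de_row("exact50", rep(1, 5)),
              de_row("down", rep(1, 5)),
              de_row("negtail", c(1, 1, 1, 1, -2)))
  sel <- suppressMessages(
    select_candidates(agg, inhib, tc, score_min = 50, alpha = 0.05))
  expect_equal(sel, "keep")
  # score 50 exactly is removed ("50 or below"); score 51 passes
  agg$score[agg$gene == "exact50"] <- 51
  expect_setequal(
    suppressMessages(select_candidates(agg, inhib, tc)), c("keep", "exact50"))
  # non-significant upregulation fails
  inhib$adj_p[inhib$id == "keep"] <- 0.06
  expect_false("keep" %in% suppressMessages(select_candidates(agg, inhib, tc)))
})

test_that("candidate selection is order-invariant and a subset of score-passers", {
  st <- small_study()
  preds <- st$predictions
  mir <- st$truth$true_interactions$mirna[1]
  agg <- aggregate_targets(preds, mir)
  inhib <- data.frame(id = agg$gene, day = 1, log2fc = 1, adj_p = 0.01)
  sel <- suppressMessages(select_candidates(agg, inhib, st$mrna_de,
                                            score_min = 0))
  set.seed(3)
  sel2 <- suppressMessages(select_candidates(
    agg[sample(nrow(agg)), ], inhib[sample(nrow(inhib)), ], st$mrna_de,
    score_min = 0))
  expect_equal(sel, sel2)
  expect_true(all(sel %in% agg$gene[agg$score > 0]))
})

test_that("chi-square overlap statistic reproduces the row/column-total formula", {
  res <- chi_square_overlap(c(10, 20, 30, 40))
  expect_equal(res$expected, c(12, 18, 28, 42))
  expect_equal(res$chi2, 4 / 12 + 4 / 18 + 4 / 28 + 4 / 42)
  expect_equal(res$chi2, 0.7936507936507935, tolerance = 1e-12)
  expect_equal(res$p, stats::pchisq(res$chi2, 1, lower.tail = FALSE))
  expect_equal(res$df, 1L)

  # perfect independence: chi2 = 0, p = 1
  res0 <- chi_square_overlap(c(10, 10, 10, 10))
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)

  # doubling all counts doubles the statistic
  set.seed(9)
  for (i in 1:10) {
    tab <- sample(1:50, 4, replace = TRUE)
    a <- chi_square_overlap(tab)$chi2
    b <- chi_square_overlap(2 * tab)$chi2
    expect_equal(b, 2 * a, tolerance = 1e-12)
    expect_gte(a, 0)
    p <- chi_square_overlap(tab)$p
    expect_true(p > 0 && p <= 1)
  }

  expect_error(chi_square_overlap(c(0, 0, 5, 5)), "expected count is zero")
  expect_error(chi_square_overlap(c(-1, 2, 3, 4)), "non-negative")
})

test_that("overlap_table cross-classifies DE sets against the universe", {
  u <- sprintf("g%02d", 1:20)
  tab <- overlap_table(u[1:8], u[5:10], u)
  expect_equal(unname(tab), c(4, 4, 2, 10))
  expect_equal(sum(tab), 20)
  expect_error(overlap_table("nope", u[1:2], u), "subsets")
})

test_that("planted upregulated targets are all recovered at zero noise", {
  st <- small_study(noise_sd = 0, seed = 5)
  mir <- st$truth$true_interactions$mirna[1]
  gene <- st$truth$true_interactions$gene[1]
  agg <- aggregate_targets(st$predictions, mir)
  inhib <- data.frame(id = gene, day = 1, log2fc = 2, adj_p = 0.001)
  tc <- st$mrna_de
  tc$log2fc[tc$id == gene] <- abs(tc$log2fc[tc$id == gene])
  sel <- suppressMessages(
    select_candidates(agg, inhib, tc, score_min = 0))
  expect_true(gene %in% sel)
})
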