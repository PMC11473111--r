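#' Aggregate miRNA target predictions across sources by rank
#'
#' Scores each predicted gene of a miRNA across up to three prediction
#' sources. Within each source genes are ranked by decreasing score; rank 1
#' earns as many points as the source has entries for that miRNA, the last
#' rank earns 1 point, and a gene absent from a source earns 0 from it. The
#' aggregate score is the sum of points over sources, so it is monotone
#' non-decreasing in any single source's evidence.
#'
#' @param predictions Data frame with columns `mirna`, `gene`, `source`,
#'   `score`.
#' @param mirna miRNA id to aggregate targets for.
#' @return Data frame with `mirna`, `gene`, `score` (aggregate points) and
#'   `n_sources`, sorted by decreasing score.
#' @examples
#' pt <- data.frame(mirna = "m", gene = c("a", "b", "a"),
#'                  source = c("s1", "s1", "s2"), score = c(9, 5, 7))
#' aggregate_targets(pt, "m")  # a: 2 + 1 = 3 points, b: 1 point
#' @export
aggregate_targets <- function(predictions, mirna) {
  need <- c("mirna", "gene", "source", "score")
  if (length(setdiff(need, names(predictions))))
    stop("predictions need columns mirna, gene, source, score")
  tab <- predictions[predictions$mirna == mirna, , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(mirna = character(0), gene = character(0),
                      score = numeric(0), n_sources = integer(0)))
  pts <- lapply(split(tab, tab$source), function(src) {
    # ties share the average rank, as rank() does by default
    rk <- rank(-src$score)
    data.frame(gene = src$gene, points = nrow(src) - rk + 1,
               stringsAsFactors = FALSE)
  })
  all_pts <- do.call(rbind, pts)
  score <- tapply(all_pts$points, all_pts$gene, sum)
  nsrc <- tapply(tab$source, tab$gene, function(x) length(unique(x)))
  genes <- names(score)
  out <- data.frame(mirna = mirna, gene = genes,
                    score = as.numeric(score),
                    n_sources = as.integer(nsrc[genes]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$score, out$gene), , drop = FALSE]
}

#' Select candidate miRNA targets from inhibition experiments
#'
#' Applies the study's filtering rules: keep a gene when (i) its aggregate
#' prediction score is strictly above `score_min` (a score of exactly
#' `score_min` is removed), (ii) it is significantly upregulated
#' (`adj_p < alpha`, `log2fc > 0`) at day 0 or day 1 of the inhibition
#' experiment, and (iii) it is not negatively changing in the chondrogenesis
#' time-series table, operationalized as log2FC >= 0 at `cut_timepoint`.
#' Genes missing from the time-series table are excluded with a message.
#'
#' @param aggregated Result of [aggregate_targets()].
#' @param inhibition_de Data frame of inhibition DE results with columns
#'   `id`, `day` (0 or 1), `log2fc`, `adj_p`.
#' @param timecourse_de DE table over the five chondrogenesis timepoints.
#' @param score_min Aggregate-score threshold; default 50 ("50 or below"
#'   removed).
#' @param alpha Adjusted-p threshold for upregulation, default 0.05.
#' @param cut_timepoint Timepoint at which negative change excludes a gene;
#'   default `"D14"`.
#' @return Character vector of selected gene ids.
#' @export
select_candidates <- function(aggregated, inhibition_de, timecourse_de,
                              score_min = 50, alpha = 0.05,
                              cut_timepoint = "D14") {
  stopifnot(score_min >= 0, alpha > 0, alpha < 1)
  scored <- aggregated[aggregated$score > score_min, , drop = FALSE]
  if (!nrow(scored)) return(character(0))
  up <- inhibition_de[inhibition_de$day %in% c(0, 1) &
                        inhibition_de$adj_p < alpha &
                        inhibition_de$log2fc > 0, , drop = FALSE]
  tc <- timecourse_de[timecourse_de$timepoint == cut_timepoint, , drop = FALSE]
  keep <- character(0)
  for (g in sort(unique(scored$gene))) {
    if (!g %in% up$id) next
    if (!g %in% tc$id) {
      message("gene ", g, " absent from time-series table; excluded")
      next
    }
    if (tc$log2fc[match(g, tc$id)] < 0) next
    keep <- c(keep, g)
  }
  keep
}

#' Build the 2x2 overlap contingency table
#'
#' Cross-classifies genes by differential expression in two experiments:
#' `a` = DE in both, `b` = DE in the first only, `c` = DE in the second
#' only, `d` = DE in neither.
#'
#' @param de_a,de_b Character vectors of DE gene ids from the two
#'   experiments.
#' @param universe Character vector of all tested genes.
#' @return Integer vector `c(a, b, c, d)`.
#' @export
overlap_table <- function(de_a, de_b, universe) {
  de_a <- unique(de_a); de_b <- unique(de_b); universe <- unique(universe)
  if (!all(c(de_a, de_b) %in% universe))
    stop("DE sets must be subsets of the universe")
  a <- length(intersect(de_a, de_b))
  b <- length(setdiff(de_a, de_b))
  cc <- length(setdiff(de_b, de_a))
  d <- length(universe) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Chi-square test of observed versus expected overlap
#'
#' For a 2x2 table the expected count of each cell is
#' row total x column total / grand total, and the statistic is the sum of
#' (observed - expected)^2 / expected over the four cells, referred to a
#' chi-square distribution with 1 degree of freedom. No continuity
#' correction is applied.
#'
#' @param counts Numeric vector `c(a, b, c, d)` of non-negative cell counts
#'   (both / first only / second only / neither).
#' @return List with `chi2`, `p`, `expected` (the four expected counts) and
#'   `df = 1`.
#' @examples
#' chi_square_overlap(c(10, 20, 30, 40))$chi2  # ~0.7937
#' @export
chi_square_overlap <- function(counts) {
  if (length(counts) != 4 || any(counts < 0))
    stop("counts must be 4 non-negative numbers")
  m <- matrix(as.numeric(counts), 2, 2, byrow = TRUE)
  gt <- sum(m)
  if (gt <= 0) stop("grand total must be positive")
  expected <- outer(rowSums(m), colSums(m)) / gt
  if (any(expected == 0)) {
    cell <- which(expected == 0)[1]
    stop("expected count is zero in cell ", cell)
  }
  chi2 <- sum((m - expected)^2 / expected)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, expected = as.numeric(t(expected)), df = 1L)
}
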