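#' Timepoint-wise significance filtration
#'
#' Splits a differential-expression table into per-timepoint sets of
#' entities with adjusted p-value strictly below `alpha`.
#'
#' @param de Data frame with columns `id`, `timepoint`, `log2fc`, `adj_p`
#'   (a DE table as produced by [generate_timecourse()] or read with
#'   [read_de_table()]).
#' @param alpha Significance threshold in (0, 1); inclusion uses
#'   `adj_p < alpha` (strict).
#' @return Named list, one character vector of entity ids per timepoint.
#' @examples
#' de <- data.frame(id = "g1", timepoint = "D1", log2fc = 2, adj_p = 0.049)
#' filter_significant(de, 0.05)
#' @export
filter_significant <- function(de, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  .check_de(de)
  if (nrow(de) == 0) return(stats::setNames(list(), character(0)))
  keep <- de[de$adj_p < alpha, , drop = FALSE]
  tps <- unique(de$timepoint)
  out <- lapply(tps, function(tp) unique(keep$id[keep$timepoint == tp]))
  stats::setNames(out, tps)
}

.check_de <- function(de) {
  need <- c("id", "timepoint", "log2fc", "adj_p")
  miss <- setdiff(need, names(de))
  if (length(miss)) stop("DE table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(de) && (any(de$adj_p < 0) || any(de$adj_p > 1)))
    stop("adj_p outside [0, 1]")
  if (anyDuplicated(de[c("id", "timepoint")]))
    stop("duplicated (id, timepoint) rows")
  invisible(de)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each pathway gene set for over-representation in a selected entity
#' set against a fixed background. The p-value is the hypergeometric upper
#' tail P(X >= k) with population `N = |background|`, successes
#' `K = |pathway n background|` and draws `n = |selected|`. Adjusted
#' p-values are Benjamini-Hochberg across the pathways tested in this call
#' (one timepoint's family).
#'
#' @param selected Character vector of selected entity ids (must be a subset
#'   of `background`).
#' @param pathways Named list of character vectors (gene sets), e.g. from
#'   [read_gmt()].
#' @param background Character vector: the background universe (for the
#'   original study, the microarray probe ids).
#' @param timepoint Optional label copied into the result.
#' @return Data frame with columns `pathway`, `timepoint`, `k`, `K`, `n`,
#'   `N`, `p`, `adj_p`. Pathways empty after intersection with the
#'   background are skipped with a message.
#' @export
ora <- function(selected, pathways, background, timepoint = NA_character_) {
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background))
    stop("selected set is not a subset of the background")
  N <- length(background)
  n <- length(selected)
  rows <- lapply(names(pathways), function(pw) {
    genes <- intersect(unique(pathways[[pw]]), background)
    K <- length(genes)
    if (K == 0) {
      message("pathway '", pw, "' empty after background intersection; skipped")
      return(NULL)
    }
    k <- length(intersect(genes, selected))
    # upper tail P(X >= k); phyper's upper tail is P(X > k-1)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, timepoint = timepoint, k = k, K = K, n = n,
               N = N, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(pathway = character(0), timepoint = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), adj_p = numeric(0)))
  res <- do.call(rbind, rows)
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Run ORA at every timepoint of a DE table
#'
#' Convenience wrapper: filters the DE table at `alpha`, then runs [ora()]
#' once per timepoint with BH correction within each timepoint's family.
#'
#' @inheritParams filter_significant
#' @inheritParams ora
#' @return One combined data frame of [ora()] results.
#' @export
ora_timecourse <- function(de, pathways, background, alpha = 0.05) {
  sets <- filter_significant(de, alpha)
  out <- lapply(names(sets), function(tp)
    ora(intersect(sets[[tp]], background), pathways, background,
        timepoint = tp))
  do.call(rbind, out)
}

#' Pathways recurrently enriched across timepoints
#'
#' @param results An [ora()]/[ora_timecourse()] result data frame spanning
#'   several timepoints.
#' @param alpha Adjusted-p significance threshold (strict `<`).
#' @param min_timepoints Minimum number of distinct timepoints at which a
#'   pathway must be significant to be kept (the study used 3 of 5).
#' @return Character vector of pathway ids.
#' @export
recurrent_pathways <- function(results, alpha = 0.05, min_timepoints = 3) {
  stopifnot(min_timepoints >= 1)
  sig <- results[results$adj_p < alpha, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  counts <- tapply(sig$timepoint, sig$pathway,
                   function(x) length(unique(x)))
  names(counts)[counts >= min_timepoints]
}

# profile matrix (entities x timepoints, in canonical order) from a DE table
.profile_matrix <- function(de, timepoints = c("D1", "D3", "D6", "D10", "D14")) {
  ids <- unique(de$id)
  m <- matrix(NA_real_, length(ids), length(timepoints),
              dimnames = list(ids, timepoints))
  keep <- de$timepoint %in% timepoints
  m[cbind(match(de$id[keep], ids), match(de$timepoint[keep], timepoints))] <-
    de$log2fc[keep]
  m
}

#' Screen miRNA-mRNA interactions by anticorrelation and database vote
#'
#' Candidate pairs are all (miRNA, gene) pairs appearing in at least one
#' prediction source. A pair passes when the Pearson correlation of the two
#' log2 fold-change profiles across the five timepoints is strictly below
#' `r_max` and the pair is predicted in at least `min_votes` distinct
#' sources. A source listing a pair twice still contributes one vote.
#'
#' @param mirna_de,mrna_de DE tables (columns `id`, `timepoint`, `log2fc`,
#'   `adj_p`) for miRNAs and mRNAs.
#' @param predictions Data frame of predicted pairs with columns `mirna`,
#'   `gene`, `source` (and optionally `score`), e.g. from
#'   [generate_prediction_tables()] or [read_predictions()].
#' @param r_max Correlation threshold; default -0.75 (pairs must be more
#'   anticorrelated than this).
#' @param min_votes Minimum number of distinct predicting sources; default 2
#'   of 3.
#' @param timepoints Canonical timepoint order for the profiles.
#' @return Data frame of interaction candidates: `mirna`, `gene`,
#'   `pearson_r`, `votes`, `passed`, `reason` (NA when evaluable). Pairs
#'   with incomplete profiles are kept with `passed = FALSE` and a reason;
#'   zero-variance profiles yield `pearson_r = NA` and fail.
#' @export
screen_interactions <- function(mirna_de, mrna_de, predictions,
                                r_max = -0.75, min_votes = 2,
                                timepoints = c("D1", "D3", "D6", "D10",
                                               "D14")) {
  stopifnot(r_max >= -1, r_max <= 1, min_votes %in% 1:3)
  .check_de(mirna_de); .check_de(mrna_de)
  need <- c("mirna", "gene", "source")
  if (length(setdiff(need, names(predictions))))
    stop("predictions need columns mirna, gene, source")
  pairs <- unique(predictions[c("mirna", "gene")])
  pairs <- pairs[order(pairs$mirna, pairs$gene), , drop = FALSE]
  votes <- tapply(predictions$source,
                  paste(predictions$mirna, predictions$gene, sep = "\r"),
                  function(x) length(unique(x)))
  mp <- .profile_matrix(mirna_de, timepoints)
  gp <- .profile_matrix(mrna_de, timepoints)
  n <- nrow(pairs)
  r <- rep(NA_real_, n); v <- integer(n)
  passed <- logical(n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    mir <- pairs$mirna[i]; g <- pairs$gene[i]
    v[i] <- votes[[paste(mir, g, sep = "\r")]]
    x <- if (mir %in% rownames(mp)) mp[mir, ] else rep(NA_real_, 5)
    y <- if (g %in% rownames(gp)) gp[g, ] else rep(NA_real_, 5)
    if (anyNA(x) || anyNA(y)) {
      reason[i] <- "incomplete profile"
      message("pair ", mir, " / ", g, " skipped: incomplete profile")
      next
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      reason[i] <- "zero-variance profile"
      next
    }
    r[i] <- stats::cor(x, y)
    passed[i] <- (r[i] < r_max) && (v[i] >= min_votes)
  }
  data.frame(mirna = pairs$mirna, gene = pairs$gene, pearson_r = r,
             votes = v, passed = passed, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scale log2 fold-change profiles for magnitude-of-change ranking
#'
#' Standardizes each entity's five-timepoint log2FC trajectory to mean 0 and
#' (sample, n-1 denominator) standard deviation 1, and flags entities whose
#' scaled trajectory reaches at least +1 at some timepoint -- the rule used
#' to highlight positively changing regulators. Constant profiles scale to
#' all zeros with a warning and are never highlighted.
#'
#' @inheritParams filter_significant
#' @param timepoints Canonical timepoint order.
#' @return Data frame with `id`, one `D*` column per timepoint (scaled
#'   values) and `highlighted`.
#' @examples
#' de <- data.frame(id = "g", timepoint = c("D1","D3","D6","D10","D14"),
#'                  log2fc = c(0, 0, 0, 0, 5), adj_p = 0.01)
#' scale_profiles(de)$highlighted  # TRUE: max scaled value 4/sqrt(5) >= 1
#' @export
scale_profiles <- function(de, timepoints = c("D1", "D3", "D6", "D10",
                                              "D14")) {
  .check_de(de)
  m <- .profile_matrix(de, timepoints)
  ok <- rowSums(is.finite(m)) >= 2
  if (any(!ok)) stop("entities with fewer than 2 finite timepoints: ",
                     paste(rownames(m)[!ok], collapse = ", "))
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    warning("constant profile(s) scaled to zero: ",
            paste(rownames(m)[sds == 0], collapse = ", "))
  sc <- t(apply(m, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  out <- data.frame(id = rownames(m), sc, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$highlighted <- apply(sc, 1, max) >= 1
  out
}
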