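# run expr with a private RNG stream so generators never disturb (or depend
# on) the caller's global RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Define the ground truth of a synthetic study
#'
#' Collects everything the generators need to plant recoverable structure:
#' the true miRNA-target interactions, pathway memberships with the
#' timepoints at which each pathway is enriched, the generating kinetic
#' parameters, the noise level and the master seed.
#'
#' @param true_interactions Data frame with columns `mirna`, `gene`.
#' @param pathway_memberships Named list: pathway id -> character vector of
#'   member genes.
#' @param enriched_timepoints Named list: pathway id -> character vector of
#'   timepoints (subset of D1/D3/D6/D10/D14) at which the pathway is
#'   enriched.
#' @param kinetic_params Named positive numeric vector; defaults to
#'   [default_params()] for the enhanced model.
#' @param noise_sd Non-negative noise level: additive Gaussian on log2FC
#'   values and lognormal sdlog on percent-scale qPCR values.
#' @param seed Integer master seed.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(true_interactions = NULL,
                         pathway_memberships = list(),
                         enriched_timepoints = list(),
                         kinetic_params = default_params("enhanced"),
                         noise_sd = 0.1, seed = 1L) {
  if (is.null(true_interactions))
    true_interactions <- data.frame(mirna = character(0),
                                    gene = character(0))
  stopifnot(noise_sd >= 0, all(kinetic_params >= 0))
  if (length(setdiff(names(enriched_timepoints),
                     names(pathway_memberships))))
    stop("enriched pathway without membership definition")
  structure(list(true_interactions = true_interactions,
                 pathway_memberships = pathway_memberships,
                 enriched_timepoints = enriched_timepoints,
                 kinetic_params = kinetic_params,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

.tp_levels <- c("D1", "D3", "D6", "D10", "D14")

#' Generate synthetic longitudinal DE tables with planted interactions
#'
#' Emulates the five-timepoint (D1/D3/D6/D10/D14 versus D0) differential
#' expression tables of a chondrogenesis time course. Planted miRNA-target
#' pairs receive exactly opposite log2FC profiles before noise (Pearson
#' correlation -1); all other profiles are drawn i.i.d. standard normal per
#' timepoint, giving a calibrated null for the correlation filter.
#' Member genes of pathways planted as enriched get adjusted p-values forced
#' below 0.05 at the designated timepoints; all other adjusted p-values are
#' uniform on (0, 1).
#'
#' @param truth A [ground_truth()].
#' @param n_genes,n_mirnas Numbers of genes and miRNAs to simulate
#'   (entities named `gene_0001` ... and `mir_001` ...; truth interactions
#'   must reference such ids within range).
#' @return List with data frames `mrna_de` and `mirna_de` (columns `id`,
#'   `timepoint`, `log2fc`, `adj_p`) and the `truth` object.
#' @export
generate_timecourse <- function(truth, n_genes = 200, n_mirnas = 20) {
  stopifnot(inherits(truth, "ground_truth"), n_genes >= 1, n_mirnas >= 1)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  mirs <- sprintf("mir_%03d", seq_len(n_mirnas))
  ti <- truth$true_interactions
  if (nrow(ti)) {
    bad <- c(setdiff(ti$mirna, mirs), setdiff(ti$gene, genes))
    if (length(bad)) stop("interaction references missing entity: ",
                          paste(bad, collapse = ", "))
  }
  for (pw in names(truth$pathway_memberships)) {
    bad <- setdiff(truth$pathway_memberships[[pw]], genes)
    if (length(bad)) stop("pathway ", pw, " references missing gene(s)")
  }
  .with_seed(truth$seed, {
    k <- length(.tp_levels)
    mprof <- matrix(stats::rnorm(n_mirnas * k), n_mirnas, k,
                    dimnames = list(mirs, .tp_levels))
    gprof <- matrix(stats::rnorm(n_genes * k), n_genes, k,
                    dimnames = list(genes, .tp_levels))
    if (nrow(ti)) {
      # a gene targeted by several planted miRNAs mirrors the first listed
      first <- ti[!duplicated(ti$gene), , drop = FALSE]
      gprof[first$gene, ] <- -mprof[first$mirna, , drop = FALSE]
    }
    if (truth$noise_sd > 0) {
      mprof <- mprof + stats::rnorm(length(mprof), sd = truth$noise_sd)
      gprof <- gprof + stats::rnorm(length(gprof), sd = truth$noise_sd)
    }
    gp <- matrix(stats::runif(n_genes * k), n_genes, k,
                 dimnames = list(genes, .tp_levels))
    for (pw in names(truth$enriched_timepoints)) {
      members <- truth$pathway_memberships[[pw]]
      tps <- truth$enriched_timepoints[[pw]]
      gp[members, tps] <- matrix(stats::runif(length(members) * length(tps),
                                              0, 0.0499),
                                 length(members), length(tps))
    }
    mp <- matrix(stats::runif(n_mirnas * k), n_mirnas, k,
                 dimnames = list(mirs, .tp_levels))
    mk_table <- function(prof, pmat) {
      data.frame(id = rep(rownames(prof), k),
                 timepoint = rep(.tp_levels, each = nrow(prof)),
                 log2fc = as.vector(prof), adj_p = as.vector(pmat),
                 stringsAsFactors = FALSE)
    }
    list(mrna_de = mk_table(gprof, gp), mirna_de = mk_table(mprof, mp),
         truth = truth)
  })
}

#' Generate three-source target-prediction tables with planted pairs
#'
#' Every true interaction is listed in at least two of the three sources
#' with a high score (uniform on 80-100); decoy pairs are random non-true
#' pairs listed in a single source (or, with probability
#' `decoy_two_source_prob`, in two) with scores uniform on 1-80.
#'
#' @param truth A [ground_truth()].
#' @param n_decoys Number of decoy pairs (>= 0).
#' @param seed Seed for this generator (defaults to `truth$seed + 1`).
#' @param entities Optional list with `genes` and `mirnas` character vectors
#'   from which decoys are drawn; defaults to the ids appearing in the truth
#'   plus generic decoy ids.
#' @param sources Source names; default TargetScan/miRDB/miRTarBase-like
#'   labels `source_A/B/C`.
#' @param decoy_two_source_prob Probability a decoy reaches two sources.
#' @return Data frame with columns `mirna`, `gene`, `source`, `score`.
#' @export
generate_prediction_tables <- function(truth, n_decoys = 50,
                                       seed = truth$seed + 1L,
                                       entities = NULL,
                                       sources = c("source_A", "source_B",
                                                   "source_C"),
                                       decoy_two_source_prob = 0) {
  stopifnot(inherits(truth, "ground_truth"), n_decoys >= 0,
            length(sources) == 3)
  ti <- truth$true_interactions
  if (is.null(entities))
    entities <- list(genes = unique(c(ti$gene,
                                      sprintf("decoygene_%04d", 1:200))),
                     mirnas = unique(c(ti$mirna,
                                       sprintf("decoymir_%03d", 1:20))))
  .with_seed(seed, {
    rows <- list()
    if (nrow(ti)) {
      for (i in seq_len(nrow(ti))) {
        nsrc <- sample(2:3, 1)
        for (s in sample(sources, nsrc))
          rows[[length(rows) + 1L]] <-
            data.frame(mirna = ti$mirna[i], gene = ti$gene[i], source = s,
                       score = stats::runif(1, 80, 100),
                       stringsAsFactors = FALSE)
      }
    }
    made <- 0L
    truekey <- paste(ti$mirna, ti$gene)
    while (made < n_decoys) {
      mir <- sample(entities$mirnas, 1)
      g <- sample(entities$genes, 1)
      if (paste(mir, g) %in% truekey) next
      nsrc <- if (stats::runif(1) < decoy_two_source_prob) 2L else 1L
      for (s in sample(sources, nsrc))
        rows[[length(rows) + 1L]] <-
          data.frame(mirna = mir, gene = g, source = s,
                     score = stats::runif(1, 1, 80),
                     stringsAsFactors = FALSE)
      made <- made + 1L
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(mirna = character(0),
                                        gene = character(0),
                                        source = character(0),
                                        score = numeric(0))
    out <- unique(out)
    rownames(out) <- NULL
    out
  })
}

.condition_model <- function(model, condition, eps = 0.925, t_off = NULL) {
  args <- list(model = model, eps = eps)
  if (!is.null(t_off)) args$t_off <- t_off
  switch(condition,
         "control" = model,
         "inh-199a" = do.call(apply_inhibition,
                              c(args, list(which = "miR-199a-5p"))),
         "inh-199b" = do.call(apply_inhibition,
                              c(args, list(which = "miR-199b-5p"))),
         "inh-199a+b" = do.call(apply_inhibition,
                                c(args, list(which = "both"))),
         stop("unknown condition: ", condition))
}

#' Generate a synthetic qPCR inhibition experiment from the kinetic model
#'
#' Simulates the control trajectory and each requested inhibition condition
#' with the model, samples the analytes at the observation days, applies
#' multiplicative lognormal noise per replicate, and rescales so that the
#' control mean is exactly 100% per analyte and day (values are percent of
#' non-targeting control). Day-0 samples precede the inhibition event, so
#' control and inhibition coincide there apart from noise. A GAG table
#' normalized to the day-7 control level is generated alongside.
#'
#' @param model A `kinetic_model` without events (the control model).
#' @param truth A [ground_truth()] supplying `noise_sd` and the seed.
#' @param conditions Inhibition condition labels among `"inh-199a"`,
#'   `"inh-199b"`, `"inh-199a+b"`.
#' @param days Observation days within the model horizon; default 0/1/3/7.
#' @param replicates Biological replicates per condition/analyte/day.
#' @param analytes Species to measure; defaults to the chondrogenic
#'   biomarkers and the miR-199 targets present in the model.
#' @param eps Knockdown fraction for the simulated events.
#' @return List with `qpcr` (columns `condition`, `analyte`, `day`,
#'   `replicate`, `pct_control`), `gag` (columns `condition`, `day`,
#'   `pct_control_d7`), and `calibration` (the control trajectory at the
#'   observation days in model units -- the anchor M for
#'   [qpcr_to_observations()]).
#' @export
generate_qpcr_experiment <- function(model, truth,
                                     conditions = c("inh-199a", "inh-199b"),
                                     days = c(0, 1, 3, 7), replicates = 6,
                                     analytes = NULL, eps = 0.925) {
  stopifnot(inherits(model, "kinetic_model"), inherits(truth, "ground_truth"),
            replicates >= 1)
  if (max(days) > model$horizon) stop("days beyond simulation horizon")
  if (is.null(analytes))
    analytes <- intersect(c("ACAN_mRNA", "COL2A1_mRNA", "SOX9_mRNA", "FZD6",
                            "ITGA3", "CAV1"), model$species$name)
  bad <- setdiff(analytes, model$species$name)
  if (length(bad)) stop("unknown analyte(s): ", paste(bad, collapse = ", "))
  traj <- list(control = simulate_model(model, times = days,
                                        condition = "control"))
  for (cond in conditions)
    traj[[cond]] <- simulate_model(.condition_model(model, cond, eps = eps),
                                   times = days, condition = cond)
  gag_ok <- "GAG" %in% model$species$name
  .with_seed(truth$seed + 2L, {
    qrows <- list()
    for (an in analytes) {
      for (d in seq_along(days)) {
        noisy <- lapply(names(traj), function(cond) {
          mu <- traj[[cond]]$states[d, an]
          mu * stats::rlnorm(replicates, 0, truth$noise_sd)
        })
        names(noisy) <- names(traj)
        scale <- mean(noisy$control)
        for (cond in names(traj))
          qrows[[length(qrows) + 1L]] <-
            data.frame(condition = cond, analyte = an, day = days[d],
                       replicate = seq_len(replicates),
                       pct_control = 100 * noisy[[cond]] / scale,
                       stringsAsFactors = FALSE)
      }
    }
    qpcr <- do.call(rbind, qrows)
    gag <- NULL
    if (gag_ok) {
      g7 <- simulate_model(model, times = c(0, 7))$states[2, "GAG"]
      grows <- list()
      for (cond in names(traj)) {
        v <- traj[[cond]]$states[, "GAG"] *
          stats::rlnorm(length(days), 0, truth$noise_sd)
        grows[[length(grows) + 1L]] <-
          data.frame(condition = cond, day = days,
                     pct_control_d7 = 100 * v / g7, stringsAsFactors = FALSE)
      }
      gag <- do.call(rbind, grows)
    }
    calibration <- data.frame(analyte = rep(analytes, each = length(days)),
                              day = rep(days, length(analytes)),
                              value = as.vector(vapply(analytes, function(an)
                                traj$control$states[, an],
                                numeric(length(days)))),
                              stringsAsFactors = FALSE)
    rownames(qpcr) <- NULL
    list(qpcr = qpcr, gag = gag, calibration = calibration)
  })
}

#' Generate a complete synthetic study
#'
#' One call producing every input of the analysis pipeline with known
#' ground truth: longitudinal DE tables with planted anticorrelated pairs
#' and enriched pathways, three-source prediction tables, and a
#' model-derived qPCR inhibition experiment.
#'
#' @param n_genes,n_mirnas Entity counts for the DE tables.
#' @param n_true Number of planted miRNA-target interactions.
#' @param n_decoys Decoy pairs in the prediction tables.
#' @param noise_sd Noise level (see [ground_truth()]).
#' @param seed Master seed.
#' @param variant Kinetic model variant backing the qPCR experiment.
#' @param n_pathways,pathway_size Planted pathway structure: each pathway is
#'   enriched at three of the five timepoints.
#' @return List with `truth`, `mrna_de`, `mirna_de`, `predictions`, `qpcr`,
#'   `gag`, `calibration`, `model`, and `pathways`.
#' @export
generate_synthetic_study <- function(n_genes = 200, n_mirnas = 20,
                                     n_true = 10, n_decoys = 100,
                                     noise_sd = 0.1, seed = 1L,
                                     variant = "enhanced",
                                     n_pathways = 4, pathway_size = 15) {
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  mirs <- sprintf("mir_%03d", seq_len(n_mirnas))
  n_true <- min(n_true, n_genes, n_mirnas)
  ti <- data.frame(mirna = mirs[seq_len(n_true)],
                   gene = genes[seq_len(n_true)], stringsAsFactors = FALSE)
  pw <- list(); en <- list()
  if (n_pathways > 0) {
    for (j in seq_len(n_pathways)) {
      lo <- (j - 1) * pathway_size + 1
      members <- genes[seq(lo, min(lo + pathway_size - 1, n_genes))]
      pw[[sprintf("pathway_%02d", j)]] <- members
      en[[sprintf("pathway_%02d", j)]] <-
        .tp_levels[seq_len(3) + (j %% 3)]
    }
  }
  truth <- ground_truth(true_interactions = ti, pathway_memberships = pw,
                        enriched_timepoints = en,
                        kinetic_params = default_params(variant),
                        noise_sd = noise_sd, seed = seed)
  tc <- generate_timecourse(truth, n_genes = n_genes, n_mirnas = n_mirnas)
  preds <- generate_prediction_tables(
    truth, n_decoys = n_decoys,
    entities = list(genes = genes, mirnas = mirs))
  model <- build_model(variant, params = truth$kinetic_params)
  qp <- generate_qpcr_experiment(model, truth)
  list(truth = truth, mrna_de = tc$mrna_de, mirna_de = tc$mirna_de,
       predictions = preds, qpcr = qp$qpcr, gag = qp$gag,
       calibration = qp$calibration, model = model, pathways = pw)
}
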