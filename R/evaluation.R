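#' Criterion closures for calibration-set search
#'
#' Wrap [cd_criterion()] or [crit_kin()] into a function of the candidate
#' subset, as consumed by [exchange_optimize()] and
#' [brute_force_optimize()]. The mixed-model individual set is rebuilt for
#' every evaluated subset as the union of the subset and the target set, in
#' stable input order (an individual may belong to both, as when the
#' calibration set is drawn from the predicted population itself).
#'
#' @param K Kinship matrix covering all candidates and targets.
#' @param targets Target spec, as in [cd_criterion()] (ids for
#'   `cdpop`/`cdallnam`, a named list of families or an id -> family vector
#'   for `cdpop_mean`).
#' @param kind Criterion kind for [cd_criterion()].
#' @param lambda Variance ratio used inside the criterion (default 1, the
#'   no-phenotypes-yet convention).
#' @return A function: character vector of ids -> scalar criterion value.
#' @export
cd_criterion_fn <- function(K, targets, kind = "cdpop", lambda = 1) {
  target_ids <- if (is.list(targets)) unlist(targets, use.names = FALSE)
                else if (!is.null(names(targets))) names(targets)
                else as.character(targets)
  force(kind); force(lambda)
  function(ids) {
    model <- unique(c(as.character(ids), target_ids))
    cd_criterion(K[model, model, drop = FALSE], ids, targets,
                 kind = kind, lambda = lambda)$aggregate
  }
}

#' @rdname cd_criterion_fn
#' @export
crit_kin_fn <- function(K, targets) {
  target_ids <- if (is.list(targets)) unlist(targets, use.names = FALSE)
                else if (!is.null(names(targets))) names(targets)
                else as.character(targets)
  function(ids) crit_kin(K, ids, target_ids)
}

#' Observed prediction accuracy
#'
#' The correlation between predictions and phenotypes divided by the square
#' root of the heritability of the predicted set, which rescales the
#' phenotype-level correlation to the genetic-value level. The sign of the
#' correlation is preserved (a negative accuracy records a genuinely
#' misleading prediction; squaring it first would hide that). Values may
#' exceed 1 through sampling noise in small families and are reported as-is.
#'
#' @param predictions Numeric vector of predicted genetic values.
#' @param phenotypes Numeric vector of observed phenotypes, same length.
#' @param h2 Heritability of the predicted set, in (0, 1].
#' @return The signed accuracy, a scalar.
#' @export
observed_accuracy <- function(predictions, phenotypes, h2) {
  if (length(predictions) != length(phenotypes))
    stop("predictions and phenotypes must have equal length")
  if (length(predictions) < 3) stop("need at least 3 prediction pairs")
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  if (stats::sd(predictions) == 0 || stats::sd(phenotypes) == 0)
    stop("zero variance in predictions or phenotypes")
  stats::cor(predictions, phenotypes) / sqrt(h2)
}

#' Configure a prediction or optimization scenario
#'
#' Scenarios follow the standard structured-population study designs:
#' \describe{
#'   \item{S1}{each NAM family predicted by each other single family.}
#'   \item{S2}{each family predicted by all other families
#'     (leave-one-cross-out).}
#'   \item{S3}{each family (and all families pooled) predicted by the
#'     diverse panel.}
#'   \item{OT1}{one family predicted; calibration sets of several sizes
#'     sampled from the other families by each sampling strategy.}
#'   \item{OT2}{as OT1 with the panel as the sampling pool.}
#'   \item{OT3}{all families predicted jointly; calibration sampled from
#'     the families themselves (includes the stratified baselines).}
#'   \item{OT4}{as OT3 with the panel as the pool.}
#' }
#' The default calibration sizes are the standard ones per scenario
#' (OT1: 10/50/150/300/500; OT2 and OT4: 10/25/50/100/200;
#' OT3: 50/150/300/500); pass smaller sizes for small datasets. In the
#' S-scenarios phenotypes exist, so `lambda` defaults to the calibration
#' set's heritability (`from_h2_table`); in the OT-scenarios phenotypes are
#' assumed unavailable at design time and `lambda` defaults to 1 (an
#' intermediate heritability of 0.5).
#'
#' @param scenario One of `"S1"`, `"S2"`, `"S3"`, `"OT1"`, `"OT2"`,
#'   `"OT3"`, `"OT4"`.
#' @param calibration_sizes Sizes of the sampled calibration sets
#'   (OT-scenarios only).
#' @param n_random_reps Replicates per sampler and size (default 20).
#' @param lambda_policy `"from_h2_table"`, `"fixed_1"` or `"reml"`.
#' @param seed Integer seed governing all sampling and optimization.
#' @param samplers Subset of the scenario's sampling strategies to run.
#' @param optimizer Named list of [optimizer_config()] overrides
#'   (`max_iterations`, `patience`, `restarts`).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("S1", "S2", "S3", "OT1", "OT2", "OT3", "OT4"),
                            calibration_sizes = NULL, n_random_reps = 20,
                            lambda_policy = NULL, seed = 1,
                            samplers = NULL, optimizer = list()) {
  scenario <- match.arg(scenario)
  is_ot <- grepl("^OT", scenario)
  if (is.null(lambda_policy))
    lambda_policy <- if (is_ot) "fixed_1" else "from_h2_table"
  lambda_policy <- match.arg(lambda_policy, c("from_h2_table", "fixed_1", "reml"))
  if (is.null(calibration_sizes) && is_ot)
    calibration_sizes <- switch(scenario,
                                OT1 = c(10, 50, 150, 300, 500),
                                OT2 = c(10, 25, 50, 100, 200),
                                OT3 = c(50, 150, 300, 500),
                                OT4 = c(10, 25, 50, 100, 200))
  default_samplers <- switch(scenario,
    OT1 = c("cdpop", "crit_kin", "random"),
    OT2 = c("cdpop", "crit_kin", "random"),
    OT3 = c("cdpop_mean", "cdallnam", "crit_kin", "random",
            "stratified_equal", "stratified_size"),
    OT4 = c("cdpop_mean", "cdallnam", "crit_kin", "random"),
    NULL)
  if (is.null(samplers)) samplers <- default_samplers
  structure(list(scenario = scenario, calibration_sizes = calibration_sizes,
                 n_random_reps = n_random_reps, lambda_policy = lambda_policy,
                 seed = as.integer(seed), samplers = samplers,
                 optimizer = optimizer),
            class = "scenario_config")
}

#' Bundle a dataset for scenario evaluation
#'
#' @param genotypes A [genotype_matrix()] with family labels covering the
#'   structured families; panel individuals may carry their own label(s).
#' @param phenotypes Named numeric vector of adjusted means (ids matching
#'   the genotypes). Optional for pure design (OT criterion) work.
#' @param h2 Named numeric vector of per-family heritabilities; optional
#'   entries `"pooled"` (multi-family calibration sets) and `"panel"` (the
#'   panel's heritability).
#' @param panel Character vector of individual ids forming the diverse
#'   panel pool (used by S3/OT2/OT4); these ids are excluded from the NAM
#'   family set.
#' @param kinship Optional precomputed kinship; default VanRaden on the
#'   full (imputed) genotype set.
#' @return A `gs_dataset` list.
#' @export
gs_dataset <- function(genotypes, phenotypes = NULL, h2 = NULL, panel = NULL,
                       kinship = NULL) {
  if (is.null(genotypes$families)) stop("genotypes must carry family labels")
  if (is.null(kinship)) {
    G <- if (anyNA(genotypes$values)) impute_missing(genotypes) else genotypes
    kinship <- vanraden_kinship(G)
  }
  nam_ids <- setdiff(rownames(kinship), panel)
  structure(list(genotypes = genotypes, phenotypes = phenotypes, h2 = h2,
                 panel = panel, kinship = kinship,
                 families = split(nam_ids,
                                  unname(genotypes$families[nam_ids]))),
            class = "gs_dataset")
}

pick_h2 <- function(h2, key, members = NULL, families = NULL) {
  if (!is.null(h2) && key %in% names(h2)) return(unname(h2[key]))
  if (identical(key, "pooled") && !is.null(members) && !is.null(families)) {
    # size-weighted mean of the per-family h2 of the calibration members
    fam_counts <- table(families[members])
    fams <- names(fam_counts)
    if (!is.null(h2) && all(fams %in% names(h2)))
      return(sum(h2[fams] * as.numeric(fam_counts)) / sum(fam_counts))
  }
  stop("no heritability available for '", key, "'; provide it in the h2 table")
}

scenario_lambda <- function(policy, data, cal_ids, h2_key) {
  switch(policy,
         fixed_1 = 1,
         from_h2_table = lambda_from_h2(
           pick_h2(data$h2, h2_key, cal_ids, data$genotypes$families)),
         reml = {
           if (is.null(data$phenotypes)) stop("reml lambda policy needs phenotypes")
           estimate_lambda_reml(data$phenotypes[cal_ids],
                                data$kinship[cal_ids, cal_ids, drop = FALSE])$lambda
         })
}

predict_targets <- function(data, cal_ids, target_ids, lambda) {
  model <- unique(c(cal_ids, target_ids))
  spec <- mixed_model_spec(cal_ids, model, lambda = lambda)
  fit <- solve_gblup(data$phenotypes[cal_ids], data$kinship, spec)
  fit$u_hat[target_ids]
}

scenario_row <- function(scenario, calibration, target, sampler, size, rep,
                         lambda, expected, observed, observed_global = NA_real_) {
  data.frame(scenario = scenario, calibration = calibration, target = target,
             sampler = sampler, size = size, rep = rep, lambda = lambda,
             expected = expected, observed = observed,
             observed_global = observed_global,
             stringsAsFactors = FALSE)
}

#' Run a prediction-reliability or calibration-optimization scenario
#'
#' Executes the configured scenario end-to-end on a dataset: builds the
#' calibration sets (fixed by the scenario for S1-S3; sampled/optimized for
#' OT1-OT4), computes the expected reliability criterion, fits G-BLUP,
#' and measures observed accuracies.
#'
#' @param data A [gs_dataset()] (phenotypes and h2 required for observed
#'   accuracies).
#' @param config A [scenario_config()].
#' @return A data.frame with one row per evaluation: columns `scenario`,
#'   `calibration` (pool or calibrating family), `target` (family or
#'   `"all"`), `sampler`, `size`, `rep`, `lambda`, `expected` (criterion
#'   value), `observed` (within-target accuracy; for multi-family targets
#'   the mean of the within-family accuracies) and `observed_global`
#'   (pooled-target accuracy, OT3/OT4 and the pooled S3 row).
#' @export
run_scenario <- function(data, config) {
  stopifnot(inherits(data, "gs_dataset"), inherits(config, "scenario_config"))
  small <- names(data$families)[vapply(data$families, length, integer(1)) < 3]
  if (length(small)) {
    warning("families too small for within-family contrasts/accuracies skipped: ",
            paste(small, collapse = ", "))
    data$families <- data$families[setdiff(names(data$families), small)]
  }
  switch(config$scenario,
         S1 = run_s1(data, config),
         S2 = run_s2(data, config),
         S3 = run_s3(data, config),
         run_ot(data, config))
}

run_s1 <- function(data, config) {
  fams <- names(data$families)
  rows <- list()
  for (cal_fam in fams) for (tgt_fam in setdiff(fams, cal_fam)) {
    cal <- data$families[[cal_fam]]
    tgt <- data$families[[tgt_fam]]
    lambda <- scenario_lambda(config$lambda_policy, data, cal, cal_fam)
    model <- c(cal, tgt)
    expected <- cd_criterion(data$kinship[model, model], cal, tgt,
                             kind = "cdpop", lambda = lambda)$aggregate
    obs <- observed_accuracy(predict_targets(data, cal, tgt, lambda),
                             data$phenotypes[tgt],
                             pick_h2(data$h2, tgt_fam))
    rows[[length(rows) + 1L]] <-
      scenario_row("S1", cal_fam, tgt_fam, NA_character_, length(cal), 1L,
                   lambda, expected, obs)
  }
  do.call(rbind, rows)
}

run_s2 <- function(data, config) {
  fams <- names(data$families)
  rows <- list()
  for (tgt_fam in fams) {
    tgt <- data$families[[tgt_fam]]
    cal <- unlist(data$families[setdiff(fams, tgt_fam)], use.names = FALSE)
    lambda <- scenario_lambda(config$lambda_policy, data, cal, "pooled")
    model <- c(cal, tgt)
    expected <- cd_criterion(data$kinship[model, model], cal, tgt,
                             kind = "cdpop", lambda = lambda)$aggregate
    obs <- observed_accuracy(predict_targets(data, cal, tgt, lambda),
                             data$phenotypes[tgt],
                             pick_h2(data$h2, tgt_fam))
    rows[[length(rows) + 1L]] <-
      scenario_row("S2", "all_other_families", tgt_fam, NA_character_,
                   length(cal), 1L, lambda, expected, obs)
  }
  do.call(rbind, rows)
}

run_s3 <- function(data, config) {
  if (is.null(data$panel)) stop("scenario S3 needs a panel pool")
  cal <- data$panel
  lambda <- scenario_lambda(config$lambda_policy, data, cal, "panel")
  rows <- list()
  for (tgt_fam in names(data$families)) {
    tgt <- data$families[[tgt_fam]]
    model <- unique(c(cal, tgt))
    expected <- cd_criterion(data$kinship[model, model], cal, tgt,
                             kind = "cdpop", lambda = lambda)$aggregate
    obs <- observed_accuracy(predict_targets(data, cal, tgt, lambda),
                             data$phenotypes[tgt],
                             pick_h2(data$h2, tgt_fam))
    rows[[length(rows) + 1L]] <-
      scenario_row("S3", "panel", tgt_fam, NA_character_, length(cal), 1L,
                   lambda, expected, obs)
  }
  # pooled target set: global reliability forecast and global accuracy
  all_tgt <- unlist(data$families, use.names = FALSE)
  model <- unique(c(cal, all_tgt))
  expected <- cd_criterion(data$kinship[model, model], cal, all_tgt,
                           kind = "cdallnam", lambda = lambda)$aggregate
  preds <- predict_targets(data, cal, all_tgt, lambda)
  obs_global <- observed_accuracy(preds, data$phenotypes[all_tgt],
                                  pick_h2(data$h2, "pooled", all_tgt,
                                          data$genotypes$families))
  rows[[length(rows) + 1L]] <-
    scenario_row("S3", "panel", "all", NA_character_, length(cal), 1L,
                 lambda, expected, NA_real_, obs_global)
  do.call(rbind, rows)
}

ot_pool_and_targets <- function(data, scenario, tgt_fam = NULL) {
  switch(scenario,
         OT1 = list(pool = unlist(data$families[setdiff(names(data$families), tgt_fam)],
                                  use.names = FALSE),
                    targets = data$families[[tgt_fam]]),
         OT2 = list(pool = data$panel, targets = data$families[[tgt_fam]]),
         OT3 = list(pool = unlist(data$families, use.names = FALSE),
                    targets = data$families),
         OT4 = list(pool = data$panel, targets = data$families))
}

ot_design <- function(sampler, pool, size, K, targets, lambda, seed, opt_over, fam_of) {
  target_ids <- if (is.list(targets)) unlist(targets, use.names = FALSE) else targets
  if (sampler %in% c("random", "stratified_equal", "stratified_size"))
    return(sample_baseline(pool, size, sampler, family_of = fam_of, seed = seed))
  crit <- switch(sampler,
                 crit_kin = crit_kin_fn(K, target_ids),
                 cdpop = cd_criterion_fn(K, target_ids, "cdpop", lambda),
                 cdallnam = cd_criterion_fn(K, target_ids, "cdallnam", lambda),
                 cdpop_mean = cd_criterion_fn(K, targets, "cdpop_mean", lambda),
                 stop("unknown sampler: ", sampler))
  cfg <- do.call(optimizer_config,
                 c(list(size = size, seed = seed, restarts = 1), opt_over))
  exchange_optimize(pool, crit, cfg, criterion_name = sampler)
}

run_ot <- function(data, config) {
  scenario <- config$scenario
  per_family <- scenario %in% c("OT1", "OT2")
  tgt_fams <- if (per_family) names(data$families) else NA_character_
  if (scenario %in% c("OT2", "OT4") && is.null(data$panel))
    stop("scenario ", scenario, " needs a panel pool")
  fam_of <- data$genotypes$families
  rows <- list()
  for (tf in tgt_fams) {
    pt <- ot_pool_and_targets(data, scenario, tf)
    target_ids <- if (is.list(pt$targets)) unlist(pt$targets, use.names = FALSE)
                  else pt$targets
    lambda <- if (config$lambda_policy == "fixed_1") 1
              else scenario_lambda(config$lambda_policy, data, pt$pool, "pooled")
    for (size in config$calibration_sizes) {
      if (size > length(pt$pool)) next
      for (rep_i in seq_len(config$n_random_reps)) {
        seed_i <- config$seed + 1000L * rep_i + size
        for (sampler in config$samplers) {
          design <- ot_design(sampler, pt$pool, size, data$kinship, pt$targets,
                              lambda, seed_i, config$optimizer, fam_of)
          cal <- design$selected_ids
          obs <- obs_global <- NA_real_
          if (!is.null(data$phenotypes)) {
            preds <- predict_targets(data, cal, target_ids, lambda)
            if (per_family) {
              obs <- observed_accuracy(preds, data$phenotypes[target_ids],
                                       pick_h2(data$h2, tf))
            } else {
              within <- vapply(names(pt$targets), function(f) {
                ids <- pt$targets[[f]]
                observed_accuracy(preds[ids], data$phenotypes[ids],
                                  pick_h2(data$h2, f))
              }, numeric(1))
              obs <- mean(within)
              obs_global <- observed_accuracy(preds, data$phenotypes[target_ids],
                                              pick_h2(data$h2, "pooled", target_ids,
                                                      fam_of))
            }
          }
          rows[[length(rows) + 1L]] <-
            scenario_row(scenario, if (per_family) "pool" else "all_families",
                         if (per_family) tf else "all", sampler, size, rep_i,
                         lambda, design$criterion_value, obs, obs_global)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize expected vs observed accuracy
#'
#' Per predicted family (and pooled over all rows): Pearson correlation
#' between the expected (criterion) and observed accuracies, and the
#' least-squares regression of observed on expected. Groups with fewer than
#' 3 pairs or zero variance in the expected values are skipped with a
#' warning.
#'
#' @param report A report data.frame from [run_scenario()] with columns
#'   `target`, `expected`, `observed`.
#' @return A data.frame with columns `target`, `n`, `correlation`, `slope`,
#'   `intercept` (the pooled row has `target = "pooled"`).
#' @export
expected_vs_observed_summary <- function(report) {
  report <- report[is.finite(report$expected) & is.finite(report$observed), ]
  groups <- c(split(report, report$target), list(pooled = report))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 3) {
      warning("group '", g, "' skipped: fewer than 3 expected/observed pairs")
      return(NULL)
    }
    if (stats::sd(d$expected) == 0) {
      warning("group '", g, "' skipped: constant expected values")
      return(NULL)
    }
    fit <- stats::lm(observed ~ expected, data = d)
    data.frame(target = g, n = nrow(d),
               correlation = stats::cor(d$expected, d$observed),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
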