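#' Optimizer configuration
#'
#' Stopping and restart controls for [exchange_optimize()]. The exchange
#' search is a stochastic local search, so restarts are cheap insurance
#' against poor local optima; patience stops a restart after a run of
#' consecutive rejected swaps, when the incumbent is very likely locally
#' optimal.
#'
#' @param size Target calibration-set size.
#' @param max_iterations Swap attempts per restart; default
#'   `max(10000, 100 * size)`.
#' @param patience Consecutive rejections that stop a restart (default 2000).
#' @param restarts Number of independent restarts (default 5).
#' @param seed Integer seed; every run is fully reproducible from it.
#' @param init `"random"` (default) or `"crit_kin_warm"` — greedy
#'   mean-relatedness warm start (requires `warm_data`, see
#'   [exchange_optimize()]).
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(size, max_iterations = max(10000, 100 * size),
                             patience = 2000, restarts = 5, seed = 1,
                             init = c("random", "crit_kin_warm")) {
  init <- match.arg(init)
  if (size < 1) stop("size must be at least 1")
  if (restarts < 1) stop("restarts must be at least 1")
  structure(list(size = size, max_iterations = max_iterations,
                 patience = patience, restarts = restarts,
                 seed = as.integer(seed), init = init),
            class = "optimizer_config")
}

new_calibration_design <- function(selected_ids, criterion_name,
                                   criterion_value, trace, seed) {
  structure(list(selected_ids = selected_ids, criterion_name = criterion_name,
                 criterion_value = criterion_value, trace = trace, seed = seed),
            class = "calibration_design")
}

#' @export
print.calibration_design <- function(x, ...) {
  cat(sprintf("calibration_design: %d individuals, %s = %.5f\n",
              length(x$selected_ids), x$criterion_name, x$criterion_value))
  invisible(x)
}

# Greedy warm start: iteratively add the candidate with the highest mean
# relatedness to the target set.
greedy_crit_kin <- function(candidate_ids, size, K, target_ids) {
  rel <- rowMeans(K[candidate_ids, target_ids, drop = FALSE])
  candidate_ids[order(rel, decreasing = TRUE)[seq_len(size)]]
}

#' Exchange-algorithm calibration-set optimization
#'
#' Maximizes an arbitrary subset criterion by stochastic single-swap local
#' search: starting from an initial subset of the requested size, a random
#' exchange of one selected individual with one excluded candidate is
#' accepted if and only if it strictly improves the criterion, and rejected
#' otherwise. Each restart runs until `max_iterations` swap attempts or
#' `patience` consecutive rejections; the best restart wins.
#'
#' @param candidate_ids Pool of selectable ids.
#' @param criterion Function mapping a character vector of ids to a scalar
#'   to be maximized, e.g. a closure around [cd_criterion()] or
#'   [crit_kin()].
#' @param config An [optimizer_config()].
#' @param criterion_name Label stored in the result.
#' @param warm_data For `init = "crit_kin_warm"`: list with elements `K` and
#'   `target_ids` used by the greedy mean-relatedness initializer.
#' @return A `calibration_design`: `selected_ids`, `criterion_name`,
#'   `criterion_value`, `seed`, and `trace`, a data.frame of the accepted
#'   swaps of the winning restart (iteration, accepted flag, criterion
#'   value; row 0 is the initial subset).
#' @examples
#' K <- diag(6) ; dimnames(K) <- list(letters[1:6], letters[1:6])
#' crit <- function(ids) crit_kin(K, ids, c("e", "f"))
#' exchange_optimize(letters[1:4], crit, optimizer_config(2, seed = 1))
#' @export
exchange_optimize <- function(candidate_ids, criterion, config,
                              criterion_name = "criterion", warm_data = NULL) {
  candidate_ids <- as.character(candidate_ids)
  size <- config$size
  if (size >= length(candidate_ids))
    stop("size must be smaller than the candidate pool")
  if (config$init == "crit_kin_warm" && is.null(warm_data))
    stop("init = 'crit_kin_warm' requires warm_data = list(K, target_ids)")
  best <- NULL
  for (r in seq_len(config$restarts)) {
    set.seed(config$seed + r - 1L)
    current <- if (config$init == "crit_kin_warm" && r == 1) {
      greedy_crit_kin(candidate_ids, size, warm_data$K, warm_data$target_ids)
    } else {
      sample(candidate_ids, size)
    }
    excluded <- setdiff(candidate_ids, current)
    value <- criterion(current)
    trace <- list(data.frame(iteration = 0L, accepted = TRUE, value = value))
    rejections <- 0L
    for (it in seq_len(config$max_iterations)) {
      i_out <- sample.int(length(current), 1L)
      i_in <- sample.int(length(excluded), 1L)
      proposal <- current
      proposal[i_out] <- excluded[i_in]
      new_value <- criterion(proposal)
      if (new_value > value) {
        excluded[i_in] <- current[i_out]
        current <- proposal
        value <- new_value
        trace[[length(trace) + 1L]] <-
          data.frame(iteration = it, accepted = TRUE, value = value)
        rejections <- 0L
      } else {
        rejections <- rejections + 1L
        if (rejections >= config$patience) break
      }
    }
    if (is.null(best) || value > best$criterion_value) {
      best <- new_calibration_design(sort(current), criterion_name, value,
                                     do.call(rbind, trace), config$seed)
    }
  }
  best
}

#' Exhaustive calibration-set search (test oracle)
#'
#' Enumerates every subset of the requested size and returns the maximizer.
#' Guarded to small problems; ties are broken in favor of the
#' lexicographically smallest subset.
#'
#' @param candidate_ids Pool of selectable ids.
#' @param size Subset size; `choose(length(candidate_ids), size)` must not
#'   exceed `max_subsets`.
#' @param criterion Function mapping an id vector to a scalar.
#' @param max_subsets Enumeration guard (default 10000).
#' @return A `calibration_design` (trace has one row).
#' @export
brute_force_optimize <- function(candidate_ids, size, criterion,
                                 max_subsets = 10000) {
  candidate_ids <- sort(as.character(candidate_ids))
  n_subsets <- choose(length(candidate_ids), size)
  if (n_subsets > max_subsets)
    stop(sprintf("%.0f subsets exceed the enumeration guard (%d); use exchange_optimize()",
                 n_subsets, max_subsets))
  subsets <- utils::combn(candidate_ids, size, simplify = FALSE)
  values <- vapply(subsets, criterion, numeric(1))
  best <- which.max(values)   # combn order = lexicographic, so first max wins ties
  new_calibration_design(subsets[[best]], "brute_force", values[best],
                         data.frame(iteration = 0L, accepted = TRUE,
                                    value = values[best]),
                         seed = NA_integer_)
}

# Largest-remainder apportionment of `size` over quotas proportional to
# `weights`; remainder ties are broken by the given (pre-shuffled) order.
largest_remainder <- function(weights, size) {
  exact <- size * weights / sum(weights)
  base <- floor(exact)
  left <- size - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Baseline calibration-set samplers
#'
#' The non-optimized sampling strategies: uniform random sampling, stratified
#' sampling with equal family quotas (`stratified_equal`), and stratified
#' sampling with quotas proportional to family sizes (`stratified_size`).
#' Non-integer quotas are resolved by the largest-remainder rule, with ties
#' spread by a seeded permutation of the families.
#'
#' @param candidate_ids Pool of selectable ids.
#' @param size Calibration-set size.
#' @param method `"random"`, `"stratified_equal"` or `"stratified_size"`.
#' @param family_of Named character vector id -> family (required for the
#'   stratified methods).
#' @param seed Integer seed.
#' @return A `calibration_design` with `criterion_value = NA`.
#' @export
sample_baseline <- function(candidate_ids, size,
                            method = c("random", "stratified_equal", "stratified_size"),
                            family_of = NULL, seed = 1) {
  method <- match.arg(method)
  candidate_ids <- as.character(candidate_ids)
  if (size > length(candidate_ids)) stop("size exceeds the candidate pool")
  set.seed(as.integer(seed))
  if (method == "random") {
    sel <- sample(candidate_ids, size)
  } else {
    if (is.null(family_of)) stop("stratified sampling requires family_of")
    fam <- family_of[candidate_ids]
    if (anyNA(fam)) stop("family_of lacks labels for some candidates")
    fams <- sample(unique(fam))          # seeded permutation for remainder ties
    sizes <- vapply(fams, function(f) sum(fam == f), numeric(1))
    weights <- if (method == "stratified_equal") rep(1, length(fams)) else sizes
    quota <- largest_remainder(weights, size)
    over <- quota > sizes
    if (any(over))
      stop("quota exceeds family size for: ", paste(fams[over], collapse = ", "))
    sel <- unlist(mapply(function(f, q) sample(candidate_ids[fam == f], q),
                         fams, quota, SIMPLIFY = FALSE))
  }
  new_calibration_design(sort(unname(sel)), paste0("baseline_", method), NA_real_,
                         data.frame(iteration = 0L, accepted = TRUE,
                                    value = NA_real_),
                         seed = as.integer(seed))
}

#' Write a calibration design to disk
#'
#' Writes the selected ids (with family labels when available) as a TSV and
#' a JSON sidecar with the criterion name/value, seed and a trace summary.
#'
#' @param design A `calibration_design`.
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @param family_of Optional named character vector id -> family.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, family_of = NULL) {
  fam <- if (is.null(family_of)) NA_character_ else unname(family_of[design$selected_ids])
  utils::write.table(data.frame(id = design$selected_ids, family = fam),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(criterion_name = design$criterion_name,
               criterion_value = design$criterion_value,
               seed = design$seed,
               size = length(design$selected_ids),
               n_accepted_swaps = max(0L, nrow(design$trace) - 1L),
               final_iteration = max(design$trace$iteration))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
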