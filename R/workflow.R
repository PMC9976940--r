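# k-fold cross-validated evaluation with absolute-percentage-error
# summaries.

#' Random fold assignment
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ
#' by at most one and the plan is deterministic per seed. Folds are at the
#' swallow level; pass patient identifiers as `group` for the stricter
#' patient-level split.
#'
#' @param ids vector of swallow identifiers.
#' @param k number of folds (at least 2).
#' @param seed integer seed.
#' @param group optional grouping vector parallel to `ids`; all swallows of
#'   one group land in the same fold.
#' @return data.frame of class `"ues_fold_plan"` with columns `id`, `fold`
#'   (1..k).
#' @export
make_folds <- function(ids, k = 10L, seed = 1, group = NULL) {
  if (k < 2L) stop("at least 2 folds required", call. = FALSE)
  if (is.null(group)) {
    if (k > length(ids)) stop("more folds than swallows", call. = FALSE)
    ord <- with_seed(seed, sample.int(length(ids)))
    plan <- data.frame(id = as.character(ids)[ord],
                       fold = rep_len(seq_len(k), length(ids)),
                       stringsAsFactors = FALSE)
    plan <- plan[order(match(plan$id, ids)), ]
  } else {
    ug <- unique(group)
    if (k > length(ug)) stop("more folds than groups", call. = FALSE)
    ord <- with_seed(seed, sample.int(length(ug)))
    gf <- stats::setNames(rep_len(seq_len(k), length(ug)), ug[ord])
    plan <- data.frame(id = as.character(ids), fold = unname(gf[as.character(group)]),
                       stringsAsFactors = FALSE)
  }
  rownames(plan) <- NULL
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "k") <- as.integer(k)
  class(plan) <- c("ues_fold_plan", "data.frame")
  plan
}

#' Summarize absolute percentage errors
#'
#' Mean, standard deviation and the percentage of swallows at or below each
#' APE threshold.
#'
#' @param apes numeric vector of APE values in percent.
#' @param thresholds APE thresholds in percent.
#' @return list with `n`, `mean_ape`, `sd_ape` and `pct_within` (named
#'   percentage per threshold).
#' @export
summarize_ape <- function(apes, thresholds = c(30, 50)) {
  if (length(apes) == 0L) stop("empty APE list", call. = FALSE)
  pct <- vapply(thresholds, function(th) 100 * mean(apes <= th), numeric(1))
  list(n = length(apes), mean_ape = mean(apes), sd_ape = stats::sd(apes),
       pct_within = stats::setNames(pct, paste0(thresholds)))
}

#' Cross-validated evaluation
#'
#' For each fold, trains on the remaining folds and predicts the held-out
#' swallows, so every swallow is predicted exactly once; pooled predictions
#' are summarized with [summarize_ape()]. Train/test disjointness is
#' asserted per fold.
#'
#' @param samples named list of [swallow_sample()] objects.
#' @param cfg a [model_config()].
#' @param plan a [make_folds()] plan covering exactly the sample ids.
#' @param epochs training epochs per fold.
#' @param seed base seed; fold `f` trains with `seed + f`.
#' @param thresholds APE thresholds for the report.
#' @param trainer fitting backend: `function(samples, cfg, epochs, seed)`
#'   returning an object usable with [predict()]. Defaults to [ues_fit()];
#'   substitute an oracle for plumbing checks.
#' @param verbose print per-fold progress.
#' @return An object of class `"uesnet_cv"`: `results` (data.frame id,
#'   fold, truth, pred, ape), the [summarize_ape()] fields, `plan` and
#'   per-fold training histories.
#' @export
cross_validate <- function(samples, cfg = model_config(), plan,
                           epochs = cfg$epochs, seed = 1,
                           thresholds = c(30, 50), trainer = ues_fit,
                           verbose = FALSE) {
  ids <- vapply(samples, `[[`, character(1), "id")
  names(samples) <- ids
  if (!setequal(plan$id, ids))
    stop("fold plan does not cover exactly the sample ids", call. = FALSE)
  k <- attr(plan, "k")
  res <- NULL
  histories <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- plan$id[plan$fold == f]
    train_ids <- plan$id[plan$fold != f]
    if (length(test_ids) == 0L)
      stop(sprintf("fold %d has no samples", f), call. = FALSE)
    stopifnot(length(intersect(train_ids, test_ids)) == 0L)
    fit <- trainer(samples[train_ids], cfg, epochs = epochs, seed = seed + f)
    preds <- predict(fit, samples[test_ids])
    truths <- vapply(samples[test_ids], `[[`, numeric(1), "target_ratio")
    res <- rbind(res, data.frame(id = test_ids, fold = f,
                                 truth = unname(truths),
                                 pred = unname(preds[test_ids]),
                                 ape = unname(ape(preds[test_ids], truths)),
                                 stringsAsFactors = FALSE))
    histories[[f]] <- if (!is.null(fit$history)) fit$history
    if (verbose)
      message(sprintf("fold %d/%d: mean APE %.1f%%", f, k,
                      mean(res$ape[res$fold == f])))
  }
  stopifnot(!anyDuplicated(res$id), setequal(res$id, ids))
  s <- summarize_ape(res$ape, thresholds)
  structure(c(list(results = res, plan = plan, histories = histories), s),
            class = "uesnet_cv")
}

#' @export
print.uesnet_cv <- function(x, ...) {
  cat(sprintf("<uesnet_cv> %d swallows over %d folds\n",
              x$n, attr(x$plan, "k")))
  cat(sprintf("  mean APE %.2f%% (sd %.2f)\n", x$mean_ape, x$sd_ape))
  for (th in names(x$pct_within))
    cat(sprintf("  APE <= %s%%: %.2f%% of swallows\n", th, x$pct_within[th]))
  invisible(x)
}
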