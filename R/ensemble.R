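#' Seeded subsample of a tree ensemble
#'
#' Draws `k` trees uniformly without replacement. The seed is recorded on
#' the result so downstream reports can state it.
#'
#' @param trees List of `phylo` objects.
#' @param k Number of trees to draw; if `k >= length(trees)` all trees are
#'   returned (in place).
#' @param seed Integer seed for the draw.
#' @return A list of trees with attributes `seed` and `indices`.
#' @export
sample_trees <- function(trees, k, seed = 1) {
  n <- length(trees)
  if (k >= n) {
    idx <- seq_len(n)
  } else {
    idx <- with_seed(seed, sample.int(n, k))
  }
  out <- trees[idx]
  attr(out, "seed") <- seed
  attr(out, "indices") <- idx
  out
}

# Shared driver: apply `fn(tree)` over an ensemble, recording failures
# instead of aborting (individual posterior-sample trees can be
# pathological). Returns list(results, failures).
map_trees <- function(trees, fn) {
  failures <- character(0)
  results <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    results[[i]] <- tryCatch(fn(trees[[i]]),
                             error = function(e) {
                               failures <<- c(failures, sprintf(
                                 "tree %d: %s", i, conditionMessage(e)))
                               NULL
                             })
  }
  list(results = results[!vapply(results, is.null, logical(1))],
       failures = failures)
}

#' Univariate PGLS over a tree ensemble
#'
#' Fits the single-predictor PGLS model on every tree and summarizes the
#' estimate, t statistic, p-value and fitted lambda for each coefficient as
#' the median and the 5th/95th percentiles across trees (linear-interpolation
#' percentiles). Per-tree fit failures are recorded and skipped, with the
#' count reported.
#'
#' @param data Data frame with `species_id`, the response and the predictor.
#' @param trees List of `phylo` objects (at least 2).
#' @param predictor Model term for the right-hand side (may be a factor
#'   column name, which expands to its indicator block).
#' @param response Response column name; default `"log_price"`.
#' @param ... Passed to [pgls()].
#' @return An `ensemble_summary` with `$summary` (one row per term),
#'   `$model_stats` (r2 and F summaries), `$raw` (per-tree statistics),
#'   `$trees_used` and `$failures`.
#' @export
run_univariate_ensemble <- function(data, trees, predictor,
                                    response = "log_price", ...) {
  if (length(trees) < 2) stopf("need at least 2 trees for an ensemble")
  f <- reformulate(predictor, response = response)
  runs <- map_trees(trees, function(tr) {
    fit <- pgls(f, data, tr, ...)
    dplyr::mutate(tidy(fit), lambda = fit$lambda, r2 = fit$r2,
                  adj_r2 = fit$adj_r2, F_statistic = fit$F_statistic,
                  F_p = fit$F_p_value, n = fit$n)
  })
  if (length(runs$results) == 0) {
    stopf("all %d per-tree fits failed; first failure: %s",
          length(trees), runs$failures[1])
  }
  raw <- dplyr::bind_rows(runs$results, .id = "tree")
  summarise_stat <- function(tab, col) {
    dplyr::summarise(dplyr::group_by(tab, .data$term),
                     "{col}_p05" := pctl_summary(.data[[col]])[["p05"]],
                     "{col}_median" := pctl_summary(.data[[col]])[["median"]],
                     "{col}_p95" := pctl_summary(.data[[col]])[["p95"]],
                     .groups = "drop")
  }
  non_int <- dplyr::filter(raw, .data$term != "(Intercept)")
  pieces <- purrr::map(c("estimate", "statistic", "p.value", "lambda"),
                       ~ summarise_stat(non_int, .x))
  summary_tab <- purrr::reduce(pieces, dplyr::left_join, by = "term")
  model_stats <- tibble::tibble(
    predictor = predictor,
    !!!setNames(as.list(pctl_summary(raw$r2[raw$term != "(Intercept)"])),
                paste0("r2_", c("p05", "median", "p95"))),
    adj_r2_median = median(non_int$adj_r2),
    F_median = median(non_int$F_statistic),
    F_p_median = median(non_int$F_p),
    n = max(raw$n))
  structure(list(predictor = predictor, response = response,
                 summary = summary_tab, model_stats = model_stats, raw = raw,
                 trees_used = length(runs$results),
                 failures = runs$failures),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Univariate PGLS ensemble: %s on %d trees (%d failures)\n",
              x$predictor, x$trees_used, length(x$failures)))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_univariate_ensemble Tidy the across-tree summary table.
#' @param x An `ensemble_summary`.
#' @export
tidy.ensemble_summary <- function(x, ...) x$summary

#' Plot an ensemble coefficient summary
#'
#' @param object An `ensemble_summary`.
#' @param ... Unused.
#' @return A ggplot: median estimate per term with 5th-95th percentile bars.
#' @export
autoplot.ensemble_summary <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$estimate_median, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$estimate_p05,
                                          xmax = .data$estimate_p95),
                             colour = "steelblue") +
    ggplot2::labs(x = "coefficient (median, 5th-95th pct across trees)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Identify the candidate model set across a small tree sample
#'
#' Runs the full all-subsets PGLS enumeration on each tree and retains the
#' models whose delta-AICc, aggregated across trees, is below the threshold.
#' Aggregation mode `"median"` (default) keeps models with median
#' across-tree delta below the threshold; `"union"` takes the union of the
#' per-tree candidate sets.
#'
#' @param data Data frame with `species_id`, response and predictors.
#' @param trees_small Small tree sample (the expensive enumeration runs once
#'   per tree).
#' @param blocks Character vector of predictor block names for the global
#'   model.
#' @param response Response column name; default `"log_price"`.
#' @param threshold delta-AICc cutoff; default 4.
#' @param mode `"median"` or `"union"`.
#' @param ... Passed to [dredge_pgls()].
#' @return A list with `$specs` (candidate models as character vectors),
#'   `$table` (per-model median delta), `$mode`, `$trees_used`, `$failures`.
#' @export
identify_candidates <- function(data, trees_small, blocks,
                                response = "log_price", threshold = 4,
                                mode = c("median", "union"), ...) {
  mode <- match.arg(mode)
  if (length(trees_small) == 0) stopf("trees_small is empty")
  runs <- map_trees(trees_small, function(tr) {
    ms <- dredge_pgls(data, tr, response = response, blocks = blocks, ...)
    ms$models[c("terms", "delta", "AICc")]
  })
  if (length(runs$results) == 0) stopf("all candidate-search fits failed")
  per_tree <- dplyr::bind_rows(runs$results, .id = "tree")
  table <- dplyr::summarise(dplyr::group_by(per_tree, .data$terms),
                            median_delta = median(.data$delta),
                            median_aicc = median(.data$AICc),
                            .groups = "drop")
  table <- dplyr::arrange(table, .data$median_delta)
  if (mode == "median") {
    keep <- table$terms[table$median_delta < threshold]
  } else {
    keep <- unique(per_tree$terms[per_tree$delta < threshold])
  }
  specs <- lapply(keep, function(s) {
    if (identical(s, "1")) character(0) else strsplit(s, " \\+ ")[[1]]
  })
  names(specs) <- keep
  list(specs = specs, table = table, mode = mode, threshold = threshold,
       trees_used = length(runs$results), failures = runs$failures)
}

#' Refit the candidate models over a large tree ensemble
#'
#' Refits each candidate model on every tree, then summarizes across trees:
#' per-term coefficient medians and 5th/95th percentiles per model;
#' per-model delta-AICc, lambda and Akaike weight summaries (weights
#' renormalized within the candidate set on each tree); per-block variable
#' importance summaries; and tallies of how many trees ranked each model
#' 1st, 2nd and 3rd.
#'
#' @param candidates Candidate models: the result of
#'   [identify_candidates()], or a list of character vectors of block names.
#' @param data Data frame with `species_id`, response and predictors.
#' @param trees_large Tree ensemble for the refit (typically 100 trees).
#' @param response Response column name; default `"log_price"`.
#' @param ... Passed to [fit_pgls()].
#' @return A `refit_ensemble` with `$models`, `$coefficients`,
#'   `$importance`, `$rank_tallies`, `$trees_used`, `$failures`.
#' @export
refit_ensemble <- function(candidates, data, trees_large,
                           response = "log_price", ...) {
  specs <- if (is.list(candidates) && !is.null(candidates$specs)) {
    candidates$specs
  } else {
    candidates
  }
  if (length(specs) == 0) stopf("no candidate models supplied")
  labels <- vapply(specs, spec_label, "")
  blocks <- unique(unlist(specs))

  runs <- map_trees(trees_large, function(tr) {
    global_vars <- unique(c(response, unlist(lapply(
      blocks, function(b) all.vars(stats::as.formula(paste("~", b)))))))
    keep <- complete.cases(data[intersect(global_vars, names(data))])
    d <- data[keep, , drop = FALSE]
    d$species_id <- normalise_labels(d$species_id)
    common <- intersect(normalise_labels(tr$tip.label), d$species_id)
    trp <- suppressWarnings(prune_to_taxa(tr, common))
    V <- vcv_from_tree(trp)
    d <- d[match(rownames(V), d$species_id), , drop = FALSE]

    fits <- lapply(specs, function(sp) {
      f <- reformulate(if (length(sp) == 0) "1" else sp, response = response)
      mf <- stats::model.frame(f, data = d)
      fit_pgls(stats::model.response(mf),
               model.matrix(attr(mf, "terms"), mf), V, ...)
    })
    aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
    delta <- aiccs - min(aiccs)
    w <- exp(-delta / 2)
    w <- w / sum(w)
    rank <- rank(delta, ties.method = "first")
    imp <- vapply(blocks, function(b) {
      sum(w[vapply(specs, function(s) b %in% s, logical(1))])
    }, numeric(1))
    coefs <- dplyr::bind_rows(purrr::imap(fits, function(f, i) {
      tibble::tibble(model = labels[[i]], term = names(f$beta),
                     estimate = unname(f$beta))
    }))
    list(models = tibble::tibble(model = labels, delta = delta, weight = w,
                                 rank = rank,
                                 lambda = vapply(fits, function(f) f$lambda,
                                                 numeric(1)),
                                 r2 = vapply(fits, function(f) f$r2,
                                             numeric(1))),
         coefs = coefs,
         importance = tibble::tibble(term = blocks, importance = unname(imp)))
  })
  if (length(runs$results) == 0) stopf("all refit-ensemble fits failed")
  n_used <- length(runs$results)

  per_tree_models <- dplyr::bind_rows(purrr::map(runs$results, "models"),
                                      .id = "tree")
  per_tree_coefs <- dplyr::bind_rows(purrr::map(runs$results, "coefs"),
                                     .id = "tree")
  per_tree_imp <- dplyr::bind_rows(purrr::map(runs$results, "importance"),
                                   .id = "tree")

  pct3 <- function(tab, group_cols, value_col) {
    dplyr::summarise(
      dplyr::group_by(tab, dplyr::across(dplyr::all_of(group_cols))),
      p05 = pctl_summary(.data[[value_col]])[["p05"]],
      median = pctl_summary(.data[[value_col]])[["median"]],
      p95 = pctl_summary(.data[[value_col]])[["p95"]],
      .groups = "drop")
  }
  models <- dplyr::summarise(
    dplyr::group_by(per_tree_models, .data$model),
    delta_p05 = pctl_summary(.data$delta)[["p05"]],
    delta_median = pctl_summary(.data$delta)[["median"]],
    delta_p95 = pctl_summary(.data$delta)[["p95"]],
    lambda_p05 = pctl_summary(.data$lambda)[["p05"]],
    lambda_median = pctl_summary(.data$lambda)[["median"]],
    lambda_p95 = pctl_summary(.data$lambda)[["p95"]],
    weight_p05 = pctl_summary(.data$weight)[["p05"]],
    weight_median = pctl_summary(.data$weight)[["median"]],
    weight_p95 = pctl_summary(.data$weight)[["p95"]],
    r2_median = median(.data$r2),
    rank1 = sum(.data$rank == 1),
    rank2 = sum(.data$rank == 2),
    rank3 = sum(.data$rank == 3),
    .groups = "drop")
  models <- dplyr::arrange(models, .data$delta_median)
  coefficients <- pct3(per_tree_coefs, c("model", "term"), "estimate")
  coefficients <- dplyr::rename(coefficients, estimate_p05 = "p05",
                                estimate_median = "median",
                                estimate_p95 = "p95")
  importance <- pct3(per_tree_imp, "term", "importance")
  importance <- dplyr::rename(importance, importance_p05 = "p05",
                              importance_median = "median",
                              importance_p95 = "p95")
  importance <- dplyr::arrange(importance, dplyr::desc(.data$importance_median))

  structure(list(models = models, coefficients = coefficients,
                 importance = importance,
                 per_tree = list(models = per_tree_models,
                                 coefficients = per_tree_coefs,
                                 importance = per_tree_imp),
                 specs = specs, labels = labels,
                 trees_used = n_used, failures = runs$failures),
            class = "refit_ensemble")
}

#' @export
print.refit_ensemble <- function(x, ...) {
  cat(sprintf("Candidate-set refit over %d trees (%d failures), %d models\n",
              x$trees_used, length(x$failures), length(x$specs)))
  print(x$models)
  cat("Variable importance:\n")
  print(x$importance)
  invisible(x)
}

#' @describeIn refit_ensemble Tidy the per-model, per-term coefficient
#'   summaries.
#' @param x A `refit_ensemble`.
#' @param ... Unused.
#' @export
tidy.refit_ensemble <- function(x, ...) x$coefficients

#' Plot a candidate-set refit
#'
#' @param object A `refit_ensemble`.
#' @param ... Unused.
#' @return A ggplot of per-model term estimates (median and 5th-95th
#'   percentile across trees).
#' @export
autoplot.refit_ensemble <- function(object, ...) {
  d <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate_median, y = .data$term,
                                  colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$estimate_p05,
                                          xmax = .data$estimate_p95),
                             position = ggplot2::position_dodge(width = 0.5),
                             show.legend = FALSE) +
    ggplot2::labs(x = "coefficient (median, 5th-95th pct across trees)",
                  y = NULL, title = "Candidate models across the tree ensemble") +
    ggplot2::theme_minimal()
}
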