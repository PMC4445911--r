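#' Enumerate all submodels of a set of predictor blocks
#'
#' Returns every subset of the predictor blocks (2^m models, including the
#' intercept-only model). A block is the unit a predictor enters or leaves
#' with: a multi-level factor is one block and its indicator columns never
#' split.
#'
#' @param blocks Character vector of predictor block names (model terms).
#' @param max_blocks Combinatorial guard: refuse more than this many blocks
#'   (default 20, i.e. about a million models).
#' @return A list of character vectors; the empty vector is the
#'   intercept-only model.
#' @export
enumerate_submodels <- function(blocks, max_blocks = 20) {
  blocks <- unique(as.character(blocks))
  m <- length(blocks)
  if (m > max_blocks) {
    stopf("%d predictor blocks would enumerate %.3g models; raise max_blocks to force",
          m, 2^m)
  }
  if (m == 0) return(list(character(0)))
  specs <- vector("list", 2^m)
  for (i in seq_len(2^m)) {
    bits <- as.logical(bitwAnd(i - 1L, bitwShiftL(1L, seq_len(m) - 1L)))
    specs[[i]] <- blocks[bits]
  }
  ord <- order(lengths(specs),
               vapply(specs, function(s) paste(s, collapse = "+"), ""))
  specs[ord]
}

spec_label <- function(spec) {
  if (length(spec) == 0) "1" else paste(spec, collapse = " + ")
}

#' Rank fitted models by AICc
#'
#' Computes each model's AICc difference from the best model
#' (`delta = AICc - min(AICc)`) and its Akaike weight
#' `exp(-delta/2) / sum(exp(-delta/2))`, and sorts models by delta with ties
#' broken by fewer parameters, then by the term string.
#'
#' @param fits List of `pgls_fit` objects.
#' @param specs List of character vectors naming the predictor blocks of
#'   each fit (parallel to `fits`).
#' @return A `model_set`: the ranked model table (`$models`), the fits in
#'   ranked order (`$fits`) and the union of blocks (`$blocks`).
#' @export
rank_models <- function(fits, specs = NULL) {
  if (length(fits) == 0) stopf("no fitted models to rank")
  specs <- specs %||% lapply(fits, function(f) {
    setdiff(names(f$beta), "(Intercept)")
  })
  models <- tibble::tibble(
    terms = vapply(specs, spec_label, ""),
    n_terms = lengths(specs),
    K = vapply(fits, function(f) f$K, numeric(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    lambda = vapply(fits, function(f) f$lambda, numeric(1)),
    r2 = vapply(fits, function(f) f$r2 %||% NA_real_, numeric(1)),
    n = vapply(fits, function(f) f$n, numeric(1)))
  models$delta <- models$AICc - min(models$AICc)
  models$weight <- exp(-models$delta / 2)
  models$weight <- models$weight / sum(models$weight)
  ord <- order(models$delta, models$K, models$terms)
  models <- models[ord, , drop = FALSE]
  models$model_id <- seq_len(nrow(models))
  models <- dplyr::relocate(models, "model_id")
  structure(list(models = models,
                 fits = fits[ord],
                 specs = specs[ord],
                 blocks = unique(unlist(specs))),
            class = "model_set")
}

#' @export
print.model_set <- function(x, n = 10, ...) {
  cat(sprintf("Model set: %d models over %d predictor blocks\n",
              nrow(x$models), length(x$blocks)))
  print(head(x$models, n))
  invisible(x)
}

#' @describeIn rank_models Tidy the ranked model table.
#' @param x A `model_set`.
#' @param ... Unused.
#' @export
tidy.model_set <- function(x, ...) x$models

#' Variable importance: summed Akaike weights
#'
#' The importance of a predictor block is the sum of the Akaike weights of
#' every model that contains it, a value in \[0, 1\].
#'
#' @param set A `model_set` from [rank_models()].
#' @param predictor Optional single block name; if omitted all blocks are
#'   returned.
#' @return A tibble (`term`, `importance`), or a scalar if `predictor` is
#'   given.
#' @export
variable_importance <- function(set, predictor = NULL) {
  blocks <- set$blocks
  if (!is.null(predictor)) {
    if (!predictor %in% blocks) stopf("unknown predictor: %s", predictor)
    blocks <- predictor
  }
  imp <- vapply(blocks, function(b) {
    has <- vapply(set$specs, function(s) b %in% s, logical(1))
    sum(set$models$weight[has])
  }, numeric(1))
  if (!is.null(predictor)) return(unname(imp))
  tibble::tibble(term = blocks, importance = unname(imp))[
    order(-imp), , drop = FALSE]
}

#' Model-averaged coefficients
#'
#' Conditional (natural) averaging is primary: for each coefficient, the
#' weighted mean over the models that contain it, with weights renormalized
#' to those models. The full average (treating the coefficient as 0 in
#' models that exclude it) is reported alongside, since the two conventions
#' answer different questions.
#'
#' @param set A `model_set`.
#' @return A tibble: `term`, `estimate_conditional`, `estimate_full`,
#'   `weight_sum` (the summed weight of models containing the term).
#' @export
model_average <- function(set) {
  w <- set$models$weight
  coef_tabs <- purrr::imap(set$fits, function(f, i) {
    tibble::tibble(term = names(f$beta), beta = unname(f$beta), weight = w[i])
  })
  all_coefs <- dplyr::bind_rows(coef_tabs)
  dplyr::summarise(
    dplyr::group_by(all_coefs, .data$term),
    estimate_conditional = sum(.data$beta * .data$weight) / sum(.data$weight),
    estimate_full = sum(.data$beta * .data$weight),
    weight_sum = sum(.data$weight),
    .groups = "drop")
}

#' Flag the candidate model set
#'
#' Marks models whose AICc difference from the best model is below the
#' threshold (default 4).
#'
#' @param set A `model_set`.
#' @param threshold Positive delta-AICc cutoff; default 4.
#' @return The `model_set` with a logical `candidate` column added to
#'   `$models`; the flagged count is in `attr(, "n_candidates")`.
#' @export
candidate_set <- function(set, threshold = 4) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stopf("threshold must be positive")
  }
  set$models$candidate <- set$models$delta < threshold
  attr(set, "n_candidates") <- sum(set$models$candidate)
  set
}

#' Bonferroni correction for a family of univariate tests
#'
#' A p-value is called significant iff it is below `alpha / m`. Used for the
#' family of 11 per-colour univariate tests.
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of tests in the family; defaults to
#'   `length(p_values)`.
#' @param alpha Family-wise error rate; default 0.05.
#' @return A tibble (`p_value`, `significant`) with the threshold, `alpha`
#'   and `m` stored as attributes.
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m < 1) stopf("m must be >= 1")
  threshold <- alpha / m
  out <- tibble::tibble(p_value = as.numeric(p_values),
                        significant = p_values < threshold)
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  out
}

#' All-subsets PGLS model selection
#'
#' Fits every submodel of a global predictor set by PGLS (lambda re-estimated
#' by maximum likelihood in each submodel) and ranks them by AICc. The
#' complete-case rows are fixed by the global model's predictor set before
#' enumeration so every submodel is fitted to the same observations --
#' information criteria are not comparable otherwise.
#'
#' @param data A data frame with `species_id`, the response and the
#'   predictors (typically from [transform_predictors()]).
#' @param tree A `phylo` object or a VCV matrix with tip dimnames.
#' @param response Name of the response column (default `"log_price"`).
#' @param blocks Character vector of predictor block names (model terms).
#' @param max_blocks Guard passed to [enumerate_submodels()].
#' @param ... Passed to [fit_pgls()].
#' @return A `model_set`.
#' @export
dredge_pgls <- function(data, tree, response = "log_price", blocks,
                        max_blocks = 20, ...) {
  specs <- enumerate_submodels(blocks, max_blocks = max_blocks)
  global_vars <- unique(c(response, unlist(
    lapply(blocks, function(b) all.vars(stats::as.formula(paste("~", b)))))))
  keep <- complete.cases(data[intersect(global_vars, names(data))])
  d <- data[keep, , drop = FALSE]
  d$species_id <- normalise_labels(d$species_id)

  if (inherits(tree, "phylo")) {
    common <- intersect(normalise_labels(tree$tip.label), d$species_id)
    tr <- suppressWarnings(prune_to_taxa(tree, common))
    V <- vcv_from_tree(tr)
  } else {
    common <- intersect(rownames(tree), d$species_id)
    V <- tree[common, common, drop = FALSE]
  }
  d <- d[match(rownames(V), d$species_id), , drop = FALSE]

  fits <- lapply(specs, function(sp) {
    f <- reformulate(if (length(sp) == 0) "1" else sp, response = response)
    mf <- stats::model.frame(f, data = d)
    y <- stats::model.response(mf)
    X <- model.matrix(attr(mf, "terms"), mf)
    fit_pgls(y, X, V, ...)
  })
  rank_models(fits, specs)
}

#' Plot a model-selection table
#'
#' @param object A `model_set`.
#' @param n Show the top `n` models; default 20.
#' @param ... Unused.
#' @return A ggplot of Akaike weight against model rank, annotated with the
#'   delta-AICc values.
#' @export
autoplot.model_set <- function(object, n = 20, ...) {
  d <- head(object$models, n)
  d$terms <- factor(d$terms, levels = rev(d$terms))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$terms)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("Δ %.2f", .data$delta)),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "Akaike weight", y = NULL,
                  title = "AICc model ranking") +
    ggplot2::theme_minimal()
}
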