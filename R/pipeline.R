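#' Assemble a pipeline run configuration
#'
#' Collects paths, analysis defaults and the seed for the pipeline stages.
#' Values may come from a YAML file (`yaml` argument), with arguments given
#' here overriding file values. Defaults are the analysis defaults used
#' throughout: 100 trees for univariate ensembles, 10 for the candidate
#' search, 100 for the refit, delta-AICc threshold 4, alpha 0.05 with an
#' 11-test colour family, and 30 TWD per USD.
#'
#' @param trait_csv,colour_csv,tree_file Input paths (optional when `data`
#'   / `trees` are supplied directly).
#' @param data A trait table supplied in memory (takes precedence over
#'   `trait_csv`).
#' @param trees A list of `phylo` objects (takes precedence over
#'   `tree_file`).
#' @param exclusions Species identifiers to drop before analysis.
#' @param n_trees_univariate,n_trees_candidate,n_trees_refit Tree counts per
#'   stage.
#' @param delta_threshold Candidate-set delta-AICc cutoff.
#' @param alpha,m_colours Bonferroni family parameters for the colour tests.
#' @param exchange_rate TWD per USD for descriptive tallies.
#' @param seed Seed for tree subsampling.
#' @param out_dir Optional output directory; when set, the `run_*` stages
#'   write CSV/JSON reports there, each stamped with the seed and a config
#'   hash.
#' @param yaml Optional path to a YAML file holding any of the above fields.
#' @return A `run_config` list with a `hash` field.
#' @export
run_config <- function(trait_csv = NULL, colour_csv = NULL, tree_file = NULL,
                       data = NULL, trees = NULL, exclusions = character(),
                       n_trees_univariate = 100, n_trees_candidate = 10,
                       n_trees_refit = 100, delta_threshold = 4,
                       alpha = 0.05, m_colours = 11, exchange_rate = 30,
                       seed = 1, out_dir = NULL, yaml = NULL) {
  cfg <- list(trait_csv = trait_csv, colour_csv = colour_csv,
              tree_file = tree_file, data = data, trees = trees,
              exclusions = exclusions,
              n_trees_univariate = n_trees_univariate,
              n_trees_candidate = n_trees_candidate,
              n_trees_refit = n_trees_refit,
              delta_threshold = delta_threshold, alpha = alpha,
              m_colours = m_colours, exchange_rate = exchange_rate,
              seed = seed, out_dir = out_dir)
  if (!is.null(yaml)) {
    from_file <- yaml::read_yaml(yaml)
    supplied <- !vapply(cfg, is.null, logical(1)) &
      names(cfg) %in% names(as.list(match.call()))
    for (nm in setdiff(names(from_file), names(cfg)[supplied])) {
      cfg[[nm]] <- from_file[[nm]]
    }
  }
  if (cfg$n_trees_univariate < 1 || cfg$n_trees_candidate < 1 ||
      cfg$n_trees_refit < 1) {
    stopf("tree counts must be >= 1")
  }
  if (cfg$delta_threshold <= 0) stopf("delta_threshold must be positive")
  hashable <- cfg[setdiff(names(cfg), c("data", "trees"))]
  cfg$hash <- rlang::hash(hashable)
  structure(cfg, class = "run_config")
}

config_table <- function(config) {
  tab <- config$data %||% read_species_table(config$trait_csv)
  if (!inherits(tab, "trait_table")) tab <- as_trait_table(tab)
  if (length(config$exclusions) > 0) {
    tab <- apply_exclusions(tab, config$exclusions)
  }
  tab
}

config_trees <- function(config) {
  trees <- config$trees %||% parse_trees(config$tree_file)
  if (length(trees) == 0) stopf("no trees available")
  trees
}

write_stage_output <- function(config, stage, tables = list(),
                               json = NULL) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = config$seed, config_hash = config$hash)
  for (nm in names(tables)) {
    path <- file.path(config$out_dir, sprintf("%s_%s.csv", stage, nm))
    tab <- dplyr::mutate(tables[[nm]], seed = stamp$seed,
                         config_hash = stamp$config_hash)
    readr::write_csv(tab, path)
  }
  if (!is.null(json)) {
    path <- file.path(config$out_dir, sprintf("%s.json", stage))
    jsonlite::write_json(c(json, stamp), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}

#' Pipeline stage: descriptive market tallies
#'
#' Loads the trait table, applies exclusions and computes
#' [summary_tallies()]; when `out_dir` is set, writes a JSON tally report
#' and a top-species CSV.
#'
#' @param config A [run_config()].
#' @param top_k Size of the top-abundance table; default 10.
#' @return The `market_tallies`, invisibly.
#' @export
run_describe <- function(config, top_k = 10) {
  tab <- config_table(config)
  tal <- summary_tallies(tab, exchange_rate = config$exchange_rate,
                         top_k = top_k)
  write_stage_output(
    config, "describe",
    tables = list(top_species = head(tal$abundance_ranking, top_k)),
    json = list(n_species = tal$n_species,
                total_individuals = tal$total_individuals,
                alien_species = tal$alien_species,
                alien_individuals = tal$alien_individuals,
                top_k = tal$top_k, top_share = tal$top_share,
                min_price_usd = tal$min_price_usd,
                max_price_usd = tal$max_price_usd,
                total_value_usd = tal$total_value_usd))
  invisible(tal)
}

default_univariate_predictors <- function(data) {
  base <- c("log_n_for_sale", "log_mass", "log_range", "song_attractiveness",
            "status", "cites_listed", "iucn", "realm")
  colours <- grep("^asr_colour_", names(data), value = TRUE)
  extra <- intersect("colour_diversity", names(data))
  c(intersect(base, names(data)), colours, extra)
}

#' Pipeline stage: univariate PGLS ensembles
#'
#' Transforms predictors, samples `n_trees_univariate` trees (seeded), and
#' fits each univariate PGLS model over the ensemble, summarizing estimate,
#' t, p and lambda as median and 5th/95th percentiles. Colour-coverage terms
#' are flagged for significance under the Bonferroni family of
#' `m_colours` tests on their median p-value.
#'
#' @param config A [run_config()].
#' @param predictors Predictor terms to test; defaults to the standard set
#'   (numbers, mass, range, song, status, CITES, IUCN, realm, each colour,
#'   colour diversity) restricted to available columns.
#' @return A tibble with one row per term, plus per-predictor summaries in
#'   `attr(, "ensembles")`.
#' @export
run_univariate <- function(config, predictors = NULL) {
  tab <- transform_predictors(config_table(config))
  trees <- sample_trees(config_trees(config), config$n_trees_univariate,
                        seed = config$seed)
  predictors <- predictors %||% default_univariate_predictors(tab)
  ensembles <- purrr::map(predictors, function(p) {
    run_univariate_ensemble(tab, trees, p)
  })
  names(ensembles) <- predictors
  rows <- purrr::imap_dfr(ensembles, function(e, p) {
    dplyr::mutate(e$summary, predictor = p, trees_used = e$trees_used,
                  failures = length(e$failures), .before = 1)
  })
  is_colour <- grepl("^asr_colour_", rows$predictor)
  rows$bonferroni_significant <- NA
  if (any(is_colour)) {
    calls <- bonferroni(rows$p.value_median[is_colour],
                        m = config$m_colours, alpha = config$alpha)
    rows$bonferroni_significant[is_colour] <- calls$significant
  }
  write_stage_output(config, "univariate", tables = list(summary = rows))
  attr(rows, "ensembles") <- ensembles
  rows
}

default_global_blocks <- function(data) {
  base <- c("cites_listed", "log_range", "log_n_for_sale", "log_mass",
            "iucn_not_lc", "song_attractiveness", "status")
  colours <- intersect(c("asr_colour_grey", "asr_colour_yellow"),
                       names(data))
  c(intersect(base, names(data)), colours)
}

#' Pipeline stage: multi-model inference over tree ensembles
#'
#' Runs the two-stage tree-uncertainty procedure: the all-subsets candidate
#' search on a small seeded tree sample ([identify_candidates()]), then the
#' candidate refit on a larger independent seeded sample
#' ([refit_ensemble()]).
#'
#' @param config A [run_config()].
#' @param blocks Predictor blocks of the global model; defaults to numbers,
#'   mass, range, song, status, CITES, the binary IUCN recode and the grey
#'   and yellow colour terms (restricted to available columns).
#' @param mode Candidate aggregation mode; see [identify_candidates()].
#' @return A list with `$candidates` and `$refit`.
#' @export
run_dredge <- function(config, blocks = NULL, mode = "median") {
  tab <- transform_predictors(config_table(config))
  all_trees <- config_trees(config)
  trees_small <- sample_trees(all_trees, config$n_trees_candidate,
                              seed = config$seed)
  trees_large <- sample_trees(all_trees, config$n_trees_refit,
                              seed = config$seed + 1L)
  blocks <- blocks %||% default_global_blocks(tab)
  cand <- identify_candidates(tab, trees_small, blocks,
                              threshold = config$delta_threshold,
                              mode = mode)
  refit <- refit_ensemble(cand, tab, trees_large)
  write_stage_output(config, "dredge",
                     tables = list(models = refit$models,
                                   coefficients = refit$coefficients,
                                   importance = refit$importance,
                                   candidate_search = cand$table))
  list(candidates = cand, refit = refit)
}

#' Pipeline stage: songbird-only sensitivity analysis
#'
#' Repeats the song-attractiveness univariate PGLS ensemble on the
#' Passeriformes subset only, to check whether the song effect in the full
#' data is driven by non-songbirds (e.g. parrots traded for other reasons).
#'
#' @param config A [run_config()].
#' @param predictor Predictor term; default `"song_attractiveness"`.
#' @param min_species Refuse subsets smaller than this; default 10.
#' @return An `ensemble_summary` for the subset.
#' @export
run_passeriformes <- function(config, predictor = "song_attractiveness",
                              min_species = 10) {
  tab <- config_table(config)
  if (!"order" %in% names(tab)) stopf("trait table has no 'order' column")
  sub <- tab[!is.na(tab$order) & tab$order == "Passeriformes", , drop = FALSE]
  if (nrow(sub) < min_species) {
    stopf("Passeriformes subset has %d species (< %d): refusing sensitivity fit",
          nrow(sub), min_species)
  }
  sub <- transform_predictors(sub)
  trees <- sample_trees(config_trees(config), config$n_trees_univariate,
                        seed = config$seed)
  res <- run_univariate_ensemble(sub, trees, predictor)
  write_stage_output(config, "passeriformes",
                     tables = list(summary = res$summary))
  res
}

#' Price-abundance scatter plot
#'
#' Log price against log number for sale, coloured by native/alien status,
#' with the pooled least-squares line.
#'
#' @param table A trait table (price and counts on the raw scale).
#' @return A ggplot.
#' @export
plot_price_abundance <- function(table) {
  d <- dplyr::mutate(tibble::as_tibble(table),
                     log_price = log(.data$price_twd),
                     log_n = log(.data$n_for_sale))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_n, y = .data$log_price)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status,
                                     shape = .data$status), alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = c(native = "grey25",
                                            alien = "firebrick")) +
    ggplot2::labs(x = "ln(number for sale)", y = "ln(price, TWD)",
                  colour = "status", shape = "status") +
    ggplot2::theme_minimal()
}
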