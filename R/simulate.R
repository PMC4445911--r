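#' Simulate a pure-birth (Yule) phylogeny
#'
#' Grows a tree under a constant per-lineage speciation rate: starting from
#' the root split (two lineages), with `k` lineages the waiting time to the
#' next split is exponential with rate `k * birth_rate`, and the splitting
#' lineage is chosen uniformly. After the `n`-th tip appears, one further
#' waiting time is drawn so terminal branches have positive length. The tree
#' is ultrametric; by default it is rescaled to unit height so that lambda
#' and the residual variance are comparable across simulated trees.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Per-lineage speciation rate; default 1.
#' @param seed Integer seed; the same seed reproduces the same tree
#'   bit-for-bit without disturbing the caller's RNG stream.
#' @param unit_height Rescale the tree to height 1 (default `TRUE`).
#' @return A `phylo` object with tips labelled `sp0001`, `sp0002`, ...
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               unit_height = TRUE) {
  if (n_tips < 2) stopf("need n_tips >= 2")
  if (birth_rate <= 0) stopf("birth_rate must be positive")
  with_seed(seed, {
    # Node bookkeeping: ids grow as lineages split; id 1 is the root.
    parent <- c(NA_integer_, 1L, 1L)
    start <- c(0, 0, 0)           # time each lineage's branch begins
    end <- rep(NA_real_, 3)       # time it splits (internal) or NA (alive)
    active <- c(2L, 3L)
    t_now <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t_now <- t_now + rexp(1, rate = k * birth_rate)
      i <- active[sample.int(k, 1)]
      end[i] <- t_now
      id1 <- length(parent) + 1L
      id2 <- id1 + 1L
      parent <- c(parent, i, i)
      start <- c(start, t_now, t_now)
      end <- c(end, NA_real_, NA_real_)
      active <- c(setdiff(active, i), id1, id2)
    }
    t_present <- t_now + rexp(1, rate = n_tips * birth_rate)
    end[active] <- t_present

    tips <- sort(active)
    internals <- setdiff(seq_along(parent), tips)
    new_id <- integer(length(parent))
    new_id[tips] <- seq_len(n_tips)
    new_id[internals] <- n_tips + seq_along(internals)
    has_edge <- which(!is.na(parent))
    edge <- cbind(new_id[parent[has_edge]], new_id[has_edge])
    edge_length <- end[has_edge] - start[has_edge]
    if (unit_height) edge_length <- edge_length / t_present
    tree <- structure(list(edge = edge, edge.length = edge_length,
                           Nnode = length(internals),
                           tip.label = sprintf("sp%04d", seq_len(n_tips))),
                      class = "phylo", order = "cladewise")
    ape::reorder.phylo(tree)
  })
}

#' Specify a trait simulation
#'
#' Bundles the generating parameters for [simulate_traits()]: the true
#' Pagel's lambda and residual variance of the response (log price), the
#' coefficient of each predictor, and how each predictor is generated.
#'
#' Predictor generator types:
#' \describe{
#'   \item{`brownian`}{Brownian motion on the tree: `list(type = "brownian",
#'     mean, sd)` -- `sd` is the trait standard deviation at the tips.}
#'   \item{`normal`}{i.i.d. normal: `list(type = "normal", mean, sd)`.}
#'   \item{`bernoulli`}{i.i.d. binary: `list(type = "bernoulli", p)`.}
#'   \item{`clade`}{Phylogenetically clumped binary: the smallest clade
#'     holding at least fraction `p` of tips is set to 1, with flip
#'     probability `noise` elsewhere: `list(type = "clade", p, noise)`.}
#'   \item{`lognormal`}{Positive counts: `list(type = "lognormal", meanlog,
#'     sdlog)`, rounded up to at least 1.}
#' }
#'
#' @param lambda True Pagel's lambda in \[0, 1\]; default 0.9.
#' @param beta Named numeric vector of coefficients, one per predictor (the
#'   intercept is supplied separately).
#' @param intercept Intercept of the response; default 0.
#' @param sigma2 Residual variance at the tips; default 0.5.
#' @param predictors Named list of generator specifications (names must
#'   match `names(beta)`).
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(lambda = 0.9,
                            beta = c(x1 = 2, x2 = -0.1, x3 = 0.6),
                            intercept = 0, sigma2 = 0.5,
                            predictors = NULL, seed = 1) {
  if (lambda < 0 || lambda > 1) stopf("lambda must be in [0, 1]")
  if (sigma2 < 0) stopf("sigma2 must be non-negative")
  predictors <- predictors %||% setNames(
    rep(list(list(type = "normal", mean = 0, sd = 1)), length(beta)),
    names(beta))
  if (!setequal(names(predictors), names(beta))) {
    stopf("predictor generators must match names(beta)")
  }
  structure(list(lambda = lambda, beta = beta, intercept = intercept,
                 sigma2 = sigma2, predictors = predictors, seed = seed),
            class = "simulation_spec")
}

generate_predictor <- function(gen, tree, V) {
  n <- length(tree$tip.label)
  switch(gen$type,
    normal = rnorm(n, gen$mean %||% 0, gen$sd %||% 1),
    brownian = {
      z <- drop(crossprod(chol(V / max(diag(V))), rnorm(n))) * (gen$sd %||% 1)
      z + (gen$mean %||% 0)
    },
    bernoulli = rbinom(n, 1, gen$p %||% 0.5),
    clade = clade_blocked_binary(tree, gen$p %||% 0.5, gen$noise %||% 0.05),
    lognormal = pmax(1, round(rlnorm(n, gen$meanlog %||% 0,
                                     gen$sdlog %||% 1))),
    stopf("unknown predictor generator type: %s", gen$type))
}

# Binary trait concentrated in one clade: choose the smallest clade covering
# at least fraction p of the tips, set it to 1, then flip each tip with
# probability `noise`.
clade_blocked_binary <- function(tree, p = 0.5, noise = 0.05) {
  n <- length(tree$tip.label)
  target <- ceiling(p * n)
  internal <- (n + 1):(n + tree$Nnode)
  sizes <- vapply(internal, function(nd) {
    length(phangorn_free_descendants(tree, nd))
  }, integer(1))
  ok <- internal[sizes >= target]
  node <- if (length(ok) > 0) ok[which.min(sizes[sizes >= target])] else internal[1]
  members <- phangorn_free_descendants(tree, node)
  x <- integer(n)
  x[members] <- 1L
  flip <- runif(n) < noise
  x[flip] <- 1L - x[flip]
  x
}

# Tip indices descending from an internal node (small trees; simple walk).
phangorn_free_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  sort(out)
}

#' Simulate traits on a phylogeny
#'
#' Builds the predictor matrix from the generators in `spec`, then draws the
#' response with phylogenetically structured noise:
#' `y = intercept + X beta + eps` with
#' `eps ~ N(0, sigma2 * lambda_transform(V, lambda))` drawn through the
#' Cholesky factor. The response is stored as `log_price` (and
#' back-transformed to `price_twd`), so the output feeds straight into the
#' regression machinery.
#'
#' @param tree A `phylo` object.
#' @param spec A [simulation_spec()].
#' @return A tibble with `species_id`, the predictors, `log_price` and
#'   `price_twd`; the spec and tree are attached as attributes.
#' @export
simulate_traits <- function(tree, spec) {
  V <- vcv_from_tree(tree)
  n <- nrow(V)
  with_seed(spec$seed, {
    X <- vapply(names(spec$beta), function(nm) {
      generate_predictor(spec$predictors[[nm]], tree, V)
    }, numeric(n))
    X <- matrix(X, nrow = n, dimnames = list(rownames(V), names(spec$beta)))
    W <- lambda_transform(V, spec$lambda)
    eps <- if (spec$sigma2 > 0) {
      drop(crossprod(chol(spec$sigma2 * W), rnorm(n)))
    } else {
      numeric(n)
    }
    y <- unname(spec$intercept + drop(X %*% spec$beta) + eps)
    out <- tibble::as_tibble(as.data.frame(X))
    out <- dplyr::mutate(out, species_id = rownames(V), log_price = y,
                         price_twd = exp(y), .before = 1)
    attr(out, "spec") <- spec
    attr(out, "tree") <- tree
    out
  })
}

#' Build a complete synthetic study: trait table, colour sheet and trees
#'
#' Generates a fixture with the shape of a market survey: 217 species with
#' prices, counts for sale, native/alien status (phylogenetically clumped),
#' realm, IUCN category, CITES flag, body mass, range size, song-recording
#' counts and a full 14-part x 11-colour score sheet, together with
#' 100 + 10 phylogenies (a base Yule tree with multiplicative branch-length
#' jitter emulating tree uncertainty).
#'
#' Log price is generated from a known linear model on the transformed
#' predictors -- strong effects of log numbers for sale (negative), log
#' body mass (positive), alien status (positive) and yellow colour coverage
#' (positive), a modest negative song-attractiveness effect -- with
#' phylogenetic residual signal `lambda = 0.9`. Abundances span 1 to several
#' thousand, mimicking the long-tailed abundance ranking of a real market.
#'
#' @param seed Integer seed; the whole study is a pure function of it.
#' @param n_species Number of species; default 217.
#' @param n_trees_univariate Trees for univariate ensembles; default 100.
#' @param n_trees_candidate Trees for the candidate search; default 10.
#' @param jitter_sd Standard deviation of the log-normal branch-length
#'   jitter; default 0.1.
#' @return A list: `$table` (trait_table), `$colour_sheet` (long format),
#'   `$trees` (all trees; first `n_trees_univariate` are the univariate
#'   sample, the rest the candidate sample), `$trees_univariate`,
#'   `$trees_candidate`, `$truth` (generating parameters), `$seed`.
#' @export
build_synthetic_study <- function(seed = 1, n_species = 217,
                                  n_trees_univariate = 100,
                                  n_trees_candidate = 10,
                                  jitter_sd = 0.1) {
  base_tree <- simulate_yule_tree(n_species, seed = seed)
  n_trees <- n_trees_univariate + n_trees_candidate
  trees <- with_seed(seed + 1L, lapply(seq_len(n_trees), function(i) {
    tr <- base_tree
    tr$edge.length <- tr$edge.length * rlnorm(length(tr$edge.length),
                                              0, jitter_sd)
    tr
  }))
  V <- vcv_from_tree(base_tree)

  study <- with_seed(seed + 2L, {
    sp <- rownames(V)
    n <- length(sp)
    # abundance: long-tailed, 1 .. thousands
    n_for_sale <- pmax(1, round(rlnorm(n, meanlog = 3, sdlog = 1.8)))
    body_mass_g <- exp(drop(crossprod(chol(V), rnorm(n))) * 1.2 + log(60))
    range_km2 <- rlnorm(n, meanlog = log(5e5), sdlog = 1.5)
    song_count <- rpois(n, lambda = pmax(0.2, 3 * (log(range_km2) - 8)))
    status <- ifelse(clade_blocked_binary(base_tree, p = 0.55,
                                          noise = 0.08) == 1,
                     "alien", "native")
    realm <- sample(c("Afrotropic", "Australasia", "Indo-Malay", "Neotropic",
                      "Palearctic"), n, replace = TRUE,
                    prob = c(0.1, 0.18, 0.3, 0.18, 0.24))
    iucn <- sample(c("LC", "NT", "VU", "EN"), n, replace = TRUE,
                   prob = c(0.8, 0.1, 0.07, 0.03))
    cites_listed <- rbinom(n, 1, 0.25)

    # full colour sheet: each part carries 1-3 colours; yellow enriched in
    # one clade so colour has phylogenetic structure
    parts <- body_part_names()
    cols <- colour_names()
    yellow_clade <- clade_blocked_binary(base_tree, p = 0.3, noise = 0.05)
    sheet <- purrr::map_dfr(seq_len(n), function(i) {
      base_probs <- setNames(rep(0.12, length(cols)), cols)
      base_probs[c("brown", "grey", "white", "black")] <- 0.25
      if (yellow_clade[i] == 1) base_probs["yellow"] <- 0.6
      cells <- purrr::map_dfr(parts, function(pt) {
        present <- rbinom(length(cols), 1, base_probs)
        if (sum(present) == 0) present[sample.int(length(cols), 1)] <- 1L
        tibble::tibble(part = pt, colour = cols, present = present)
      })
      dplyr::mutate(cells, species_id = sp[i], .before = 1)
    })
    cov <- colour_coverage(sheet)

    song_attr <- song_attractiveness(song_count, range_km2)
    lx_mass <- log(body_mass_g)
    lx_n <- log(n_for_sale)
    asr_yellow <- asin(sqrt(cov$colour_yellow[match(sp, cov$species_id)]))

    truth <- list(lambda = 0.9, sigma2 = 0.35,
                  beta = c(log_n_for_sale = -0.35, log_mass = 0.55,
                           status_alien = 0.6, song_attractiveness = -0.1,
                           asr_colour_yellow = 1.2),
                  intercept = 6,
                  strong_predictor = "log_n_for_sale")
    lp <- truth$intercept +
      truth$beta[["log_n_for_sale"]] * lx_n +
      truth$beta[["log_mass"]] * (lx_mass - mean(lx_mass)) +
      truth$beta[["status_alien"]] * (status == "alien") +
      truth$beta[["song_attractiveness"]] * song_attr +
      truth$beta[["asr_colour_yellow"]] * asr_yellow
    eps <- drop(crossprod(chol(truth$sigma2 *
                                 lambda_transform(V, truth$lambda)),
                          rnorm(n)))
    log_price <- lp + eps

    tab <- tibble::tibble(
      species_id = sp,
      family = paste0("fam", sprintf("%02d", 1 + (seq_len(n) - 1) %/% 12)),
      order = ifelse(seq_len(n) <= round(0.6 * n), "Passeriformes",
                     "Psittaciformes"),
      price_twd = exp(log_price),
      n_for_sale = n_for_sale, status = status, realm = realm, iucn = iucn,
      cites_listed = cites_listed, body_mass_g = body_mass_g,
      range_km2 = range_km2, song_count = song_count)
    tab <- dplyr::bind_cols(tab, cov[match(sp, cov$species_id),
                                     -1, drop = FALSE])
    list(table = as_trait_table(tab, source = "synthetic"),
         colour_sheet = sheet, truth = truth)
  })

  list(table = study$table, colour_sheet = study$colour_sheet,
       trees = trees,
       trees_univariate = trees[seq_len(n_trees_univariate)],
       trees_candidate = trees[n_trees_univariate + seq_len(n_trees_candidate)],
       truth = study$truth, seed = seed)
}
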