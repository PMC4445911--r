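# Shared fixtures and independent oracles for the test suite.

# A small, fully valid trait table built in code.
make_trait_tibble <- function(n = 8, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    species_id = sprintf("sp%03d", seq_len(n)),
    family = rep(c("famA", "famB"), length.out = n),
    order = rep(c("Passeriformes", "Psittaciformes"), length.out = n),
    price_twd = round(exp(stats::rnorm(n, 5, 1)), 1),
    n_for_sale = stats::rpois(n, 20) + 1L,
    status = rep(c("native", "alien"), length.out = n),
    realm = rep(c("Indo-Malay", "Neotropic", "Palearctic", "Australasia"),
                length.out = n),
    iucn = rep(c("LC", "LC", "NT", "VU"), length.out = n),
    cites_listed = rep(c(0L, 1L), length.out = n),
    body_mass_g = round(exp(stats::rnorm(n, 4, 1)), 1),
    range_km2 = round(exp(stats::rnorm(n, 13, 1))),
    song_count = stats::rpois(n, 10),
    colour_yellow = round(stats::runif(n), 2),
    colour_grey = round(stats::runif(n), 2)
  ))
}

write_trait_csv <- function(tab, path = withr::local_tempfile(
                              fileext = ".csv",
                              .local_envir = parent.frame())) {
  readr::write_csv(tab, path)
  path
}

# Independent VCV oracle: pairwise root-to-MRCA depths, one MRCA lookup per
# tip pair -- a different route from the production code.
vcv_oracle <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  m <- ape::mrca(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      V[i, j] <- if (i == j) depth[i] else depth[m[i, j]]
    }
  }
  V
}

# Closed-form OLS via the normal equations (dense inverse), used as the
# regression oracle.
ols_oracle <- function(y, X) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# Dense-inverse GLS oracle.
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  unname(drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)))
}

# Minimal stand-in for a fitted model, for exercising the ranking machinery
# with exactly controlled AICc values.
fake_fit <- function(loglik, K = 3, n = 217,
                     beta = c("(Intercept)" = 0), lambda = 0.9) {
  structure(list(beta = beta, loglik = loglik, K = K, n = n,
                 aicc = aicc(loglik, K, n), lambda = lambda,
                 r2 = NA_real_),
            class = "pgls_fit")
}

# A long-format colour sheet where `spec` maps colour -> number of parts on
# which it is present (painted onto the first parts). Any part left bare is
# topped up with "brown" so the every-part-coloured invariant holds.
make_colour_sheet <- function(spec, species_id = "spA") {
  parts <- body_part_names()
  cols <- colour_names()
  grid <- expand.grid(part = parts, colour = cols, stringsAsFactors = FALSE)
  grid$present <- 0L
  for (cl in names(spec)) {
    k <- spec[[cl]]
    if (k > 0) grid$present[grid$colour == cl &
                              grid$part %in% parts[seq_len(k)]] <- 1L
  }
  tot <- tapply(grid$present, grid$part, sum)
  bare <- names(tot)[tot == 0]
  grid$present[grid$part %in% bare & grid$colour == "brown"] <- 1L
  tibble::tibble(species_id = species_id, part = grid$part,
                 colour = grid$colour, present = grid$present)
}
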