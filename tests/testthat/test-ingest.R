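test_that("read_species_table validates schema and flags missing rows", {
  tab <- make_trait_tibble(3)
  path <- write_trait_csv(tab)
  got <- read_species_table(path)
  expect_s3_class(got, "trait_table")
  expect_equal(nrow(got), 3)
  expect_false(any(got$has_missing))

  # missing required column is a schema error naming the column
  path2 <- write_trait_csv(dplyr::select(tab, -"price_twd"))
  expect_error(read_species_table(path2), "price_twd")

  # non-numeric price reports the offending row
  bad <- tab
  bad$price_twd <- as.character(bad$price_twd)
  bad$price_twd[2] <- "expensive"
  path3 <- write_trait_csv(bad)
  expect_error(read_species_table(path3), "row: 2")

  # rows with missing predictor values are retained but flagged
  tab$body_mass_g[1] <- NA
  got2 <- as_trait_table(tab)
  expect_equal(nrow(got2), 3)
  expect_equal(got2$has_missing, c(TRUE, FALSE, FALSE))

  expect_error(as_trait_table(dplyr::mutate(tab, price_twd = -price_twd)),
               "positive")
})

test_that("apply_exclusions removes listed species and tolerates drift", {
  tab <- make_trait_tibble(221, seed = 7)
  out <- suppressMessages(apply_exclusions(tab, tab$species_id[1:4]))
  expect_equal(nrow(out), 217)

  expect_identical(suppressMessages(apply_exclusions(tab, character())), tab)

  expect_warning(out2 <- suppressMessages(
    apply_exclusions(tab, "not_a_species")), "not_a_species")
  expect_equal(nrow(out2), nrow(tab))
})

test_that("colour coverage is parts-present over 14, in [0, 1]", {
  sheet <- make_colour_sheet(list(yellow = 7, grey = 14, blue = 0))
  cov <- colour_coverage(sheet)
  expect_equal(cov$colour_yellow, 0.5)
  expect_equal(cov$colour_grey, 1)
  expect_equal(cov$colour_blue, 0)
  vals <- as.matrix(cov[-1])
  expect_true(all(vals >= 0 & vals <= 1))

  # malformed sheet: a species scoring fewer than 14 parts
  expect_error(colour_coverage(sheet[sheet$part != "bill", ]), "14")
  # a bare part is invalid
  bare <- sheet
  bare$present[bare$part == "legs"] <- 0L
  expect_error(colour_coverage(bare), "at least one colour")
})

test_that("colour diversity counts colours at or above 3% coverage", {
  cov <- c(0.5, 0.5, rep(0, 9))
  expect_equal(colour_diversity(cov), 2L)
  expect_equal(colour_diversity(c(0.02, rep(0, 10))), 0L)
  expect_equal(colour_diversity(c(0.03, rep(0, 10))), 1L)
  expect_equal(colour_diversity(rep(0.05, 11)), 11L)
  expect_error(colour_diversity(c(1.2, rep(0, 10))), "\\[0, 1\\]")

  # monotone non-decreasing in each coverage value
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- runif(11, 0, 0.2)
      j <- sample.int(11, 1)
      y <- x
      y[j] <- min(1, x[j] + runif(1))
      expect_gte(colour_diversity(y), colour_diversity(x))
    }
  })
})

test_that("song attractiveness residuals match the closed-form OLS oracle", {
  # two species lying exactly on a line -> residuals 0
  r2 <- song_attractiveness(c(exp(2) - 1, exp(3) - 1), c(exp(1), exp(2)))
  expect_equal(r2, c(0, 0), tolerance = 1e-12)

  withr::with_seed(5, {
    n <- 50
    range_km2 <- exp(rnorm(n, 13, 1.5))
    song <- round(exp(0.5 * log(range_km2) - 3 + rnorm(n, 0, 0.8)))
    got <- song_attractiveness(song, range_km2)
    X <- cbind(1, log(range_km2))
    yv <- log1p(song)
    beta <- ols_oracle(yv, X)
    expect_equal(got, yv - drop(X %*% beta), tolerance = 1e-9)
    expect_lt(abs(sum(got)), 1e-9)
    # species above the fitted line has a positive residual
    expect_gt(song_attractiveness(c(song, max(song) * 50),
                                  c(range_km2, range_km2[1]))[n + 1], 0)
  })

  expect_error(song_attractiveness(c(1, 2, 3), rep(10, 3)), "degenerate")
})

test_that("transforms use natural logs and arcsine-sqrt, and invert", {
  tab <- make_trait_tibble(6)
  tab$colour_yellow[1] <- 0.5
  tab$price_twd[1] <- 30
  out <- transform_predictors(tab)
  expect_equal(out$asr_colour_yellow[1], pi / 4)
  expect_equal(transform_predictors(
    dplyr::mutate(tab, colour_yellow = 0))$asr_colour_yellow,
    rep(0, 6))
  expect_equal(transform_predictors(
    dplyr::mutate(tab, colour_yellow = 1))$asr_colour_yellow,
    rep(pi / 2, 6))
  expect_equal(out$log_price[1], log(30))
  expect_equal(round(out$log_price[1], 4), 3.4012)

  # round-trip invertibility on the continuous transforms
  expect_equal(exp(out$log_price), tab$price_twd, tolerance = 1e-12)
  expect_equal(exp(out$log_mass), tab$body_mass_g, tolerance = 1e-12)
  expect_equal(sin(out$asr_colour_grey)^2, tab$colour_grey,
               tolerance = 1e-12)

  # categorical encodings
  expect_s3_class(out$status, "factor")
  expect_equal(levels(out$status)[1], "native")
  expect_equal(out$iucn_not_lc, as.integer(tab$iucn != "LC"))

  expect_error(transform_predictors(
    dplyr::mutate(tab, colour_yellow = 1.5)), "arcsine")
})

test_that("summary tallies reproduce totals, shares and USD conversion", {
  tab <- make_trait_tibble(12, seed = 3)
  tal <- summary_tallies(tab)
  expect_equal(tal$total_individuals, sum(tab$n_for_sale))
  expect_equal(tal$alien_individuals,
               sum(tab$n_for_sale[tab$status == "alien"]))
  expect_equal(tal$total_value_usd,
               sum(tab$price_twd * tab$n_for_sale) / 30)

  # invariant to row order
  tal2 <- summary_tallies(tab[sample(nrow(tab)), ])
  expect_equal(tal2$total_individuals, tal$total_individuals)
  expect_equal(tal2$top_share, tal$top_share)

  # single-species table: top-1 share is 100%
  expect_equal(summary_tallies(tab[1, ], top_k = 1)$top_share, 1)

  # USD conversion at 30 TWD/USD
  two <- make_trait_tibble(2)
  two$price_twd <- c(30, 240000)
  tal3 <- summary_tallies(two)
  expect_equal(tal3$min_price_usd, 1)
  expect_equal(tal3$max_price_usd, 8000)

  expect_error(summary_tallies(tab[0, ]), "empty")
})

test_that("the published top-ten market table yields the printed 80% share", {
  path <- system.file("extdata", "market_top_species.csv",
                      package = "birdmarket")
  top <- readr::read_csv(path, show_col_types = FALSE)
  tab <- make_trait_tibble(nrow(top))
  tab$species_id <- top$species_id
  tab$n_for_sale <- top$n_for_sale
  tab$price_twd <- top$price_usd * 30
  tab$status <- top$status
  tal <- summary_tallies(as_trait_table(tab), grand_total = 26165)
  expect_equal(round(100 * tal$top_share), 80)
})
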