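test_that("category mapping enforces its invariants and maps levels", {
  m <- category_mapping()
  expect_equal(category_to_count(1L, m), 10)
  expect_equal(category_to_count(3L, m), 100)
  expect_equal(category_to_count(0L, category_mapping(c(0, 1, 2, 3))), 0)
  expect_error(category_mapping(c(1, 10, 50, 100)), "level 0")
  expect_error(category_mapping(c(0, 50, 50, 100)), "strictly increasing")
})

test_that("host mean density averages mapped counts over included plates", {
  s18 <- load_fixture(2018)
  # saturated host: six plates all +++ for every species -> 100/25 = 4
  h24 <- host_mean_density(s18[s18$host_id == "CCR18-24", ], paper_mapping)
  expect_equal(h24, c(C_manati = 4, LT = 4, ST = 4))
  # hand arithmetic on the audited fixture: (0+10+0+0+50+50)/6/25 = 11/15
  h22 <- host_mean_density(s18[s18$host_id == "CCR18-22", ], paper_mapping)
  expect_equal(h22[["C_manati"]], 11 / 15)
  # all-absent plate
  zero <- as_scrape_survey(data.frame(
    host_id = "z", sample_label = "A", pass_index = 1L, is_resample = FALSE,
    species = c("a", "b"), category = "0", skin_remnants = "A"))
  expect_equal(host_mean_density(zero, paper_mapping),
               c(a = 0, b = 0))
  # empty after filtering
  only_res <- as_scrape_survey(data.frame(
    host_id = "z", sample_label = "A-2", pass_index = 2L, is_resample = TRUE,
    species = "a", category = "+", skin_remnants = "P"))
  expect_error(host_mean_density(only_res, paper_mapping, "nonsequential"),
               "no included samples")
})

test_that("population density is the unweighted mean of host means", {
  # two hosts, unequal plate counts, one species: (2 + 4) / 2 = 3
  df <- data.frame(
    host_id = c("h1", "h2", "h2", "h2", "h2", "h2"),
    sample_label = c("A", LETTERS[1:5]),
    pass_index = 1L, is_resample = FALSE, area_cm2 = 25,
    species = "spA",
    category = c("++", rep("+++", 5)),  # h1: 50/25 = 2; h2: 100/25 = 4
    skin_remnants = "A", stringsAsFactors = FALSE)
  est <- population_mean_density(df, paper_mapping)
  expect_equal(est$densities[["spA"]], 3)
  # degenerate case: one host, one plate == host mean
  one <- df[1, ]
  expect_equal(population_mean_density(one, paper_mapping)$densities,
               host_mean_density(one, paper_mapping))
})

test_that("two-stage estimator matches the brute-force oracle on random surveys", {
  set.seed(101)
  for (rep in 1:25) {
    df <- random_survey()
    include <- !df$is_resample
    oracle <- brute_force_two_stage(df, c(0, 10, 50, 100), include)
    est <- population_mean_density(df, paper_mapping, "nonsequential")
    expect_equal(est$densities[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("raising any single plate category never decreases a density", {
  set.seed(202)
  df <- random_survey()
  base <- population_mean_density(df, paper_mapping, "all")$densities
  lev <- match(df$category, c("0", "+", "++", "+++")) - 1
  raisable <- which(lev < 3)
  for (i in sample(raisable, min(10, length(raisable)))) {
    df2 <- df
    df2$category[i] <- c("0", "+", "++", "+++")[lev[i] + 2]
    up <- population_mean_density(df2, paper_mapping, "all")$densities
    expect_true(all(up >= base - 1e-15))
  }
})

test_that("scaling representative counts scales densities, not composition", {
  set.seed(303)
  df <- random_survey()
  e1 <- population_mean_density(df, category_mapping(c(0, 10, 50, 100)))
  e3 <- population_mean_density(df, category_mapping(3 * c(0, 10, 50, 100)))
  expect_equal(e3$densities, 3 * e1$densities)
  expect_equal(composition_fractions(e3), composition_fractions(e1))
})

test_that("composition fractions sum to one and flag the all-zero case", {
  set.seed(404)
  for (rep in 1:10) {
    d <- runif(3, 0, 5)
    f <- composition_fractions(d)
    expect_equal(sum(f), 1)
    expect_equal(f, d / sum(d))
  }
  expect_equal(unname(composition_fractions(c(1, 0, 0))), c(1, 0, 0))
  expect_error(composition_fractions(c(0, 0, 0)), "all densities are zero")
  # rounded reporting of the published 2018 composition
  expect_equal(round(100 * composition_fractions(
    c(2.2571, 3.1937, 2.7619))), c(27, 39, 34), ignore_attr = TRUE)
})

test_that("prevalence marks a species present from any positive plate", {
  prev18 <- prevalence_summary(load_fixture(2018))
  expect_equal(prev18$n_hosts, 7)
  expect_equal(prev18$n_hosts_all_species, 7)
  prev19 <- prevalence_summary(load_fixture(2019))
  expect_equal(prev19$positive_samples["CCR19-03", "ST"], 0,
               ignore_attr = TRUE)
  expect_false(prev19$presence["CCR19-03", "ST"])
  empty <- prevalence_summary(data.frame())
  expect_equal(empty$n_hosts, 0L)
})

test_that("depth yield forms per-host all-pass over first-pass count ratios", {
  dy <- depth_yield(load_fixture(2019), paper_mapping)
  per <- dy$per_host
  rownames(per) <- per$host_id
  expect_equal(per["CCR19-01", "multiplier"], 1100 / 300)
  # juvenile host with no sequential area contributes nothing
  expect_false("CCR19-03" %in% per$host_id)
  expect_true(all(per$multiplier[per$defined] >= 1))
  expect_equal(unname(dy$summary["min"]), 3.5)

  # saturated synthetic host: k passes all at the top level -> m = k
  k <- 5
  sat <- data.frame(
    host_id = "s", sample_label = c("A", paste0("A-", 1:(k - 1))),
    pass_index = 1:k, is_resample = c(FALSE, rep(TRUE, k - 1)),
    species = "spA", category = "+++", skin_remnants = "P",
    stringsAsFactors = FALSE)
  expect_equal(depth_yield(sat, paper_mapping)$per_host$multiplier, k)

  # zero first-pass total: flagged undefined, excluded from summary
  z <- sat
  z$category[1] <- "0"
  dz <- depth_yield(z, paper_mapping)
  expect_false(dz$per_host$defined)
  expect_true(is.na(dz$per_host$multiplier))
  expect_true(all(is.na(dz$summary)))

  expect_error(depth_yield(load_fixture(2018)[1:3, ]), "no sequentially")
})
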