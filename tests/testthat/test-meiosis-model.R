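# Exact enumeration and Monte Carlo simulation of segregation scenarios.

test_that("wild-type enumeration is deterministic: one chromatid of one homolog per pair per spermatid", {
  d <- as.data.frame(enumerate_meioses(scenario_wildtype()))
  expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  for (nm in c("XY", "chr2", "chr3", "chr4")) {
    h1 <- as.matrix(d[, sprintf("%s.1_s%d", nm, 1:4)])
    h2 <- as.matrix(d[, sprintf("%s.2_s%d", nm, 1:4)])
    # every spermatid holds exactly 1 chromatid of exactly one homolog
    expect_true(all(h1 + h2 == 1))
    expect_true(all(h1 * h2 == 0))
  }
})

test_that("X/Y univalents with regular sisters give 4 equiprobable outcomes", {
  d <- as.data.frame(enumerate_meioses(xy_only("regular_sisters")))
  expect_equal(nrow(d), 4L)
  expect_equal(d$probability, rep(0.25, 4))
})

test_that("exact FISH class probabilities match the elementary brute-force oracle", {
  for (rule in c("regular_sisters", "random_chromatids")) {
    oracle <- oracle_xy_classes(rule)
    cls <- fish_class_probabilities(xy_only(rule))
    expect_equal(cls$p_none, unname(oracle["none"]), tolerance = 1e-12)
    expect_equal(cls$p_red_only, unname(oracle["red_only"]), tolerance = 1e-12)
    expect_equal(cls$p_green_only, unname(oracle["green_only"]), tolerance = 1e-12)
    expect_equal(cls$p_both, unname(oracle["both"]), tolerance = 1e-12)
  }
  # frozen values from the oracle: (25, 15, 15, 9)/64 under random chromatids
  cls <- fish_class_probabilities(xy_only("random_chromatids"))
  expect_equal(cls$p_none, 25 / 64)
  expect_equal(cls$p_red_only, 15 / 64)
  expect_equal(cls$p_green_only, 15 / 64)
  expect_equal(cls$p_both, 9 / 64)
  # and all classes 1/4 under regular sisters
  cls <- fish_class_probabilities(xy_only("regular_sisters"))
  expect_equal(unlist(cls[c("p_none", "p_red_only", "p_green_only", "p_both")]),
               c(p_none = 0.25, p_red_only = 0.25, p_green_only = 0.25,
                 p_both = 0.25))
})

test_that("probed homologs on different pairs are handled via independence", {
  sc <- meiosis_scenario(list(
    chromosome_pair("a", conjunction = "univalent_pair", probe = c("red", "none")),
    chromosome_pair("b", conjunction = "univalent_pair", probe = c("green", "none"))
  ), mII_rule = "random_chromatids")
  cls <- fish_class_probabilities(sc)
  # P(specific homolog absent from a spermatid) = 5/8 per the oracle logic
  expect_equal(cls$p_none, 25 / 64, tolerance = 1e-12)
  expect_equal(cls$p_both, 9 / 64, tolerance = 1e-12)
})

test_that("0/RG and normal:abnormal ratios are exact, and undefined where the model says so", {
  expect_equal(zero_to_rg_ratio(scenario_xy_univalent("regular_sisters")), 1)
  expect_equal(zero_to_rg_ratio(scenario_xy_univalent("random_chromatids")),
               25 / 9, tolerance = 1e-12)
  expect_equal(normal_to_abnormal_ratio(scenario_xy_univalent("regular_sisters")), 1)
  expect_equal(normal_to_abnormal_ratio(scenario_xy_univalent("random_chromatids")),
               15 / 17, tolerance = 1e-12)
  expect_error(zero_to_rg_ratio(scenario_wildtype()),
               class = "meioconj_undefined_ratio")
  expect_error(normal_to_abnormal_ratio(scenario_wildtype()),
               class = "meioconj_undefined_ratio")
})

test_that("pattern distribution matches brute force and the folded binomial closed form", {
  # 4 univalent pairs = 8 independent units, enumerated over all 2^8 assignments
  pd <- pattern_distribution(scenario_uno_null())
  expect_equal(pd$pattern, c("4:4", "5:3", "6:2", "7:1", "8:0"))
  expect_equal(pd$probability, oracle_unit_patterns(8), tolerance = 1e-12)
  expect_equal(pd$probability, c(70, 112, 56, 16, 2) / 256, tolerance = 1e-12)
  # closed form: Binomial(n, 1/2) folded at n/2, for several unit counts
  for (k in 1:3) {
    sc <- meiosis_scenario(lapply(seq_len(k), function(i) {
      chromosome_pair(paste0("u", i), conjunction = "univalent_pair")
    }), mII_rule = "regular_sisters")
    n <- 2L * k
    pd <- pattern_distribution(sc)
    a <- seq.int(ceiling(n / 2), n)
    folded <- stats::dbinom(a, n, 0.5) +
      ifelse(a != n - a, stats::dbinom(n - a, n, 0.5), 0)
    expect_equal(pd$probability, folded, tolerance = 1e-12)
  }
  # forced splitting: all bivalents
  pd <- pattern_distribution(scenario_wildtype())
  expect_equal(pd$probability[pd$pattern == "4:4"], 1)
  expect_equal(sum(pd$probability), 1)
  # 3 bivalents + 1 univalent pair: only 4:4 and 5:3, equally likely
  pd <- pattern_distribution(scenario_xy_univalent())
  expect_equal(pd$probability,
               c(0.5, 0.5, 0, 0, 0))
})

test_that("outcome distributions sum to one and conserve 4 chromatids per pair on random scenarios", {
  set.seed(20260924)
  for (rep in 1:25) {
    sc <- random_scenario()
    d <- as.data.frame(enumerate_meioses(sc))
    expect_equal(sum(d$probability), 1, tolerance = 1e-12)
    for (p in sc$chromosomes) {
      tot <- rowSums(d[, grep(sprintf("^%s\\.", p$name), names(d)), drop = FALSE])
      expect_true(all(tot == 4))
    }
    # pole-relabeling symmetry when red/green homologs share symmetric specs
    cls <- fish_class_probabilities(sc)
    expect_equal(cls$p_red_only, cls$p_green_only, tolerance = 1e-12)
  }
})

test_that("Monte Carlo frequencies agree with enumeration within 4 standard errors", {
  n <- 1e5
  for (rule in c("regular_sisters", "random_chromatids")) {
    sc <- scenario_xy_univalent(rule)
    exact <- fish_class_probabilities(sc)
    sim <- simulate_meioses(sc, n_meioses = n, seed = 101)
    fc <- fish_counts(sim)
    emp <- table(factor(as.character(classify_nucleus(fc[, "red"], fc[, "green"])),
                        levels = c("none", "red_only", "green_only", "both"))) /
      nrow(fc)
    for (cl in c("none", "red_only", "green_only", "both")) {
      p <- exact[[paste0("p_", cl)]]
      se <- sqrt(p * (1 - p) / (4 * n))
      expect_lt(abs(emp[[cl]] - p), max(4 * se, 1e-12))
    }
  }
})

test_that("simulation is reproducible and leaves the caller's RNG untouched", {
  sc <- scenario_uno_null("random_chromatids")
  set.seed(1); before <- runif(1)
  set.seed(1)
  s1 <- simulate_meioses(sc, 500, seed = 7)
  after <- runif(1)
  expect_identical(before, after)  # caller RNG stream not consumed
  s2 <- simulate_meioses(sc, 500, seed = 7)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_meioses(sc, 500, seed = 8)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("simulate() method requires an explicit seed", {
  expect_error(simulate(scenario_wildtype(), nsim = 10),
               class = "meioconj_invalid_input")
  s <- simulate(scenario_wildtype(), nsim = 10, seed = 3)
  expect_s3_class(s, "meiosis_sample")
})

test_that("DNA content variability: zero for regular scenarios, sqrt(2)/4 for 8 unit-content univalents", {
  v <- dna_content_distribution(scenario_wildtype(), n_cysts = 5, seed = 2)
  expect_equal(unclass(v)[1:5], rep(0, 5))
  un <- meiosis_scenario(lapply(1:4, function(i) {
    chromosome_pair(paste0("u", i), dna_content = 1,
                    conjunction = "univalent_pair",
                    probe = if (i == 1) c("red", "green") else "none")
  }), mII_rule = "regular_sisters")
  v <- dna_content_distribution(un, spermatids_per_cyst = 64, n_cysts = 150,
                                seed = 5)
  # spermatid content ~ Binomial(8, 1/2): cv = sqrt(2)/4
  expect_equal(mean(v), sqrt(2) / 4, tolerance = 0.05)
  v2 <- dna_content_distribution(un, spermatids_per_cyst = 64, n_cysts = 150,
                                 seed = 5)
  expect_identical(as.numeric(v), as.numeric(v2))
})

test_that("scenario validation enforces the model invariants", {
  expect_error(chromosome_pair("x", dna_content = 0), class = "meioconj_invalid_scenario")
  expect_error(chromosome_pair("x", probe = c("red", "red")),
               class = "meioconj_invalid_scenario")
  expect_error(meiosis_scenario(lapply(1:9, function(i) chromosome_pair(paste0("c", i)))),
               class = "meioconj_size_limit")
  expect_error(
    meiosis_scenario(list(chromosome_pair("a", probe = "red"),
                          chromosome_pair("b", probe = "red"))),
    class = "meioconj_invalid_scenario")
  expect_error(fish_class_probabilities(meiosis_scenario(list(chromosome_pair("a")))),
               class = "meioconj_missing_probe")
})
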