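# Classification and aggregation of per-nucleus FISH signal counts.

test_that("nucleus classification follows the presence-based scoring rules", {
  expect_equal(as.character(classify_nucleus(0, 0)), "none")
  expect_equal(as.character(classify_nucleus(1, 0)), "red_only")
  expect_equal(as.character(classify_nucleus(0, 1)), "green_only")
  expect_equal(as.character(classify_nucleus(1, 1)), "both")
  # two same-color signals without the other color cannot be scored reliably
  expect_equal(as.character(classify_nucleus(2, 0)), "unscored_multisignal")
  expect_equal(as.character(classify_nucleus(0, 3)), "unscored_multisignal")
  # presence-based 'both': extra same-color signals do not change the class
  expect_equal(as.character(classify_nucleus(2, 1)), "both")
  expect_equal(as.character(classify_nucleus(1, 2)), "both")
  expect_error(classify_nucleus(-1, 0), class = "meioconj_invalid_input")
  expect_error(classify_nucleus(0.5, 0), class = "meioconj_invalid_input")
})

make_cyst <- function(n_none, n_red, n_green, n_both, n_multi = 0, id = "c1") {
  total <- n_none + n_red + n_green + n_both + n_multi
  data.frame(
    cyst_id = rep(id, total),
    nucleus_id = sprintf("n%d", seq_len(total)),
    red_count = c(rep(0, n_none), rep(1, n_red), rep(0, n_green),
                  rep(1, n_both), rep(2, n_multi)),
    green_count = c(rep(0, n_none), rep(0, n_red), rep(1, n_green),
                    rep(1, n_both), rep(0, n_multi))
  )
}

test_that("cyst summaries count classes and compute the per-cyst 0/RG", {
  # wild-type pattern: no abnormal nuclei, ratio undefined
  s <- summarize_cyst(make_cyst(0, 8, 8, 0))
  expect_equal(s$n_scored, 16L)
  expect_equal(s$abnormal_fraction, 0)
  expect_true(is.na(s$zero_to_rg))
  # 4 nuclei per class
  s <- summarize_cyst(make_cyst(4, 4, 4, 4))
  expect_equal(s$abnormal_fraction, 0.5)
  expect_equal(s$zero_to_rg, 1)
  # expectation of the random-chromatid model over 64 nuclei
  s <- summarize_cyst(make_cyst(25, 15, 15, 9))
  expect_equal(s$zero_to_rg, 25 / 9, tolerance = 1e-12)
  expect_equal(s$f_none + s$f_red_only + s$f_green_only + s$f_both, 1,
               tolerance = 1e-12)
  # multisignal nuclei are excluded from fractions but counted
  s <- summarize_cyst(make_cyst(4, 4, 4, 4, n_multi = 4))
  expect_equal(s$n_scored, 16L)
  expect_equal(s$n_unscored_multisignal, 4L)
  expect_equal(s$abnormal_fraction, 0.5)
  expect_error(summarize_cyst(make_cyst(0, 0, 0, 0)),
               class = "meioconj_invalid_input")
})

test_that("genotype aggregation uses sample s.d. and excludes undefined ratios", {
  cysts <- rbind(make_cyst(4, 4, 4, 4, id = "a"),
                 make_cyst(4, 4, 4, 4, id = "b"),
                 make_cyst(4, 4, 4, 4, id = "c"))
  agg <- aggregate_genotype(summarize_fish_table(cysts))
  expect_equal(agg$zero_to_rg$mean, 1)
  expect_equal(agg$zero_to_rg$sd, 0)
  # cysts with ratios 0.5 and 1.5: mean 1, sample s.d. 1/sqrt(2)
  cysts <- rbind(make_cyst(2, 6, 6, 4, id = "a"),   # 2/4 = 0.5
                 make_cyst(6, 4, 4, 4, id = "b"))   # 6/4 = 1.5
  agg <- aggregate_genotype(summarize_fish_table(cysts))
  expect_equal(agg$zero_to_rg$mean, 1)
  expect_equal(agg$zero_to_rg$sd, sqrt(0.5), tolerance = 1e-12)
  # undefined cysts excluded and reported
  cysts <- rbind(make_cyst(4, 4, 4, 4, id = "a"),
                 make_cyst(4, 4, 4, 4, id = "b"),
                 make_cyst(0, 8, 8, 0, id = "c"))
  agg <- aggregate_genotype(summarize_fish_table(cysts))
  expect_equal(agg$zero_to_rg$n, 2L)
  expect_equal(agg$n_cysts_undefined_ratio, 1L)
  expect_equal(agg$abnormal_fraction$n, 3L)
  # all undefined: aggregate impossible
  cysts <- rbind(make_cyst(0, 8, 8, 0, id = "a"),
                 make_cyst(0, 8, 8, 0, id = "b"))
  expect_error(aggregate_genotype(summarize_fish_table(cysts)),
               class = "meioconj_aggregate_undefined")
})

test_that("class fractions are invariant under nucleus order and cyst partitioning", {
  tab <- gen_fish_table(scenario_xy_univalent("random_chromatids"),
                        n_cysts = 4, nuclei_per_cyst = 100, seed = 31)
  pooled <- tab
  pooled$cyst_id <- "all"
  s_pooled <- summarize_cyst(pooled)
  shuffled <- pooled[sample(nrow(pooled)), ]
  expect_equal(summarize_cyst(shuffled)[, -1], s_pooled[, -1])
  # pooled class counts equal the weighted combination of per-cyst fractions
  per <- summarize_fish_table(tab)
  for (f in c("f_none", "f_red_only", "f_green_only", "f_both")) {
    expect_equal(sum(per[[f]] * per$n_scored) / sum(per$n_scored),
                 s_pooled[[f]], tolerance = 1e-12)
  }
})

test_that("generated tables scored end to end recover scenario class probabilities", {
  sc <- scenario_xy_univalent("random_chromatids")
  exact <- fish_class_probabilities(sc)
  n_total <- 1e4
  tab <- gen_fish_table(sc, n_cysts = 1, nuclei_per_cyst = n_total, seed = 77)
  s <- summarize_cyst(tab)
  for (cl in c("none", "red_only", "green_only", "both")) {
    p <- exact[[paste0("p_", cl)]]
    se <- sqrt(p * (1 - p) / n_total)
    expect_lt(abs(s[[paste0("f_", cl)]] - p), 4 * se)
  }
  # 13 cysts of 200 nuclei under random-MI/regular-MII: 0/RG aggregates near 1
  tab <- gen_fish_table(scenario_xy_univalent("regular_sisters"),
                        n_cysts = 13, nuclei_per_cyst = 200, seed = 13)
  agg <- aggregate_genotype(summarize_fish_table(tab))
  se <- max(agg$zero_to_rg$sd / sqrt(agg$zero_to_rg$n), 0.05)
  expect_lt(abs(agg$zero_to_rg$mean - 1), 3 * se)
})
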