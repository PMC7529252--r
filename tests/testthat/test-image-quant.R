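# Nucleus segmentation, particle filtering, QC, cyst variability and trace
# normalization, validated against generator ground truth.

test_that("noise-free disks are segmented with exact intensities and accurate areas", {
  set.seed(1)
  contents <- runif(12, 5, 10)
  syn <- gen_cyst_image(n_nuclei = 12, contents = contents, seed = 21)
  seg <- segment_nuclei(syn$image, quant_config())
  expect_equal(nrow(seg$retained), 12L)
  true_area <- pi * 1.5^2
  expect_true(all(abs(seg$retained$area_um2 - true_area) / true_area <= 0.10))
  expect_equal(sort(seg$retained$integrated_intensity), sort(contents),
               tolerance = 1e-9)
  expect_true(all(seg$retained$circularity >= 0.9))
})

test_that("constant images yield no objects, with a warning", {
  expect_warning(seg <- segment_nuclei(matrix(3, 80, 80), quant_config()),
                 "dynamic range")
  expect_equal(nrow(seg$measurements), 0L)
  expect_error(segment_nuclei(matrix(1, 10, 10), quant_config(),
                              roi = matrix(FALSE, 10, 10)),
               class = "meioconj_invalid_input")
})

test_that("watershed splits touching nuclei", {
  syn <- gen_cyst_image(n_nuclei = 12, touching_fraction = 1 / 6, seed = 4)
  seg <- segment_nuclei(syn$image, quant_config())
  expect_equal(nrow(seg$retained), 12L)
})

test_that("stacks are max-projected before segmentation", {
  syn <- gen_cyst_image(n_nuclei = 6, seed = 9)
  stack <- array(0, dim = c(dim(syn$image), 3))
  stack[, , 2] <- syn$image
  seg <- segment_nuclei(stack, quant_config())
  expect_equal(nrow(seg$retained), 6L)
})

test_that("the exclusion mask removes labels, as manual cyst-cell deletion would", {
  syn <- gen_cyst_image(n_nuclei = 6, seed = 9)
  excl <- matrix(FALSE, nrow(syn$image), ncol(syn$image))
  one <- syn$truth[1, ]
  excl[round(one$x), round(one$y)] <- TRUE
  seg <- segment_nuclei(syn$image, quant_config(), exclusion = excl)
  expect_equal(nrow(seg$retained), 5L)
})

test_that("particle filter applies inclusive area and circularity bounds", {
  m <- data.frame(
    label = 1:5,
    area_um2 = c(10, 30, 10, 1, 25),       # 30 exceeds the 25 um^2 bound
    circularity = c(0.95, 0.95, 0.5, 0.70, 1.00),  # 0.5 below the 0.70 bound
    integrated_intensity = 1
  )
  keep <- particle_filter(m, quant_config())
  expect_equal(keep$label, c(1L, 4L, 5L))
})

test_that("QC discards images missing more than 10% of expected nuclei", {
  expect_true(qc_check(64, 64)$pass)
  expect_true(qc_check(64, 60)$pass)       # 6.25% missed
  expect_false(qc_check(64, 56)$pass)      # 12.5% missed
  expect_equal(qc_check(64, 56)$missed_fraction, 0.125)
  expect_error(qc_check(0, 10), class = "meioconj_invalid_input")
})

test_that("cyst variability normalizes to mean 1 and is scale invariant", {
  cv <- cyst_variability(c(1, 3))
  expect_equal(cv$normalized_contents, c(0.5, 1.5))
  expect_equal(cv$sd_normalized, sqrt(0.5), tolerance = 1e-12)
  expect_equal(cyst_variability(rep(4, 10))$sd_normalized, 0)
  x <- runif(20, 1, 5)
  expect_equal(cyst_variability(x * 1000)$sd_normalized,
               cyst_variability(x)$sd_normalized, tolerance = 1e-12)
  expect_equal(mean(cyst_variability(x)$normalized_contents), 1,
               tolerance = 1e-9)
  expect_error(cyst_variability(5), class = "meioconj_invalid_input")
  expect_error(cyst_variability(c(0, 0)), class = "meioconj_degenerate_input")
})

test_that("adding a nucleus at the cyst mean never increases the variability statistic", {
  set.seed(77)
  for (i in 1:20) {
    x <- runif(sample(5:30, 1), 0.5, 3)
    before <- cyst_variability(x)$sd_normalized
    after <- cyst_variability(c(x, mean(x)))$sd_normalized
    expect_lte(after, before + 1e-12)
  }
})

test_that("cyst images from the binomial univalent model recover sqrt(2)/4 variability", {
  un <- meiosis_scenario(lapply(1:4, function(i) {
    chromosome_pair(paste0("u", i), conjunction = "univalent_pair")
  }), mII_rule = "regular_sisters")
  # contents span 0-8 chromatid equivalents; keep every foreign disk
  # outside the 15 px local-mean window so dim nuclei are not eroded by
  # bright neighbours (centers >= window radius + 2 disk radii)
  sds <- vapply(1:4, function(i) {
    syn <- gen_cyst_image(n_nuclei = 64, scenario = un,
                          min_separation_um = 5.6, seed = 100 + i)
    seg <- segment_nuclei(syn$image, quant_config())
    # zero-content nuclei are dark and undetectable: pad the measured
    # intensities back to cyst size with zeros
    measured <- seg$retained$integrated_intensity
    truth_nonzero <- syn$truth$content[syn$truth$content > 0]
    expect_equal(sort(measured), sort(truth_nonzero), tolerance = 1e-9)
    cyst_variability(c(measured, rep(0, 64 - length(measured))))$sd_normalized
  }, numeric(1))
  expect_equal(mean(sds), sqrt(2) / 4, tolerance = 0.1)
})

test_that("wild-type images show lower DNA-content variability than univalent images", {
  n_cysts <- 10
  sd_of <- function(scenario, seed0) {
    vapply(seq_len(n_cysts), function(i) {
      syn <- gen_cyst_image(n_nuclei = 16, scenario = scenario,
                            noise_sigma = 0.02, seed = seed0 + i)
      seg <- segment_nuclei(syn$image, quant_config())
      cyst_variability(seg$retained)$sd_normalized
    }, numeric(1))
  }
  wt <- sd_of(scenario_wildtype(), 200)
  mut <- sd_of(scenario_uno_null("random_chromatids"), 300)
  expect_lt(mean(wt), mean(mut))
})

test_that("trace normalization sets the top-ten mean to 100 a.u.", {
  nt <- normalize_trace(1:20, rep(7, 20))
  expect_equal(nt$intensity_au, rep(100, 20))
  # plateau of 12 points at 50 then decay: top-10 mean is 50, plateau -> 100
  tr <- gen_intensity_trace(n_points = 30, plateau = 50, decay_start = 12,
                            decay_duration = 9, seed = 1)
  nt <- normalize_trace(tr$time, tr$intensity)
  expect_equal(max(nt$intensity_au), 100)
  expect_equal(sort(nt$intensity_au, decreasing = TRUE)[1:10], rep(100, 10))
  # scale invariance
  nt2 <- normalize_trace(tr$time, tr$intensity * 3.7)
  expect_equal(nt2$intensity_au, nt$intensity_au, tolerance = 1e-12)
  # alignment frame becomes t = 0
  nt3 <- normalize_trace(tr$time, tr$intensity, nebd_index = 5)
  expect_equal(nt3$time[5], 0)
  expect_error(normalize_trace(1:9, 1:9), class = "meioconj_invalid_input")
  expect_error(normalize_trace(c(1:10, 10), c(1:10, 10)),
               class = "meioconj_invalid_input")
  expect_error(normalize_trace(1:10, rep(0, 10)),
               class = "meioconj_degenerate_input")
})
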