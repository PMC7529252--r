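# Monte Carlo simulation of meioses: the stochastic twin of the enumerator.
# Sampling is vectorized over meioses; loops run only over homologs (<= 16).

#' Simulate complete meioses under a segregation scenario
#'
#' Draws `n_meioses` independent meioses and records, for every homolog of
#' every chromosome pair, the chromatid count each of the four spermatids
#' receives. Spermatids 1,2 descend from meiosis I pole 1 and spermatids 3,4
#' from pole 2. Reproducible for a fixed seed; empirical frequencies converge
#' to the exact law of [enumerate_meioses()].
#'
#' @param scenario A [meiosis_scenario()].
#' @param n_meioses Number of meioses to draw (>= 1).
#' @param seed Integer seed; every source of randomness in the call is
#'   governed by it and the caller's RNG state is left untouched.
#' @return An object of class `meiosis_sample`: a list with `counts`, an
#'   integer array of dimension `n_meioses x n_homologs x 4` (chromatid
#'   counts; homolog order as in the scenario, two rows per pair), the
#'   `scenario`, the `homologs` table and the `seed`.
#' @examples
#' sim <- simulate_meioses(scenario_xy_univalent("random_chromatids"),
#'                         n_meioses = 1000, seed = 1)
#' colMeans(fish_counts(sim) >= 1)
#' @export
simulate_meioses <- function(scenario, n_meioses, seed) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  if (!is_count(n_meioses)) {
    stop_meioconj("`n_meioses` must be a positive integer",
                  "meioconj_invalid_input")
  }
  n <- as.integer(n_meioses)
  ht <- homolog_table(scenario)
  nh <- nrow(ht)
  counts <- array(0L, dim = c(n, nh, 4L))
  with_seed(seed, {
    for (e in seq_along(scenario$chromosomes)) {
      pair <- scenario$chromosomes[[e]]
      rows <- which(ht$entry == e)
      # meiosis I: pole of each homolog (1 or 2)
      if (pair$conjunction == "bivalent") {
        o <- sample.int(2L, n, replace = TRUE)
        poles <- cbind(o, 3L - o)
      } else {
        poles <- cbind(sample.int(2L, n, replace = TRUE),
                       sample.int(2L, n, replace = TRUE))
      }
      # meiosis II within each pole (spermatids 2p-1, 2p)
      for (h in 1:2) {
        first <- 2L * poles[, h] - 1L
        if (scenario$mII_rule == "regular_sisters") {
          k <- rep.int(1L, n)
        } else {
          k <- stats::rbinom(n, 2L, 0.5)
        }
        i <- seq_len(n)
        counts[cbind(i, rows[h], first)] <- k
        counts[cbind(i, rows[h], first + 1L)] <- 2L - k
      }
    }
  })
  structure(
    list(counts = counts, scenario = scenario, homologs = ht,
         seed = as.integer(seed)),
    class = "meiosis_sample"
  )
}

#' @export
print.meiosis_sample <- function(x, ...) {
  cat(sprintf("Simulated meioses: %d tetrads under scenario '%s' (seed %d)\n",
              dim(x$counts)[1], x$scenario$name, x$seed))
  invisible(x)
}

#' @rdname simulate_meioses
#' @param object A [meiosis_scenario()].
#' @param nsim Number of meioses (alias of `n_meioses`).
#' @param ... Unused.
#' @export
simulate.meiosis_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) {
    stop_meioconj("`seed` is required: all stochastic results must be pinned",
                  "meioconj_invalid_input")
  }
  simulate_meioses(object, n_meioses = nsim, seed = seed)
}

#' Per-spermatid FISH signal counts of a simulated sample
#'
#' Converts simulated chromatid counts into red/green signal counts per
#' spermatid nucleus. With `chromatid_resolved = FALSE` (the default,
#' matching FISH scoring practice) presence of >= 1 chromatid of a probed
#' chromosome yields one signal; with `TRUE` the signal count equals the
#' chromatid count, so 2-chromatid nuclei show two same-color signals.
#'
#' @param sample A `meiosis_sample` from [simulate_meioses()].
#' @param chromatid_resolved Report one signal per chromatid instead of per
#'   present chromosome.
#' @return Integer matrix with `4 * n_meioses` rows (spermatids, meiosis by
#'   meiosis) and columns `red`, `green`.
#' @export
fish_counts <- function(sample, chromatid_resolved = FALSE) {
  stopifnot(inherits(sample, "meiosis_sample"))
  ht <- sample$homologs
  red <- which(ht$probe == "red")
  green <- which(ht$probe == "green")
  if (length(red) != 1L || length(green) != 1L) {
    stop_meioconj("sample's scenario lacks a red- and green-probed homolog",
                  "meioconj_missing_probe")
  }
  # rows: meiosis 1 spermatids 1..4, meiosis 2 spermatids 1..4, ...
  r <- t(sample$counts[, red, , drop = TRUE])
  g <- t(sample$counts[, green, , drop = TRUE])
  if (is.null(dim(r))) { r <- matrix(r, nrow = 4L); g <- matrix(g, nrow = 4L) }
  out <- cbind(red = as.integer(r), green = as.integer(g))
  if (!chromatid_resolved) out <- pmin(out, 1L)
  out
}

#' Per-spermatid DNA contents of a simulated sample
#'
#' @param sample A `meiosis_sample`.
#' @return Numeric matrix `n_meioses x 4`: total DNA content of each
#'   spermatid (sum over homologs of chromatid count times per-chromatid
#'   content).
#' @export
spermatid_contents <- function(sample) {
  stopifnot(inherits(sample, "meiosis_sample"))
  w <- sample$homologs$dna_content
  out <- matrix(0, dim(sample$counts)[1], 4L)
  for (s in 1:4) out[, s] <- sample$counts[, , s, drop = TRUE] %*% w
  out
}

#' Per-cyst DNA content variability under a scenario
#'
#' Simulates spermatid cysts (each pooling the four spermatids of
#' `spermatids_per_cyst / 4` meioses — 64 spermatids from 16 spermatocytes in
#' the fly), normalizes each nucleus content by its cyst mean, and returns
#' the standard deviation of the normalized values per cyst — the DNA-content
#' variability statistic. Under regular segregation all nuclei are identical
#' and the statistic is 0; under genome-wide univalent segregation with unit
#' contents the spermatid content is Binomial(8, 1/2) and the statistic
#' converges to sqrt(2)/4.
#'
#' @param scenario A [meiosis_scenario()].
#' @param spermatids_per_cyst Cyst size, a positive multiple of 4
#'   (default 64).
#' @param n_cysts Number of cysts to simulate.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_cysts`: the per-cyst s.d. of
#'   cyst-mean-normalized DNA contents (sample s.d., n - 1 denominator).
#' @section Errors: a cyst whose mean content is 0 (possible only when some
#'   spermatid content can be 0 and all draws hit it) raises a
#'   degenerate-input error rather than dividing by zero.
#' @examples
#' sd64 <- dna_content_distribution(scenario_uno_null(), n_cysts = 5, seed = 1)
#' mean(sd64)
#' @export
dna_content_distribution <- function(scenario, spermatids_per_cyst = 64,
                                     n_cysts, seed) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  if (!is_count(spermatids_per_cyst) || spermatids_per_cyst %% 4 != 0) {
    stop_meioconj("`spermatids_per_cyst` must be a positive multiple of 4 (cysts pool complete meioses)",
                  "meioconj_invalid_input")
  }
  if (!is_count(n_cysts)) {
    stop_meioconj("`n_cysts` must be a positive integer", "meioconj_invalid_input")
  }
  m <- as.integer(spermatids_per_cyst) %/% 4L
  sim <- simulate_meioses(scenario, n_meioses = m * n_cysts, seed = seed)
  contents <- spermatid_contents(sim)
  out <- numeric(n_cysts)
  for (i in seq_len(n_cysts)) {
    v <- as.numeric(t(contents[((i - 1L) * m + 1L):(i * m), , drop = FALSE]))
    mu <- mean(v)
    if (mu == 0) {
      stop_meioconj("cyst mean DNA content is 0; normalization undefined",
                    "meioconj_degenerate_input")
    }
    out[i] <- stats::sd(v / mu)
  }
  attr(out, "spermatids_per_cyst") <- as.integer(spermatids_per_cyst)
  attr(out, "seed") <- as.integer(seed)
  out
}
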