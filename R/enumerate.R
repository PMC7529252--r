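# Exact enumeration of meiosis I/II chromosome transmission.
#
# Homolog pairs are probabilistically independent of each other: every random
# choice (univalent pole at M I, chromatid fate at M II) involves one pair
# only, and the four spermatid slots are fixed (pole 1 -> spermatids 1,2;
# pole 2 -> spermatids 3,4). The exact tetrad law therefore factorizes over
# entries; we enumerate one tetrad marginal per pair and keep the product
# form, materializing the full support only on request.

# Tetrad marginal of one homolog pair: all distinct 2 x 4 chromatid-count
# matrices (rows = homologs, cols = spermatids) with exact probabilities.
entry_marginal <- function(pair, mII_rule) {
  # M I pole assignments: pole[h] in {1, 2} for homolog h
  mI <- if (pair$conjunction == "bivalent") {
    list(list(p = 0.5, pole = c(1L, 2L)), list(p = 0.5, pole = c(2L, 1L)))
  } else {
    out <- list()
    for (p1 in 1:2) for (p2 in 1:2) {
      out[[length(out) + 1L]] <- list(p = 0.25, pole = c(p1, p2))
    }
    out
  }
  acc <- new.env(parent = emptyenv())
  add_outcome <- function(counts, prob) {
    key <- paste(counts, collapse = ",")
    cur <- acc[[key]]
    if (is.null(cur)) acc[[key]] <- list(counts = counts, prob = prob)
    else acc[[key]]$prob <- cur$prob + prob
  }
  spermatids_of <- list(`1` = c(1L, 2L), `2` = c(3L, 4L))
  for (a in mI) {
    if (mII_rule == "regular_sisters") {
      counts <- matrix(0L, 2L, 4L)
      for (h in 1:2) counts[h, spermatids_of[[a$pole[h]]]] <- 1L
      add_outcome(counts, a$p)
    } else {
      # each homolog's 2 chromatids flip independently: k of them to the
      # first spermatid of the pole, k ~ Binomial(2, 1/2)
      for (k1 in 0:2) for (k2 in 0:2) {
        counts <- matrix(0L, 2L, 4L)
        ks <- c(k1, k2)
        for (h in 1:2) {
          sp <- spermatids_of[[a$pole[h]]]
          counts[h, sp[1]] <- ks[h]
          counts[h, sp[2]] <- 2L - ks[h]
        }
        p2 <- prod(choose(2, ks)) / 16
        add_outcome(counts, a$p * p2)
      }
    }
  }
  outs <- as.list(acc)
  list(
    counts = lapply(outs, `[[`, "counts"),
    prob = vapply(outs, `[[`, numeric(1), "prob")
  )
}

#' Exhaustively enumerate the outcomes of one meiosis
#'
#' Computes the exact probability law over tetrad outcomes — the chromatid
#' count (0, 1 or 2 per homolog) of every chromosome in each of the four
#' spermatids of one meiosis — under the scenario's conjunction states and
#' meiosis II rule. Every independent binary choice (univalent pole at
#' meiosis I, chromatid fate at meiosis II under `random_chromatids`) carries
#' equal elementary probability; the computation is deterministic and exact.
#'
#' Homolog pairs behave independently, so the law is stored in factorized
#' form (one tetrad marginal per pair). `as.data.frame()` materializes the
#' full joint support (one row per outcome, probability first), which is
#' refused above 200 000 outcomes.
#'
#' @param scenario A [meiosis_scenario()].
#' @return An object of class `outcome_distribution`.
#' @examples
#' od <- enumerate_meioses(scenario_xy_univalent())
#' head(as.data.frame(od))
#' @export
enumerate_meioses <- function(scenario) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  marginals <- lapply(scenario$chromosomes, entry_marginal,
                      mII_rule = scenario$mII_rule)
  names(marginals) <- vapply(scenario$chromosomes, `[[`, character(1), "name")
  structure(
    list(scenario = scenario, marginals = marginals),
    class = "outcome_distribution"
  )
}

#' @export
print.outcome_distribution <- function(x, ...) {
  sizes <- vapply(x$marginals, function(m) length(m$prob), integer(1))
  cat(sprintf("Exact tetrad outcome distribution for scenario '%s'\n",
              x$scenario$name))
  cat(sprintf("  factorized over %d homolog pair(s); per-pair support sizes: %s\n",
              length(sizes), paste(sizes, collapse = ", ")))
  cat(sprintf("  joint support size: %s\n",
              format(prod(sizes), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.outcome_distribution <- function(x, ...,
                                               max_outcomes = 2e5) {
  sizes <- vapply(x$marginals, function(m) length(m$prob), integer(1))
  total <- prod(sizes)
  if (total > max_outcomes) {
    stop_meioconj(
      sprintf("joint support has %s outcomes (> %s); work with the factorized object or raise `max_outcomes`",
              format(total, big.mark = ","), format(max_outcomes, big.mark = ",")),
      "meioconj_size_limit"
    )
  }
  idx <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  prob <- rep(1, nrow(idx))
  cols <- list()
  for (e in seq_along(x$marginals)) {
    m <- x$marginals[[e]]
    prob <- prob * m$prob[idx[[e]]]
    arr <- array(unlist(m$counts), dim = c(2L, 4L, length(m$prob)))
    for (h in 1:2) for (s in 1:4) {
      cols[[sprintf("%s.%d_s%d", names(x$marginals)[e], h, s)]] <-
        arr[h, s, idx[[e]]]
    }
  }
  out <- data.frame(probability = prob, cols, check.names = FALSE)
  out[order(-out$probability), , drop = FALSE]
}

#' Exact meiosis I centromere segregation pattern distribution
#'
#' Each bivalent contributes two centromere-bearing units that split 1:1 at
#' anaphase I; each univalent pair contributes two units that segregate
#' independently. The result is the exact distribution over the unordered
#' pole splits "a:b" (a >= b, a + b = total units) — for the full Drosophila
#' complement of 8 units these are the five patterns 4:4, 5:3, 6:2, 7:1
#' and 8:0.
#'
#' @param scenario A [meiosis_scenario()].
#' @return A data.frame with columns `pattern` (all `floor(n/2) + 1` splits)
#'   and `probability`.
#' @examples
#' pattern_distribution(scenario_uno_null())   # random segregation of 8 units
#' @export
pattern_distribution <- function(scenario) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  # distribution of number of units at pole 1, convolved across entries
  dist <- c(1)  # P(0 units so far) = 1; index i -> i-1 units
  for (pair in scenario$chromosomes) {
    step <- if (pair$conjunction == "bivalent") c(0, 1, 0) else c(0.25, 0.5, 0.25)
    new <- numeric(length(dist) + 2L)
    for (k in 0:2) new[seq_along(dist) + k] <- new[seq_along(dist) + k] + dist * step[k + 1L]
    dist <- new
  }
  n <- 2L * length(scenario$chromosomes)
  splits <- seq.int(ceiling(n / 2), n)
  prob <- vapply(splits, function(a) {
    p <- dist[a + 1L]
    if (a != n - a) p <- p + dist[n - a + 1L]
    p
  }, numeric(1))
  data.frame(
    pattern = sprintf("%d:%d", splits, n - splits),
    probability = prob,
    stringsAsFactors = FALSE
  )
}

#' Exact per-spermatid FISH class probabilities
#'
#' Marginalizes the enumerated tetrad law over the four spermatids of a
#' meiosis and classifies each spermatid by presence (at least one chromatid)
#' of the red- and green-probed chromosomes: `none`, `red_only`,
#' `green_only`, or `both`. Presence-based classification mirrors FISH
#' scoring, where two chromatids of the same chromosome are not reliably
#' resolved as two spots.
#'
#' @param scenario A [meiosis_scenario()] carrying one red- and one
#'   green-probed homolog.
#' @return An object of class `fish_class_summary`: a list with the four
#'   class probabilities `p_none`, `p_red_only`, `p_green_only`, `p_both`
#'   plus the derived ratios `zero_to_rg` (`NA` when `p_both` is 0) and
#'   `normal_to_abnormal` (`NA` when `p_none + p_both` is 0).
#' @seealso [zero_to_rg_ratio()], [normal_to_abnormal_ratio()] which raise
#'   an explicit error instead of returning `NA` for undefined ratios.
#' @examples
#' fish_class_probabilities(scenario_xy_univalent("random_chromatids"))
#' @export
fish_class_probabilities <- function(scenario) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  pi <- probe_index(scenario)
  ht <- pi$table
  od <- enumerate_meioses(scenario)
  e_r <- ht$entry[pi$red];  h_r <- ht$homolog[pi$red]
  e_g <- ht$entry[pi$green]; h_g <- ht$homolog[pi$green]
  cls <- c(p_none = 0, p_red_only = 0, p_green_only = 0, p_both = 0)
  for (s in 1:4) {
    if (e_r == e_g) {
      m <- od$marginals[[e_r]]
      joint <- c(0, 0, 0, 0)  # none, red, green, both
      for (i in seq_along(m$prob)) {
        r <- m$counts[[i]][h_r, s] >= 1L
        g <- m$counts[[i]][h_g, s] >= 1L
        j <- 1L + r + 2L * g
        joint[j] <- joint[j] + m$prob[i]
      }
      cls <- cls + c(joint[1], joint[2], joint[3], joint[4]) / 4
    } else {
      pr <- marginal_presence(od$marginals[[e_r]], h_r, s)
      pg <- marginal_presence(od$marginals[[e_g]], h_g, s)
      cls <- cls + c((1 - pr) * (1 - pg), pr * (1 - pg),
                     (1 - pr) * pg, pr * pg) / 4
    }
  }
  structure(
    list(p_none = unname(cls[1]), p_red_only = unname(cls[2]),
         p_green_only = unname(cls[3]), p_both = unname(cls[4]),
         zero_to_rg = if (cls[4] > 0) unname(cls[1] / cls[4]) else NA_real_,
         normal_to_abnormal = if (cls[1] + cls[4] > 0)
           unname((cls[2] + cls[3]) / (cls[1] + cls[4])) else NA_real_,
         scenario_name = scenario$name),
    class = "fish_class_summary"
  )
}

marginal_presence <- function(m, h, s) {
  sum(m$prob[vapply(m$counts, function(cc) cc[h, s] >= 1L, logical(1))])
}

#' @export
print.fish_class_summary <- function(x, ...) {
  cat(sprintf("Exact FISH class probabilities (scenario '%s')\n", x$scenario_name))
  v <- unlist(x[c("p_none", "p_red_only", "p_green_only", "p_both")])
  print(round(v, 6))
  cat(sprintf("  0/RG: %s   normal:abnormal: %s\n",
              if (is.na(x$zero_to_rg)) "undefined" else format(x$zero_to_rg),
              if (is.na(x$normal_to_abnormal)) "undefined"
              else format(x$normal_to_abnormal)))
  invisible(x)
}

#' The 0/RG diagnostic ratio
#'
#' Ratio between the probability of spermatid nuclei without any FISH signal
#' and that of nuclei with both a red and a green signal,
#' `p_none / p_both`, computed by exact enumeration. Under random univalent
#' segregation at meiosis I the ratio diagnoses the meiosis II rule: it is 1
#' when sisters split regularly 1:1 and 25/9 = 2.777... when chromatids
#' segregate independently at meiosis II.
#'
#' @param x A [meiosis_scenario()] or a `fish_class_summary`.
#' @return The exact ratio (a single number).
#' @section Errors: when `p_both` is 0 (e.g. the wild type, which produces no
#'   double-signal nuclei) the ratio is undefined and an error of class
#'   `meioconj_undefined_ratio` is raised; no numeric sentinel is returned.
#' @examples
#' zero_to_rg_ratio(scenario_xy_univalent("regular_sisters"))    # 1
#' zero_to_rg_ratio(scenario_xy_univalent("random_chromatids"))  # 25/9
#' @export
zero_to_rg_ratio <- function(x) {
  cls <- as_fish_class_summary(x)
  if (!(cls$p_both > 0)) stop_undefined_ratio("0/RG ratio")
  cls$p_none / cls$p_both
}

#' The normal:abnormal FISH class ratio
#'
#' Ratio between the probability of spermatid nuclei with normal signals
#' (exactly one red or one green) and that of nuclei with abnormal signals
#' (none, or both red and green): `(p_red_only + p_green_only) /
#' (p_none + p_both)`. Expected to be 1 under random segregation of the sex
#' chromosomes at meiosis I.
#'
#' @inheritParams zero_to_rg_ratio
#' @return The exact ratio.
#' @section Errors: undefined (error class `meioconj_undefined_ratio`) when
#'   no abnormal class has positive probability, as in the wild type.
#' @examples
#' normal_to_abnormal_ratio(scenario_xy_univalent("regular_sisters"))  # 1
#' @export
normal_to_abnormal_ratio <- function(x) {
  cls <- as_fish_class_summary(x)
  denom <- cls$p_none + cls$p_both
  if (!(denom > 0)) stop_undefined_ratio("normal:abnormal ratio")
  (cls$p_red_only + cls$p_green_only) / denom
}

as_fish_class_summary <- function(x) {
  if (inherits(x, "fish_class_summary")) x
  else if (inherits(x, "meiosis_scenario")) fish_class_probabilities(x)
  else stop_meioconj("expected a meiosis_scenario or fish_class_summary",
                     "meioconj_invalid_input")
}

#' Model predictions for a segregation scenario
#'
#' The exact model outputs for a scenario: per-spermatid FISH class
#' probabilities (`type = "classes"`), the meiosis I centromere split
#' distribution (`type = "patterns"`), or the derived 0/RG and
#' normal:abnormal ratios (`type = "ratios"`).
#'
#' @param object A [meiosis_scenario()].
#' @param type Which prediction to return.
#' @param ... Unused.
#' @return See each type; `"ratios"` returns a named list where an undefined
#'   ratio appears as `NA` (use [zero_to_rg_ratio()] for the erroring
#'   contract).
#' @examples
#' predict(scenario_uno_null("random_chromatids"), type = "ratios")
#' @export
predict.meiosis_scenario <- function(object,
                                     type = c("classes", "patterns", "ratios"),
                                     ...) {
  type <- match.arg(type)
  switch(type,
    classes = fish_class_probabilities(object),
    patterns = pattern_distribution(object),
    ratios = {
      cls <- fish_class_probabilities(object)
      list(zero_to_rg = cls$zero_to_rg,
           normal_to_abnormal = cls$normal_to_abnormal)
    }
  )
}

#' @export
plot.meiosis_scenario <- function(x, ...) {
  pd <- pattern_distribution(x)
  graphics::barplot(pd$probability, names.arg = pd$pattern,
                    ylab = "probability",
                    xlab = "M I centromere segregation pattern",
                    main = sprintf("Scenario '%s'", x$name), ...)
  invisible(pd)
}
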