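# Scoring of per-nucleus X/Y FISH signal counts and per-cyst aggregation.

fish_classes <- c("none", "red_only", "green_only", "both", "unscored_multisignal")

#' Classify spermatid nuclei by their FISH signal counts
#'
#' Presence-based classification of red/green signal counts per nucleus:
#' (0,0) is `none`; (1,0) `red_only`; (0,1) `green_only`; at least one signal
#' of each color is `both`. Nuclei with two or more signals of one color and
#' none of the other are `unscored_multisignal`: two same-color spots are not
#' reliably resolved, so such nuclei are excluded from class fractions and
#' counted separately.
#'
#' @param red_count,green_count Nonnegative integer vectors (recycled to a
#'   common length).
#' @return Factor with levels `none`, `red_only`, `green_only`, `both`,
#'   `unscored_multisignal`.
#' @examples
#' classify_nucleus(c(0, 1, 0, 1, 2), c(0, 0, 1, 1, 0))
#' @export
classify_nucleus <- function(red_count, green_count) {
  n <- max(length(red_count), length(green_count))
  r <- rep_len(red_count, n)
  g <- rep_len(green_count, n)
  if (!is.numeric(r) || !is.numeric(g) || any(!is.finite(c(r, g))) ||
      any(c(r, g) < 0) || any(c(r, g) != floor(c(r, g)))) {
    stop_meioconj("signal counts must be nonnegative integers",
                  "meioconj_invalid_input")
  }
  out <- character(n)
  out[r == 0 & g == 0] <- "none"
  out[r == 1 & g == 0] <- "red_only"
  out[r == 0 & g == 1] <- "green_only"
  out[r >= 1 & g >= 1] <- "both"
  out[(r >= 2 & g == 0) | (r == 0 & g >= 2)] <- "unscored_multisignal"
  factor(out, levels = fish_classes)
}

#' Summarize FISH classes for one spermatid cyst
#'
#' Computes class fractions over the scored nuclei of one cyst, the count of
#' excluded multi-signal nuclei, the abnormal fraction (classes `none` +
#' `both`), and the cyst's 0/RG ratio — the count of zero-signal nuclei
#' divided by the count of red-plus-green nuclei, `NA` when no `both` nucleus
#' was seen.
#'
#' @param records Data frame with columns `cyst_id`, `nucleus_id`,
#'   `red_count`, `green_count` for a single cyst.
#' @return One-row data.frame of class `cyst_fish_summary` with columns
#'   `cyst_id`, `n_scored`, `n_unscored_multisignal`, `f_none`, `f_red_only`,
#'   `f_green_only`, `f_both`, `abnormal_fraction`, `zero_to_rg`.
#' @export
summarize_cyst <- function(records) {
  validate_fish_table(records)
  if (nrow(records) == 0L) {
    stop_meioconj("empty cyst: no nuclei to summarize", "meioconj_invalid_input")
  }
  if (length(unique(records$cyst_id)) != 1L) {
    stop_meioconj("summarize_cyst expects records of a single cyst (see summarize_fish_table)",
                  "meioconj_invalid_input")
  }
  cls <- classify_nucleus(records$red_count, records$green_count)
  tab <- table(cls)
  n_unscored <- as.integer(tab[["unscored_multisignal"]])
  n_scored <- nrow(records) - n_unscored
  if (n_scored == 0L) {
    stop_meioconj("cyst has no scored nuclei (all multi-signal)",
                  "meioconj_invalid_input")
  }
  f <- as.numeric(tab[c("none", "red_only", "green_only", "both")]) / n_scored
  out <- data.frame(
    cyst_id = records$cyst_id[1],
    n_scored = n_scored,
    n_unscored_multisignal = n_unscored,
    f_none = f[1], f_red_only = f[2], f_green_only = f[3], f_both = f[4],
    abnormal_fraction = f[1] + f[4],
    zero_to_rg = if (tab[["both"]] > 0) tab[["none"]] / tab[["both"]] else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cyst_fish_summary", class(out))
  out
}

#' Summarize every cyst of a FISH count table
#'
#' @param records Data frame with columns `cyst_id`, `nucleus_id`,
#'   `red_count`, `green_count` (any number of cysts).
#' @return Data.frame with one [summarize_cyst()] row per cyst, in order of
#'   first appearance.
#' @examples
#' tab <- gen_fish_table(scenario_xy_univalent(), n_cysts = 3,
#'                       nuclei_per_cyst = 64, seed = 7)
#' summarize_fish_table(tab)
#' @export
summarize_fish_table <- function(records) {
  validate_fish_table(records)
  ids <- unique(records$cyst_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    summarize_cyst(records[records$cyst_id == id, , drop = FALSE])
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate per-cyst FISH statistics for one genotype
#'
#' Cross-cyst sample mean and sample s.d. (n - 1 denominator, appropriate for
#' the small cyst numbers typical of the assay) of the per-cyst 0/RG ratio
#' and abnormal fraction. Cysts whose 0/RG is undefined are excluded from the
#' ratio's aggregate and reported separately, never imputed.
#'
#' @param cyst_summaries Output of [summarize_fish_table()] (>= 2 cysts).
#' @return List of class `fish_genotype_summary` with elements `n_cysts`,
#'   `zero_to_rg` (list `mean`, `sd`, `n` over cysts with a defined ratio),
#'   `n_cysts_undefined_ratio`, and `abnormal_fraction` (list `mean`, `sd`,
#'   `n`).
#' @section Errors: if fewer than 2 cysts have a defined 0/RG the ratio
#'   aggregate is impossible and an error of class
#'   `meioconj_aggregate_undefined` is raised.
#' @export
aggregate_genotype <- function(cyst_summaries) {
  stopifnot(is.data.frame(cyst_summaries))
  need <- c("cyst_id", "zero_to_rg", "abnormal_fraction")
  if (!all(need %in% names(cyst_summaries))) {
    stop_meioconj("expected the output of summarize_fish_table()",
                  "meioconj_invalid_input")
  }
  if (nrow(cyst_summaries) < 2L) {
    stop_meioconj("need at least 2 cysts to aggregate", "meioconj_invalid_input")
  }
  ratio <- cyst_summaries$zero_to_rg[!is.na(cyst_summaries$zero_to_rg)]
  if (length(ratio) < 2L) {
    stop_meioconj("fewer than 2 cysts have a defined 0/RG ratio; aggregate undefined",
                  "meioconj_aggregate_undefined")
  }
  ab <- cyst_summaries$abnormal_fraction
  structure(
    list(
      n_cysts = nrow(cyst_summaries),
      zero_to_rg = list(mean = mean(ratio), sd = stats::sd(ratio),
                        n = length(ratio)),
      n_cysts_undefined_ratio = nrow(cyst_summaries) - length(ratio),
      abnormal_fraction = list(mean = mean(ab), sd = stats::sd(ab),
                               n = length(ab))
    ),
    class = "fish_genotype_summary"
  )
}

#' @export
print.fish_genotype_summary <- function(x, ...) {
  cat(sprintf("FISH genotype summary over %d cysts\n", x$n_cysts))
  cat(sprintf("  0/RG: %.3f +/- %.3f (s.d., n = %d; %d cyst(s) undefined)\n",
              x$zero_to_rg$mean, x$zero_to_rg$sd, x$zero_to_rg$n,
              x$n_cysts_undefined_ratio))
  cat(sprintf("  abnormal fraction: %.3f +/- %.3f (s.d., n = %d)\n",
              x$abnormal_fraction$mean, x$abnormal_fraction$sd,
              x$abnormal_fraction$n))
  invisible(x)
}

validate_fish_table <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("cyst_id", "nucleus_id", "red_count", "green_count") %in%
           names(records))) {
    stop_meioconj("FISH table needs columns cyst_id, nucleus_id, red_count, green_count",
                  "meioconj_invalid_input")
  }
  invisible(records)
}
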