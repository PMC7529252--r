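#' Describe one homolog pair of a meiotic segregation scenario
#'
#' A scenario entry represents one pair of homologous chromosomes as it enters
#' meiosis I, i.e. two homologs of two sister chromatids each after pre-meiotic
#' S phase. The two homologs may differ: the Drosophila sex "pair" consists of
#' chr X and chr Y, which carry different FISH probes and DNA contents, so
#' `dna_content` and `probe` are per homolog (a single value is recycled to
#' both).
#'
#' @param name Label for the pair (e.g. `"XY"`, `"chr2"`).
#' @param dna_content Relative DNA amount per single chromatid, `> 0`. Length 1
#'   (both homologs equal) or 2 (per homolog).
#' @param conjunction `"bivalent"` (homologs conjoined; the bivalent splits 1:1
#'   at anaphase I, one homolog per pole) or `"univalent_pair"` (conjunction
#'   lost; each homolog segregates at meiosis I as an intact two-chromatid
#'   univalent, independently to either pole with probability 1/2).
#' @param probe FISH probe carried by each homolog: `"none"`, `"red"` or
#'   `"green"`. Length 1 or 2. At most one homolog in a scenario may carry each
#'   color.
#' @return An object of class `chromosome_pair`.
#' @examples
#' chromosome_pair("XY", dna_content = 1, conjunction = "bivalent",
#'                 probe = c("red", "green"))
#' @export
chromosome_pair <- function(name, dna_content = 1,
                            conjunction = c("bivalent", "univalent_pair"),
                            probe = "none") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  conjunction <- match.arg(conjunction)
  if (!is.numeric(dna_content) || !length(dna_content) %in% c(1L, 2L) ||
      any(!is.finite(dna_content)) || any(dna_content <= 0)) {
    stop_meioconj("`dna_content` must be one or two finite values > 0",
                  "meioconj_invalid_scenario")
  }
  dna_content <- rep_len(as.numeric(dna_content), 2L)
  if (!is.character(probe) || !length(probe) %in% c(1L, 2L) ||
      !all(probe %in% c("none", "red", "green"))) {
    stop_meioconj("`probe` must be one or two of 'none', 'red', 'green'",
                  "meioconj_invalid_scenario")
  }
  probe <- rep_len(probe, 2L)
  if (probe[1] != "none" && probe[1] == probe[2]) {
    stop_meioconj("the two homologs of one pair cannot carry the same probe color",
                  "meioconj_invalid_scenario")
  }
  structure(
    list(name = name, dna_content = dna_content,
         conjunction = conjunction, probe = probe),
    class = "chromosome_pair"
  )
}

#' Construct a meiotic segregation scenario
#'
#' A scenario is the complete parameterization of the segregation model: the
#' chromosome roster with per-pair conjunction state, plus the meiosis II rule.
#' Meiosis I behavior is fixed by the conjunction states (bivalents split 1:1;
#' univalents segregate randomly and intact). The returned object is the
#' package's central model object: [predict.meiosis_scenario()] performs the
#' exact enumeration, [simulate.meiosis_scenario()] the Monte Carlo twin.
#'
#' @param chromosomes List of [chromosome_pair()] entries (1 to 8).
#' @param mII_rule Meiosis II sister segregation: `"regular_sisters"` (each
#'   chromosome's two chromatids split 1:1 between the two spermatids of its
#'   pole) or `"random_chromatids"` (each chromatid independently goes to
#'   either spermatid with probability 1/2, so 2:0 splits can occur).
#' @param name Optional scenario label.
#' @return An object of class `meiosis_scenario`.
#' @seealso [scenario_wildtype()], [scenario_xy_univalent()],
#'   [scenario_uno_null()] for the shipped standard scenarios.
#' @examples
#' sc <- meiosis_scenario(
#'   list(chromosome_pair("XY", probe = c("red", "green"),
#'                        conjunction = "univalent_pair")),
#'   mII_rule = "random_chromatids")
#' predict(sc)
#' @export
meiosis_scenario <- function(chromosomes,
                             mII_rule = c("regular_sisters", "random_chromatids"),
                             name = NULL) {
  mII_rule <- match.arg(mII_rule)
  if (inherits(chromosomes, "chromosome_pair")) chromosomes <- list(chromosomes)
  if (!is.list(chromosomes) ||
      !all(vapply(chromosomes, inherits, logical(1), "chromosome_pair"))) {
    stop_meioconj("`chromosomes` must be a list of chromosome_pair objects",
                  "meioconj_invalid_scenario")
  }
  n <- length(chromosomes)
  if (n < 1L || n > 8L) {
    stop_meioconj(
      sprintf("a scenario needs 1 to 8 chromosome entries, got %d (state space grows as 4^k per chromatid set)", n),
      "meioconj_size_limit"
    )
  }
  nms <- vapply(chromosomes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_meioconj("chromosome names must be unique", "meioconj_invalid_scenario")
  }
  probes <- unlist(lapply(chromosomes, `[[`, "probe"))
  for (color in c("red", "green")) {
    if (sum(probes == color) > 1L) {
      stop_meioconj(
        sprintf("at most one chromosome may carry the %s probe", color),
        "meioconj_invalid_scenario"
      )
    }
  }
  structure(
    list(chromosomes = chromosomes, mII_rule = mII_rule,
         name = name %||% "scenario"),
    class = "meiosis_scenario"
  )
}

# Flat per-homolog view of a scenario: one row per homolog (2 per entry).
# Used throughout the enumeration and simulation code.
homolog_table <- function(scenario) {
  ch <- scenario$chromosomes
  data.frame(
    entry = rep(seq_along(ch), each = 2L),
    pair = rep(vapply(ch, `[[`, character(1), "name"), each = 2L),
    homolog = rep(1:2, length(ch)),
    dna_content = unlist(lapply(ch, `[[`, "dna_content")),
    conjunction = rep(vapply(ch, `[[`, character(1), "conjunction"), each = 2L),
    probe = unlist(lapply(ch, `[[`, "probe")),
    stringsAsFactors = FALSE
  )
}

# Locate the red- and green-probed homologs; error when absent.
probe_index <- function(scenario) {
  ht <- homolog_table(scenario)
  red <- which(ht$probe == "red")
  green <- which(ht$probe == "green")
  if (length(red) != 1L || length(green) != 1L) {
    stop_meioconj(
      "scenario must carry exactly one red-probed and one green-probed homolog for FISH class computation",
      "meioconj_missing_probe"
    )
  }
  list(red = red, green = green, table = ht)
}

#' @export
print.chromosome_pair <- function(x, ...) {
  probes <- ifelse(x$probe == "none", "-", x$probe)
  cat(sprintf("<chromosome pair> %s: %s; chromatid DNA content %s/%s; probes %s/%s\n",
              x$name, x$conjunction,
              format(x$dna_content[1]), format(x$dna_content[2]),
              probes[1], probes[2]))
  invisible(x)
}

#' @export
print.meiosis_scenario <- function(x, ...) {
  cat(sprintf("Meiotic segregation scenario '%s'\n", x$name))
  cat(sprintf("  %d homolog pair(s); M II rule: %s\n",
              length(x$chromosomes), x$mII_rule))
  for (p in x$chromosomes) {
    cat("  "); print(p)
  }
  invisible(x)
}

#' @export
summary.meiosis_scenario <- function(object, ...) {
  n_biv <- sum(vapply(object$chromosomes, `[[`, character(1), "conjunction") == "bivalent")
  n_uni <- length(object$chromosomes) - n_biv
  out <- list(
    scenario = object,
    n_bivalents = n_biv,
    n_univalent_pairs = n_uni,
    n_centromere_units = 2L * length(object$chromosomes),
    patterns = pattern_distribution(object)
  )
  out$classes <- tryCatch(fish_class_probabilities(object),
                          meioconj_missing_probe = function(e) NULL)
  class(out) <- "summary.meiosis_scenario"
  out
}

#' @export
print.summary.meiosis_scenario <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  %d bivalent(s), %d univalent pair(s), %d centromere-bearing units at M I\n",
              x$n_bivalents, x$n_univalent_pairs, x$n_centromere_units))
  cat("  M I centromere split distribution:\n")
  pp <- x$patterns$probability
  names(pp) <- x$patterns$pattern
  print(round(pp, 5))
  if (!is.null(x$classes)) {
    cat("  Exact per-spermatid FISH class probabilities:\n")
    print(unlist(x$classes[c("p_none", "p_red_only", "p_green_only", "p_both")]))
  }
  invisible(x)
}

#' Standard scenarios of Drosophila male meiosis
#'
#' Ready-made rosters of the four D. melanogaster chromosome pairs with a red
#' FISH probe on chr X and a green probe on chr Y:
#' \describe{
#'   \item{`scenario_wildtype()`}{all four pairs conjoined as bivalents,
#'     regular sister segregation — the control situation; every spermatid
#'     receives exactly one chromatid per pair.}
#'   \item{`scenario_xy_univalent()`}{conjunction lost for the sex chromosomes
#'     only: chr X and chr Y segregate as two independent univalents at
#'     meiosis I while the autosomes stay bivalent (3 bivalents + 1 univalent
#'     pair).}
#'   \item{`scenario_uno_null()`}{conjunction lost genome-wide, as in
#'     conjunction-null mutants: all four pairs are univalent pairs, i.e. all
#'     8 centromere-bearing units segregate independently at meiosis I.}
#' }
#' Default chromatid DNA contents are equal for X and Y (and unity for the
#' large chromosomes, 0.2 for the dot chr 4) so that the wild-type scenario
#' yields spermatids of identical DNA content.
#'
#' @param mII_rule Meiosis II rule, see [meiosis_scenario()].
#' @return A `meiosis_scenario`.
#' @examples
#' zero_to_rg_ratio(scenario_xy_univalent("random_chromatids"))  # 25/9
#' @export
scenario_wildtype <- function(mII_rule = "regular_sisters") {
  meiosis_scenario(drosophila_roster(univalent = character(0)),
                   mII_rule = mII_rule, name = "wild type")
}

#' @rdname scenario_wildtype
#' @export
scenario_xy_univalent <- function(mII_rule = "regular_sisters") {
  meiosis_scenario(drosophila_roster(univalent = "XY"),
                   mII_rule = mII_rule, name = "XY univalent")
}

#' @rdname scenario_wildtype
#' @export
scenario_uno_null <- function(mII_rule = "regular_sisters") {
  meiosis_scenario(drosophila_roster(univalent = c("XY", "chr2", "chr3", "chr4")),
                   mII_rule = mII_rule, name = "conjunction null")
}

drosophila_roster <- function(univalent) {
  conj <- function(nm) if (nm %in% univalent) "univalent_pair" else "bivalent"
  list(
    chromosome_pair("XY", dna_content = 1, conjunction = conj("XY"),
                    probe = c("red", "green")),
    chromosome_pair("chr2", dna_content = 1, conjunction = conj("chr2")),
    chromosome_pair("chr3", dna_content = 1, conjunction = conj("chr3")),
    chromosome_pair("chr4", dna_content = 0.2, conjunction = conj("chr4"))
  )
}
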