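# Configuration and table I/O, scenario hashing, and the reproducible
# pipeline runner with its JSON manifest.

#' Read and write segregation scenario configuration files
#'
#' Scenarios are stored as JSON with the schema
#' `{"name": ..., "mII_rule": ..., "chromosomes": [{"name": ...,
#' "dna_content": number or [a, b], "conjunction": ...,
#' "probe": string or [p1, p2]}, ...]}`. Unknown keys are rejected so that
#' typos never pass silently; all scenario invariants (probe uniqueness,
#' entry count, valid rule names) are enforced on read.
#'
#' @param path Path to a JSON scenario file (`parse_scenario` also accepts a
#'   literal JSON string).
#' @return `parse_scenario()`: a [meiosis_scenario()].
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_scenario(scenario_xy_univalent("random_chromatids"), f)
#' parse_scenario(f)
#' @export
parse_scenario <- function(path) {
  txt <- if (length(path) == 1L && !grepl("[{\n]", path) && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else paste(path, collapse = "\n")
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyDataFrame = FALSE),
                  error = function(e) {
                    stop_meioconj(sprintf("malformed scenario config: %s",
                                          conditionMessage(e)),
                                  "meioconj_config_error")
                  })
  allowed_top <- c("name", "mII_rule", "chromosomes")
  unknown <- setdiff(names(obj), allowed_top)
  if (length(unknown) > 0L) {
    stop_meioconj(sprintf("unknown scenario key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "meioconj_config_error")
  }
  if (is.null(obj$chromosomes) || is.null(obj$mII_rule)) {
    stop_meioconj("scenario config requires 'chromosomes' and 'mII_rule'",
                  "meioconj_config_error")
  }
  allowed_ch <- c("name", "dna_content", "conjunction", "probe")
  pairs <- lapply(obj$chromosomes, function(ch) {
    unknown <- setdiff(names(ch), allowed_ch)
    if (length(unknown) > 0L) {
      stop_meioconj(sprintf("unknown chromosome key(s): %s",
                            paste(unknown, collapse = ", ")),
                    "meioconj_config_error")
    }
    if (is.null(ch$name) || is.null(ch$conjunction)) {
      stop_meioconj("each chromosome needs 'name' and 'conjunction'",
                    "meioconj_config_error")
    }
    chromosome_pair(ch$name,
                    dna_content = unlist(ch$dna_content) %||% 1,
                    conjunction = ch$conjunction,
                    probe = unlist(ch$probe) %||% "none")
  })
  meiosis_scenario(pairs, mII_rule = obj$mII_rule, name = obj$name)
}

#' @rdname parse_scenario
#' @param scenario A [meiosis_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  jsonlite::write_json(scenario_to_list(scenario), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

scenario_to_list <- function(scenario) {
  list(
    name = scenario$name,
    mII_rule = scenario$mII_rule,
    chromosomes = lapply(scenario$chromosomes, function(p) {
      list(name = p$name, dna_content = p$dna_content,
           conjunction = p$conjunction, probe = p$probe)
    })
  )
}

#' Fingerprint of a scenario configuration
#'
#' 32-bit FNV-1a hash of the canonical JSON form, recorded in every output
#' header so that tables can be traced back to the exact model
#' parameterization that produced them.
#'
#' @param scenario A [meiosis_scenario()].
#' @return 8-character hex string.
#' @export
scenario_hash <- function(scenario) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  fnv1a32(jsonlite::toJSON(scenario_to_list(scenario), auto_unbox = TRUE,
                           digits = NA))
}

#' Write a result table with a provenance header
#'
#' Writes a CSV preceded by a `#` comment line recording the package
#' version, the scenario hash and the seed, so every table is traceable and
#' reproducible. [read_result_table()] (and plain
#' `read.csv(comment.char = "#")`) reads it back.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param scenario Optional [meiosis_scenario()] whose hash is recorded.
#' @param seed Optional integer seed to record.
#' @export
write_result_table <- function(df, path, scenario = NULL, seed = NULL) {
  stopifnot(is.data.frame(df))
  header <- sprintf(
    "# meioconj %s%s%s",
    as.character(utils::packageVersion("meioconj")),
    if (!is.null(scenario)) sprintf("; scenario_hash=%s", scenario_hash(scenario)) else "",
    if (!is.null(seed)) sprintf("; seed=%d", as.integer(seed)) else ""
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a per-nucleus FISH count table
#'
#' @param path CSV with columns `cyst_id`, `nucleus_id`, `red_count`,
#'   `green_count` (comment lines starting with `#` are ignored).
#' @return Validated data.frame.
#' @export
read_fish_table <- function(path) {
  validate_fish_table(read_result_table(path))
}

#' Run the synthetic FISH pipeline end to end
#'
#' Generates a FISH count table under a scenario, scores and aggregates it,
#' computes the exact model predictions for comparison, writes all outputs
#' as provenance-stamped CSVs plus a JSON run manifest, and returns the
#' results. A stage failure propagates as an error naming the stage and no
#' manifest is written.
#'
#' @param scenario A [meiosis_scenario()] with probes.
#' @param out_dir Output directory (created if needed).
#' @param n_cysts,nuclei_per_cyst,dropout Passed to [gen_fish_table()].
#' @param seed Integer seed governing the whole run.
#' @return List of class `pipeline_run`: `table`, `cysts`, `aggregate`,
#'   `prediction` (exact class probabilities), `manifest` (also written to
#'   `manifest.json`).
#' @examples
#' run <- run_fish_pipeline(scenario_xy_univalent(), out_dir = tempfile(),
#'                          n_cysts = 3, nuclei_per_cyst = 64, seed = 11)
#' run$aggregate
#' @export
run_fish_pipeline <- function(scenario, out_dir, n_cysts = 13,
                              nuclei_per_cyst = 200, dropout = 0, seed) {
  stopifnot(inherits(scenario, "meiosis_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_meioconj(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)),
                    "meioconj_pipeline_error")
    })
  }
  tab <- stage("synth", gen_fish_table(scenario, n_cysts = n_cysts,
                                       nuclei_per_cyst = nuclei_per_cyst,
                                       dropout = dropout, seed = seed))
  cysts <- stage("fish-score", summarize_fish_table(tab))
  agg <- stage("aggregate", aggregate_genotype(cysts))
  pred <- stage("predict", fish_class_probabilities(scenario))
  paths <- list(
    table = file.path(out_dir, "fish_table.csv"),
    cysts = file.path(out_dir, "cyst_summaries.csv"),
    prediction = file.path(out_dir, "prediction.csv")
  )
  write_result_table(tab, paths$table, scenario = scenario, seed = seed)
  write_result_table(as.data.frame(unclass(cysts)), paths$cysts,
                     scenario = scenario, seed = seed)
  write_result_table(
    data.frame(class = c("none", "red_only", "green_only", "both"),
               probability = c(pred$p_none, pred$p_red_only,
                               pred$p_green_only, pred$p_both)),
    paths$prediction, scenario = scenario
  )
  manifest <- list(
    command = "run_fish_pipeline",
    package = "meioconj",
    version = as.character(utils::packageVersion("meioconj")),
    scenario = scenario_to_list(scenario),
    scenario_hash = scenario_hash(scenario),
    seed = as.integer(seed),
    parameters = list(n_cysts = n_cysts, nuclei_per_cyst = nuclei_per_cyst,
                      dropout = dropout),
    stages = c("synth", "fish-score", "predict"),
    outputs = paths,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(
    list(table = tab, cysts = cysts, aggregate = agg, prediction = pred,
         manifest = manifest),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, scenario %s): %d cysts scored\n",
              x$manifest$seed, x$manifest$scenario_hash, x$aggregate$n_cysts))
  print(x$aggregate)
  invisible(x)
}

#' Write and read images as TIFF
#'
#' @param image Numeric matrix (intensities are stored as 32-bit floats via
#'   [EBImage::writeImage()] after scaling to 0-1 when needed).
#' @param path File path.
#' @return `read_cyst_tiff()`: numeric matrix.
#' @export
write_cyst_tiff <- function(image, path) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  stopifnot(is.matrix(image))
  mx <- max(image)
  scale <- if (mx > 1) mx else 1
  EBImage::writeImage(EBImage::Image(image / scale), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_cyst_tiff
#' @export
read_cyst_tiff <- function(path) {
  EBImage::imageData(EBImage::readImage(path))
}
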