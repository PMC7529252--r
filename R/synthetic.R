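# Seeded generators of every input the pipeline consumes: FISH count
# tables, cyst images with ground truth, motif-planted protein sets, and
# single-dot intensity traces. Each generator is deterministic for a fixed
# (parameters, seed) pair.

#' Generate a per-nucleus FISH count table from a segregation scenario
#'
#' Draws complete meioses from the scenario and emits one row per spermatid
#' nucleus with red/green signal counts. By default signals are
#' presence-based (one signal per present probed chromosome), matching FISH
#' scoring practice; `chromatid_resolved = TRUE` emits one signal per
#' chromatid so 2:0 meiosis II segregation produces two same-color signals
#' (the unscored multi-signal class). Optional detection dropout removes
#' each signal independently.
#'
#' @param scenario A [meiosis_scenario()] with red/green probes.
#' @param n_cysts Number of cysts.
#' @param nuclei_per_cyst Nuclei per cyst, a positive multiple of 4.
#' @param dropout Probability that a true signal is missed (default 0).
#' @param chromatid_resolved See above.
#' @param seed Integer seed.
#' @return Data.frame with columns `cyst_id`, `nucleus_id`, `red_count`,
#'   `green_count`.
#' @examples
#' tab <- gen_fish_table(scenario_xy_univalent("random_chromatids"),
#'                       n_cysts = 2, nuclei_per_cyst = 64, seed = 3)
#' table(classify_nucleus(tab$red_count, tab$green_count))
#' @export
gen_fish_table <- function(scenario, n_cysts = 13, nuclei_per_cyst = 200,
                           dropout = 0, chromatid_resolved = FALSE, seed) {
  stopifnot(inherits(scenario, "meiosis_scenario"),
            is_count(n_cysts), is_count(nuclei_per_cyst),
            dropout >= 0, dropout <= 1)
  if (nuclei_per_cyst %% 4 != 0) {
    stop_meioconj("`nuclei_per_cyst` must be a multiple of 4 (complete meioses)",
                  "meioconj_invalid_input")
  }
  m <- as.integer(nuclei_per_cyst) %/% 4L
  with_seed(seed, {
    sim <- simulate_meioses(scenario, n_meioses = m * n_cysts,
                            seed = sample.int(.Machine$integer.max, 1))
    counts <- fish_counts(sim, chromatid_resolved = chromatid_resolved)
    if (dropout > 0) {
      counts[, "red"] <- stats::rbinom(nrow(counts), counts[, "red"], 1 - dropout)
      counts[, "green"] <- stats::rbinom(nrow(counts), counts[, "green"], 1 - dropout)
    }
    data.frame(
      cyst_id = rep(sprintf("cyst%02d", seq_len(n_cysts)),
                    each = nuclei_per_cyst),
      nucleus_id = sprintf("n%03d", rep(seq_len(nuclei_per_cyst), n_cysts)),
      red_count = as.integer(counts[, "red"]),
      green_count = as.integer(counts[, "green"]),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic cyst image with ground truth
#'
#' Renders spermatid nuclei as uniform disks on a dark field. Each disk's
#' integrated intensity equals the nucleus's DNA content — drawn from a
#' segregation scenario when one is supplied, otherwise taken from
#' `contents` (or unity). Nuclei are placed on a jittered grid, which
#' guarantees the requested minimal separation or fails with a layout
#' error; a `touching_fraction` of nuclei is instead placed as touching
#' pairs to exercise watershed splitting. Optional per-nucleus lognormal
#' intensity noise, Gaussian blur and additive background emulate imaging
#' imperfections.
#'
#' @param n_nuclei Number of nuclei (default 64, one cyst).
#' @param contents Optional numeric vector (length `n_nuclei`) of true DNA
#'   contents; overrides `scenario`.
#' @param scenario Optional [meiosis_scenario()]; contents are the spermatid
#'   DNA contents of `n_nuclei / 4` simulated meioses (then `n_nuclei` must
#'   be a multiple of 4).
#' @param pixel_size_um Micrometers per pixel.
#' @param nucleus_radius_um Disk radius in micrometers.
#' @param min_separation_um Minimal center-to-center distance between
#'   non-touching nuclei; default `2 * nucleus_radius_um + 3 * pixel_size_um`.
#' @param touching_fraction Fraction of nuclei placed as touching pairs
#'   (center distance `1.8 * radius`).
#' @param noise_sigma Standard deviation (log scale) of per-nucleus
#'   multiplicative lognormal intensity noise; 0 disables it. Lognormal
#'   rather than Gaussian noise keeps intensities positive.
#' @param background Additive constant background intensity per pixel.
#' @param blur_sigma Gaussian blur s.d. in pixels; 0 disables it.
#' @param field_px Image side length in pixels; computed from the layout
#'   when `NULL`.
#' @param seed Integer seed.
#' @return List of class `cyst_image`: `image` (numeric matrix), `labels`
#'   (ground-truth label matrix), `truth` (data.frame `nucleus`, `x`, `y`,
#'   `content` — the rendered integrated intensity, after noise, before
#'   blur/background), `pixel_size_um`.
#' @section Errors: a grid cell smaller than the required separation is an
#'   infeasible-packing error.
#' @examples
#' syn <- gen_cyst_image(n_nuclei = 12, seed = 1)
#' range(syn$labels)
#' @export
gen_cyst_image <- function(n_nuclei = 64, contents = NULL, scenario = NULL,
                           pixel_size_um = 0.16, nucleus_radius_um = 1.5,
                           min_separation_um = NULL, touching_fraction = 0,
                           noise_sigma = 0, background = 0, blur_sigma = 0,
                           field_px = NULL, seed) {
  stopifnot(is_count(n_nuclei), pixel_size_um > 0, nucleus_radius_um > 0,
            touching_fraction >= 0, touching_fraction <= 1,
            noise_sigma >= 0, background >= 0, blur_sigma >= 0)
  with_seed(seed, {
    if (is.null(contents)) {
      if (!is.null(scenario)) {
        if (n_nuclei %% 4 != 0) {
          stop_meioconj("`n_nuclei` must be a multiple of 4 when drawing from a scenario",
                        "meioconj_invalid_input")
        }
        sim <- simulate_meioses(scenario, n_meioses = n_nuclei %/% 4L,
                                seed = sample.int(.Machine$integer.max, 1))
        contents <- as.numeric(t(spermatid_contents(sim)))
      } else {
        contents <- rep(1, n_nuclei)
      }
    }
    stopifnot(length(contents) == n_nuclei, all(contents >= 0))
    r_px <- nucleus_radius_um / pixel_size_um
    min_sep_px <- (min_separation_um %||%
                     (2 * nucleus_radius_um + 3 * pixel_size_um)) / pixel_size_um
    n_pairs <- floor(touching_fraction * n_nuclei / 2)
    n_sites <- n_nuclei - n_pairs  # a touching pair occupies one site
    ncell <- ceiling(sqrt(n_sites))
    # a site hosting a touching pair extends 0.9 r beyond its center on
    # both sides; enlarge the required separation accordingly
    sep_req <- min_sep_px + if (n_pairs > 0) 1.8 * r_px else 0
    cell_px <- sep_req + 2
    margin <- cell_px / 2 + r_px
    side <- field_px %||% ceiling(ncell * cell_px + 2 * margin)
    cell_avail <- (side - 2 * margin) / ncell
    if (cell_avail < sep_req) {
      stop_meioconj("infeasible packing: field too small for the requested separation",
                    "meioconj_layout_error")
    }
    jitter_max <- max(0, (cell_avail - sep_req) / 2)
    sites <- utils::head(expand.grid(gx = seq_len(ncell), gy = seq_len(ncell)),
                         n_sites)
    cx <- margin + (sites$gx - 0.5) * cell_avail +
      stats::runif(n_sites, -jitter_max, jitter_max)
    cy <- margin + (sites$gy - 0.5) * cell_avail +
      stats::runif(n_sites, -jitter_max, jitter_max)
    # expand touching-pair sites into two centers 1.8 r apart
    centers_x <- numeric(0); centers_y <- numeric(0)
    pair_sites <- utils::head(seq_len(n_sites), n_pairs)
    for (i in seq_len(n_sites)) {
      if (i %in% pair_sites) {
        ang <- stats::runif(1, 0, 2 * pi)
        dx <- 0.9 * r_px * cos(ang); dy <- 0.9 * r_px * sin(ang)
        centers_x <- c(centers_x, cx[i] - dx, cx[i] + dx)
        centers_y <- c(centers_y, cy[i] - dy, cy[i] + dy)
      } else {
        centers_x <- c(centers_x, cx[i]); centers_y <- c(centers_y, cy[i])
      }
    }
    noisy <- contents * if (noise_sigma > 0)
      stats::rlnorm(n_nuclei, meanlog = -noise_sigma^2 / 2, sdlog = noise_sigma)
      else 1
    img <- matrix(0, side, side)
    labels <- matrix(0L, side, side)
    xg <- matrix(seq_len(side), side, side)
    yg <- matrix(seq_len(side), side, side, byrow = TRUE)
    rendered <- numeric(n_nuclei)
    for (i in seq_len(n_nuclei)) {
      d2 <- (xg - centers_x[i])^2 + (yg - centers_y[i])^2
      inside <- d2 <= r_px^2
      npx <- sum(inside)
      img[inside] <- img[inside] + noisy[i] / npx
      # ground truth: overlapping pixels go to the nearer center
      claim <- inside & (labels == 0L |
                           d2 < (xg - centers_x[pmax(labels, 1L)])^2 +
                                (yg - centers_y[pmax(labels, 1L)])^2)
      labels[claim] <- i
      rendered[i] <- noisy[i]
    }
    if (blur_sigma > 0) {
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = blur_sigma))
    }
    img <- img + background
    structure(
      list(image = img, labels = labels,
           truth = data.frame(nucleus = seq_len(n_nuclei),
                              x = centers_x, y = centers_y,
                              content = rendered),
           pixel_size_um = pixel_size_um),
      class = "cyst_image"
    )
  })
}

#' @export
print.cyst_image <- function(x, ...) {
  cat(sprintf("Synthetic cyst image: %d nuclei, %d x %d px at %.3g um/px\n",
              nrow(x$truth), nrow(x$image), ncol(x$image), x$pixel_size_um))
  invisible(x)
}

#' Generate a kleisin-like protein set with planted motifs
#'
#' Emulates the domain architecture of the conjunction protein family:
#' conserved N- and C-terminal blocks flanking a divergent central linker,
#' with a separase cleavage consensus (`[E/D]XXR`) planted at a fixed linker
#' position in every sequence (optionally also a `[L/V/I/M]PE` docking
#' motif). Incidental consensus matches are scrubbed from the family
#' consensus so that, at zero divergence, the planted sites are the only
#' hits. Per-position substitutions are applied at `linker_divergence` in
#' the linker and `terminal_divergence` in the blocks, sparing the planted
#' motifs.
#'
#' @param n_sequences Number of family members (>= 1).
#' @param linker_divergence Per-position substitution probability in the
#'   linker (0-1).
#' @param terminal_divergence Per-position substitution probability in the
#'   conserved blocks (default 0.02).
#' @param n_term_len,linker_len,c_term_len Segment lengths.
#' @param motif_text Planted cleavage site (must match `[E/D]XXR`).
#' @param motif_offset 1-based offset of the planted site within the linker
#'   (default: centered).
#' @param plant_docking Also plant an `LPE` docking motif 20 residues after
#'   the cleavage site.
#' @param seed Integer seed.
#' @return List: `sequences` (named character vector, equal lengths — usable
#'   directly as an alignment), `truth` (data.frame of planted motif
#'   positions: `motif`, `start` in ungapped coordinates).
#' @examples
#' ps <- gen_protein_set(n_sequences = 4, linker_divergence = 0, seed = 2)
#' scan_motif(ps$sequences)
#' @export
gen_protein_set <- function(n_sequences = 8, linker_divergence = 0.5,
                            terminal_divergence = 0.02,
                            n_term_len = 60, linker_len = 120, c_term_len = 60,
                            motif_text = "EAIR", motif_offset = NULL,
                            plant_docking = FALSE, seed) {
  stopifnot(is_count(n_sequences), linker_divergence >= 0,
            linker_divergence <= 1, terminal_divergence >= 0,
            terminal_divergence <= 1, linker_len >= 8)
  if (!grepl("^[ED]..R$", motif_text)) {
    stop_meioconj("`motif_text` must match the [E/D]XXR consensus",
                  "meioconj_invalid_input")
  }
  aa20 <- setdiff(AA_ALPHABET, "X")
  with_seed(seed, {
    total <- n_term_len + linker_len + c_term_len
    consensus <- sample(aa20, total, replace = TRUE)
    motif_offset <- motif_offset %||% max(1L, floor(linker_len / 2) - 1L)
    start <- n_term_len + motif_offset
    if (start + 3L > n_term_len + linker_len) {
      stop_meioconj("planted motif does not fit in the linker",
                    "meioconj_invalid_input")
    }
    consensus[start:(start + 3L)] <- strsplit(motif_text, "")[[1]]
    truth <- data.frame(motif = "cleavage_ExxR", start = start,
                        stringsAsFactors = FALSE)
    if (plant_docking) {
      dstart <- start + 20L
      stopifnot(dstart + 2L <= n_term_len + linker_len)
      consensus[dstart:(dstart + 2L)] <- c("L", "P", "E")
      truth <- rbind(truth, data.frame(motif = "docking_LVIMPE", start = dstart))
    }
    consensus <- scrub_incidental(consensus, truth, plant_docking)
    # per-sequence divergence, sparing planted positions
    rate <- c(rep(terminal_divergence, n_term_len),
              rep(linker_divergence, linker_len),
              rep(terminal_divergence, c_term_len))
    planted <- unlist(mapply(function(s, m) {
      seq.int(s, s + if (m == "cleavage_ExxR") 3L else 2L)
    }, truth$start, truth$motif, SIMPLIFY = FALSE))
    rate[planted] <- 0
    seqs <- vapply(seq_len(n_sequences), function(i) {
      s <- consensus
      mut <- stats::runif(total) < rate
      s[mut] <- vapply(which(mut), function(p) {
        sample(setdiff(aa20, s[p]), 1)
      }, character(1))
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("seq%02d", seq_len(n_sequences))
    list(sequences = seqs, truth = truth)
  })
}

# Remove consensus matches other than the planted ones from the family
# consensus: break incidental [E/D]XXR by R -> K, incidental [L/V/I/M]PE
# (when a docking motif is planted) by P -> G.
scrub_incidental <- function(consensus, truth, scrub_docking) {
  repeat {
    s <- paste(consensus, collapse = "")
    hits <- scan_motif(stats::setNames(s, "c"), "cleavage_ExxR")
    bad <- setdiff(hits$start, truth$start[truth$motif == "cleavage_ExxR"])
    if (length(bad) == 0L) break
    consensus[bad[1] + 3L] <- "K"
  }
  if (scrub_docking) {
    repeat {
      s <- paste(consensus, collapse = "")
      hits <- scan_motif(stats::setNames(s, "c"), "docking_LVIMPE")
      bad <- setdiff(hits$start, truth$start[truth$motif == "docking_LVIMPE"])
      if (length(bad) == 0L) break
      consensus[bad[1] + 1L] <- "G"
    }
  }
  consensus
}

#' Generate a single-dot intensity time course
#'
#' Emulates the intensity of a separase-substrate dot through meiosis I: a
#' plateau at `plateau` until `decay_start`, then a linear decay to
#' `background` over `decay_duration` minutes (about nine minutes for the
#' degradation observed at anaphase onset), plus optional additive Gaussian
#' noise.
#'
#' @param n_points Number of time points (>= 10).
#' @param dt Sampling interval in minutes.
#' @param plateau Plateau intensity (raw units).
#' @param decay_start Time at which the decay begins (minutes).
#' @param decay_duration Duration of the linear decay (minutes); default 9.
#' @param background Post-decay intensity.
#' @param noise_sigma Additive Gaussian noise s.d.; 0 disables it.
#' @param seed Integer seed.
#' @return List of class `intensity_trace_truth`: `time` (minutes),
#'   `intensity` (raw), and the generating parameters.
#' @section Errors: a decay that does not fit inside the sampled span is an
#'   error.
#' @examples
#' tr <- gen_intensity_trace(seed = 5)
#' nt <- normalize_trace(tr$time, tr$intensity)
#' max(nt$intensity_au)
#' @export
gen_intensity_trace <- function(n_points = 40, dt = 1, plateau = 50,
                                decay_start = 20, decay_duration = 9,
                                background = 0, noise_sigma = 0, seed) {
  stopifnot(is_count(n_points, min = 10L), dt > 0, plateau > background,
            decay_duration > 0, noise_sigma >= 0)
  time <- (seq_len(n_points) - 1) * dt
  if (decay_start + decay_duration > max(time)) {
    stop_meioconj("decay does not fit within the sampled time span",
                  "meioconj_invalid_input")
  }
  frac <- pmin(pmax((time - decay_start) / decay_duration, 0), 1)
  intensity <- plateau + (background - plateau) * frac
  if (noise_sigma > 0) {
    intensity <- with_seed(seed, intensity + stats::rnorm(n_points, 0, noise_sigma))
  }
  structure(
    list(time = time, intensity = intensity, plateau = plateau,
         decay_start = decay_start, decay_duration = decay_duration,
         background = background, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "intensity_trace_truth"
  )
}
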