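# Independent brute-force oracles for the segregation model, written
# directly over elementary assignments and kept free of any package
# internals beyond the public constructors.

# Minimal scenario: the sex pair alone (X red, Y green), both univalent.
xy_only <- function(mII_rule) {
  meiosis_scenario(
    chromosome_pair("XY", conjunction = "univalent_pair",
                    probe = c("red", "green")),
    mII_rule = mII_rule
  )
}

# Brute force over every elementary assignment of the X/Y univalent model:
# poles of the two univalents (2 x 2) and, for random chromatid segregation,
# the spermatid of each of the four chromatids within its pole (2^4).
# Returns the per-spermatid FISH class probabilities.
oracle_xy_classes <- function(mII_rule) {
  grid <- expand.grid(px = 1:2, py = 1:2,
                      x1 = 1:2, x2 = 1:2, y1 = 1:2, y2 = 1:2)
  counts <- c(none = 0, red_only = 0, green_only = 0, both = 0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    x_sp <- integer(0); y_sp <- integer(0)
    if (mII_rule == "regular_sisters") {
      x_sp <- c(2 * g$px - 1, 2 * g$px)       # one X chromatid to each
      y_sp <- c(2 * g$py - 1, 2 * g$py)
    } else {
      x_sp <- c(2 * g$px - 2 + g$x1, 2 * g$px - 2 + g$x2)
      y_sp <- c(2 * g$py - 2 + g$y1, 2 * g$py - 2 + g$y2)
    }
    for (s in 1:4) {
      r <- s %in% x_sp
      gg <- s %in% y_sp
      cls <- if (r && gg) "both" else if (r) "red_only"
             else if (gg) "green_only" else "none"
      counts[cls] <- counts[cls] + 1
    }
  }
  counts / sum(counts)
}

# Brute force over all 2^n pole assignments of n independently segregating
# centromere units: unordered a:b split distribution.
oracle_unit_patterns <- function(n_units) {
  poles <- as.matrix(expand.grid(rep(list(1:2), n_units)))
  at1 <- rowSums(poles == 1)
  a <- pmax(at1, n_units - at1)
  tab <- table(factor(sprintf("%d:%d", a, n_units - a),
                      levels = sprintf("%d:%d",
                                       seq.int(ceiling(n_units / 2), n_units),
                                       n_units - seq.int(ceiling(n_units / 2), n_units))))
  as.numeric(tab) / nrow(poles)
}

# Random valid scenario for property tests (1-3 pairs so that the joint
# support stays small enough to materialize).
random_scenario <- function() {
  n <- sample(1:3, 1)
  pairs <- lapply(seq_len(n), function(i) {
    chromosome_pair(
      paste0("p", i),
      dna_content = stats::runif(2, 0.2, 2),
      conjunction = sample(c("bivalent", "univalent_pair"), 1),
      probe = if (i == 1) c("red", "green") else "none"
    )
  })
  meiosis_scenario(pairs, mII_rule = sample(c("regular_sisters",
                                              "random_chromatids"), 1))
}

# Naive overlapping motif scan by explicit window checks.
oracle_scan <- function(s, motif) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (motif == "cleavage_ExxR") {
    starts <- which(vapply(seq_len(max(n - 3, 0)), function(i) {
      ch[i] %in% c("E", "D") && ch[i + 3] == "R"
    }, logical(1)))
  } else {
    starts <- which(vapply(seq_len(max(n - 2, 0)), function(i) {
      ch[i] %in% c("L", "V", "I", "M") && ch[i + 1] == "P" && ch[i + 2] == "E"
    }, logical(1)))
  }
  as.integer(starts)
}

random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}
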