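# Small deterministic fixtures shared across test files. Everything is
# built in code; no data files.

# 1 taxon, 2 habitats, hand-evaluated: delta_A = 6/7, delta_B = 1/14.
toy_pair_table <- function() {
  tab <- abundance_table(matrix(c(0.2, 0.4, 0.1, 0), 1, 4,
                                dimnames = list("t1",
                                                c("a1", "a2", "b1", "b2"))))
  map <- habitat_map(stats::setNames(c("A", "A", "B", "B"),
                                     c("a1", "a2", "b1", "b2")),
                     level = "diet")
  list(table = tab, map = map)
}

# 3 habitats x 4 samples, taxa with known roles: a perfect specialist of
# habitat h1, a perfect generalist, and a sparse taxon.
toy_landscape <- function() {
  samples <- paste0("s", 1:12)
  hab <- rep(c("h1", "h2", "h3"), each = 4)
  v <- rbind(
    specialist = c(rep(0.3, 4), rep(0, 8)),
    generalist = rep(0.2, 12),
    sparse     = c(0.1, 0, 0, 0, 0.4, 0, 0, 0, 0, 0, 0, 0),
    filler     = rep(0.5, 12))
  colnames(v) <- samples
  tab <- abundance_table(v)
  map <- habitat_map(stats::setNames(hab, samples), level = "class")
  list(table = tab, map = map)
}

# Random non-negative table with a sprinkling of zeros, for properties.
random_table <- function(n_taxa, n_samples, zero_frac = 0.4) {
  v <- matrix(stats::rexp(n_taxa * n_samples), n_taxa, n_samples)
  v[stats::runif(length(v)) < zero_frac] <- 0
  rownames(v) <- paste0("t", seq_len(n_taxa))
  colnames(v) <- paste0("s", seq_len(n_samples))
  abundance_table(v)
}

random_map <- function(table, n_habitats, level = "class") {
  ids <- sample_ids(table)
  lab <- paste0("h", rep_len(seq_len(n_habitats), length(ids)))
  habitat_map(stats::setNames(lab, ids), level = level)
}

# Independent, loop-based evaluation of the specificity definition, kept
# deliberately naive: per taxon and habitat, count detections, average
# abundances, and form prevalence x share by hand.
oracle_specificity <- function(values, labels) {
  habitats <- sort(unique(labels))
  delta <- matrix(0, nrow(values), length(habitats),
                  dimnames = list(rownames(values), habitats))
  for (i in seq_len(nrow(values))) {
    means <- numeric(length(habitats))
    prev <- numeric(length(habitats))
    for (h in seq_along(habitats)) {
      cols <- which(labels == habitats[h])
      prev[h] <- sum(values[i, cols] > 0) / length(cols)
      means[h] <- mean(values[i, cols])
    }
    tot <- sum(means)
    if (tot > 0)
      for (h in seq_along(habitats))
        delta[i, h] <- prev[h] * means[h] / tot
  }
  delta
}

# Naive Hill number for the diversity oracle.
oracle_hill <- function(delta, q) {
  if (sum(delta) == 0) return(0)
  lam <- delta / sum(delta)
  lam <- lam[lam > 0]
  if (q == 0) length(lam)
  else if (q == 1) exp(-sum(lam * log(lam)))
  else sum(lam^q)^(1 / (1 - q))
}

# Exhaustive SP exceedance probability for tiny m + n via all C(m+n, m)
# splits, computed with the naive two-group specificity formula.
oracle_sp_exceedance <- function(values, in_A) {
  labels <- ifelse(in_A, "A", "B")
  obs <- oracle_specificity(values, labels)
  obs_diff <- abs(obs[, "A"] - obs[, "B"])
  n_tot <- ncol(values)
  m <- sum(in_A)
  splits <- utils::combn(n_tot, m)
  exceed <- matrix(FALSE, nrow(values), ncol(splits))
  for (k in seq_len(ncol(splits))) {
    lab_k <- rep("B", n_tot)
    lab_k[splits[, k]] <- "A"
    d <- oracle_specificity(values, lab_k)
    exceed[, k] <- abs(d[, "A"] - d[, "B"]) > obs_diff
  }
  stats::setNames(rowMeans(exceed), rownames(values))
}
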