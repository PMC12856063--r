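#' Generate a null (habitat-free) community table
#'
#' Every taxon's abundances are drawn i.i.d. across all samples with no
#' habitat effect: presence with a per-taxon detection probability, and,
#' when present, a lognormal abundance draw (lognormal base abundances
#' with partial detection give the strongly left-skewed specificity
#' distributions typical of real surveys). Samples are then normalized to
#' relative abundances. Detection is modelled separately from abundance
#' so that prevalence and abundance share can be manipulated
#' independently by the planted generator.
#'
#' @param n_taxa number of taxa (default 200).
#' @param habitats habitat labels (default two, "A" and "B").
#' @param samples_per_habitat samples per habitat (default 10).
#' @param seed RNG seed (required: generators are seed-deterministic).
#' @param detection_range per-taxon detection probabilities are drawn
#'   uniformly from this interval (default c(0.2, 0.8)).
#' @param meanlog_sd spread of per-taxon lognormal location parameters
#'   (default 1).
#' @param sdlog lognormal scale of within-taxon abundance noise
#'   (default 1).
#' @param level habitat level recorded in the map (default "host_species").
#' @return list with `table` (normalized `ssd_table`), `map`
#'   (`habitat_map`), and `seed`.
#' @export
generate_null <- function(n_taxa = 200, habitats = c("A", "B"),
                          samples_per_habitat = 10, seed,
                          detection_range = c(0.2, 0.8),
                          meanlog_sd = 1, sdlog = 1,
                          level = "host_species") {
  if (n_taxa < 1 || samples_per_habitat < 1 || length(habitats) < 1)
    stop("sizes must be >= 1")
  set.seed(seed)
  n_samples <- length(habitats) * samples_per_habitat
  det <- stats::runif(n_taxa, detection_range[1], detection_range[2])
  mu <- stats::rnorm(n_taxa, 0, meanlog_sd)
  pres <- matrix(stats::rbinom(n_taxa * n_samples, 1, rep(det, n_samples)),
                 n_taxa, n_samples)
  ab <- matrix(stats::rlnorm(n_taxa * n_samples, rep(mu, n_samples), sdlog),
               n_taxa, n_samples)
  values <- pres * ab
  rownames(values) <- sprintf("taxon_%03d", seq_len(n_taxa))
  colnames(values) <- sprintf("s_%s_%02d", rep(habitats, each = samples_per_habitat),
                              rep(seq_len(samples_per_habitat), length(habitats)))
  tab <- suppressWarnings(normalize_relative(abundance_table(values)))
  map <- habitat_map(stats::setNames(rep(habitats, each = samples_per_habitat),
                                     colnames(values)), level = level)
  list(table = tab, map = map, seed = seed)
}

#' Generate a table with planted unique and enriched taxa
#'
#' Plants known ground truth on top of the null model: unique taxa are
#' present in every sample of their target habitat (prevalence 1 there)
#' and absent everywhere else; enriched taxa are present in every sample
#' of every habitat but with their mean abundance multiplied by `fold` in
#' the target habitat; all remaining taxa follow the null model. Target
#' habitats are assigned round-robin so that, with two habitats, both
#' sides receive planted signals. The returned truth table fully
#' determines the expected SP-test categories for strong effects.
#'
#' @inheritParams generate_null
#' @param n_taxa total number of taxa (default 100).
#' @param n_unique,n_enriched numbers of planted unique / enriched taxa
#'   (defaults 20 and 20); their sum must not exceed `n_taxa`.
#' @param fold abundance multiplier in the target habitat for enriched
#'   taxa (default 8).
#' @return list with `table`, `map`, `truth` (data.frame taxon, role,
#'   target), and `seed`.
#' @export
generate_planted <- function(n_taxa = 100, habitats = c("A", "B"),
                             samples_per_habitat = 10,
                             n_unique = 20, n_enriched = 20, fold = 8,
                             seed, detection_range = c(0.2, 0.8),
                             meanlog_sd = 1, sdlog = 1,
                             level = "host_species") {
  if (n_unique + n_enriched > n_taxa)
    stop("n_unique + n_enriched must not exceed n_taxa")
  base <- generate_null(n_taxa, habitats, samples_per_habitat, seed,
                        detection_range, meanlog_sd, sdlog, level)
  values <- base$table$values
  # rebuild on the raw scale so planted effects survive renormalization
  set.seed(seed + 1L)
  n_samples <- ncol(values)
  mu <- stats::rnorm(n_taxa, 0, meanlog_sd)
  raw <- matrix(stats::rlnorm(n_taxa * n_samples, rep(mu, n_samples), sdlog),
                n_taxa, n_samples, dimnames = dimnames(values))
  det <- stats::runif(n_taxa, detection_range[1], detection_range[2])
  pres <- matrix(stats::rbinom(n_taxa * n_samples, 1, rep(det, n_samples)),
                 n_taxa, n_samples)
  labels <- base$map$assignments[colnames(values)]
  roles <- rep("noise", n_taxa)
  targets <- rep(NA_character_, n_taxa)
  idx_u <- seq_len(n_unique)
  idx_e <- n_unique + seq_len(n_enriched)
  roles[idx_u] <- "unique"
  roles[idx_e] <- "enriched"
  targets[c(idx_u, idx_e)] <-
    habitats[((seq_len(n_unique + n_enriched) - 1) %% length(habitats)) + 1]
  for (i in c(idx_u, idx_e)) {
    in_target <- labels == targets[i]
    if (roles[i] == "unique") {
      pres[i, ] <- as.numeric(in_target)       # prevalence 1 in target only
    } else {
      pres[i, ] <- 1                           # present everywhere
      raw[i, in_target] <- raw[i, in_target] * fold
    }
  }
  out <- raw * pres
  tab <- suppressWarnings(normalize_relative(abundance_table(out)))
  truth <- data.frame(taxon = rownames(out), role = roles, target = targets,
                      stringsAsFactors = FALSE)
  attr(truth, "fold") <- fold
  list(table = tab, map = base$map, truth = truth, seed = seed)
}

#' Generate phylogenetic-timeline vs specificity-diversity pairs
#'
#' SD values are drawn log-uniformly on `sd_range`; PT follows the power
#' law with multiplicative lognormal noise:
#' `PT = exp(ln_a + b * ln(SD) + eps)`, `eps ~ Normal(0, noise_sd)`.
#'
#' @param n_species number of host species (default 60).
#' @param ln_a,b power-law parameters (intercept on the log scale and
#'   scaling exponent).
#' @param noise_sd standard deviation of the log-scale noise (>= 0).
#' @param sd_range positive range for the SD draw (default c(1, 100)).
#' @param seed RNG seed (required).
#' @return data.frame with `host_species`, `sd`, `pt`; attributes record
#'   the generating parameters and seed.
#' @export
generate_ptsd <- function(n_species = 60, ln_a = log(2), b = -0.8,
                          noise_sd = 0.3, sd_range = c(1, 100), seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(sd_range) != 2 || any(sd_range <= 0) || sd_range[1] >= sd_range[2])
    stop("sd_range must be a positive increasing pair")
  set.seed(seed)
  sd <- exp(stats::runif(n_species, log(sd_range[1]), log(sd_range[2])))
  eps <- stats::rnorm(n_species, 0, noise_sd)
  pt <- exp(ln_a + b * log(sd) + eps)
  structure(data.frame(host_species = sprintf("host_%03d", seq_len(n_species)),
                       sd = sd, pt = pt),
            ln_a = ln_a, b = b, noise_sd = noise_sd, seed = seed)
}
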