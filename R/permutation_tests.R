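#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: sort, multiply each p by m/rank, then take
#' the cumulative minimum from the largest rank down and cap at 1. Kept as
#' an explicit implementation (rather than delegating) so tests can check
#' it against an independent oracle.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, same order as input; always `>= p`.
#' @export
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / (m:1)))[ro]
  q
}

#' Classify a taxon from its two-treatment specificities
#'
#' Five-way rule on the pair of specificity values and the (possibly
#' FDR-adjusted) p-value:
#' * `US_A`: p <= alpha, delta_B = 0, delta_A > 0 (unique to A)
#' * `US_B`: symmetric
#' * `ES_A`: p <= alpha, delta_B > 0, delta_A > delta_B (enriched in A)
#' * `ES_B`: symmetric
#' * `indifferent`: everything else (in particular all p > alpha)
#'
#' @param delta_A,delta_B specificity of the taxon in each treatment
#'   (vectorized).
#' @param pseudo_p p-value(s) used for the significance gate.
#' @param alpha significance level (default 0.05).
#' @return character vector of category labels.
#' @export
classify_taxon <- function(delta_A, delta_B, pseudo_p, alpha = 0.05) {
  stopifnot(all(is.finite(delta_A)), all(is.finite(delta_B)),
            all(is.finite(pseudo_p)))
  sig <- pseudo_p <= alpha
  out <- rep("indifferent", length(delta_A))
  out[sig & delta_B == 0 & delta_A > 0] <- "US_A"
  out[sig & delta_A == 0 & delta_B > 0] <- "US_B"
  out[sig & delta_B > 0 & delta_A > delta_B] <- "ES_A"
  out[sig & delta_A > 0 & delta_B > delta_A] <- "ES_B"
  out
}

# Shared set-up for sp_test/sdp_test: pool two treatment tables, normalize
# per sample, canonicalize column order by sample id (so swapping the A/B
# argument order with equal group sizes and the same seed reproduces the
# identical permutation splits), and drop taxa absent from both sides.
.pool_pair <- function(table_A, table_B) {
  va <- if (inherits(table_A, "ssd_table")) table_A$values else as.matrix(table_A)
  vb <- if (inherits(table_B, "ssd_table")) table_B$values else as.matrix(table_B)
  if (!identical(rownames(va), rownames(vb)))
    stop("the two treatments must share the same taxon universe (row ids)")
  if (ncol(va) == 0 || ncol(vb) == 0)
    stop("both treatment groups must contain at least one sample")
  if (length(intersect(colnames(va), colnames(vb))))
    stop("sample ids overlap between treatments")
  pooled <- cbind(va, vb)
  pooled <- suppressWarnings(normalize_relative(abundance_table(pooled)))$values
  ord <- order(colnames(pooled))
  pooled <- pooled[, ord, drop = FALSE]
  in_A <- colnames(pooled) %in% colnames(va)
  dropped <- rownames(pooled)[rowSums(pooled) == 0]
  keep <- rowSums(pooled) > 0
  list(values = pooled[keep, , drop = FALSE], in_A = in_A,
       m = ncol(va), n = ncol(vb), dropped = dropped)
}

# K random splits of m+n pooled samples into first-m/last-n, as a 0/1
# samples x K membership indicator for the simulated A side.
.perm_indicator <- function(n_samples, m, n_perm) {
  ind <- matrix(0, n_samples, n_perm)
  for (k in seq_len(n_perm)) ind[sample.int(n_samples, m), k] <- 1
  ind
}

.resolve_seed <- function(seed) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("no seed supplied; drew seed ", seed)
  }
  set.seed(seed)
  seed
}

#' Specificity permutation (SP) test between two treatments
#'
#' Per-taxon permutation test of the absolute specificity difference
#' between two treatments A and B. Specificity is recomputed with H = 2
#' over exactly these two sample groups. The observed difference
#' `|delta_A - delta_B|` is compared with the differences obtained by
#' pooling the m + n samples, re-splitting them at random into simulated
#' groups of the same sizes `n_perm` times, and recomputing both
#' specificity lists. The pseudo p-value is T / n_perm, where T counts
#' permutations whose simulated difference strictly exceeds the observed
#' one (ties count as non-exceedance). Taxa are then classified with
#' [classify_taxon()], by default on the FDR-adjusted p-values.
#'
#' @param table_A,table_B `ssd_table` (or plain matrix) for each
#'   treatment, sharing the same taxon rows. Taxa absent from both groups
#'   are dropped and recorded in the `dropped` attribute.
#' @param n_perm number of random re-splits (default 1000).
#' @param alpha significance level for classification (default 0.05).
#' @param seed RNG seed; drawn (and reported) if NULL. Identical seeds
#'   give bit-identical results.
#' @param use_fdr classify on FDR-adjusted q-values (default TRUE); set
#'   FALSE to gate on raw pseudo p-values.
#' @param detection_threshold presence cutoff for prevalence.
#' @param plus_one use the (T + 1) / (n_perm + 1) pseudo-p correction
#'   instead of the literal T / n_perm (default FALSE).
#' @param midp count ties as half-exceedances (default FALSE).
#' @return data.frame of class `sp_result` with columns `taxon`,
#'   `delta_A`, `delta_B`, `obs_diff`, `T`, `pseudo_p`, `q_value`,
#'   `category`; attributes record seed, group sizes, labels and dropped
#'   taxa.
#' @export
sp_test <- function(table_A, table_B, n_perm = 1000, alpha = 0.05,
                    seed = NULL, use_fdr = TRUE, detection_threshold = 0,
                    plus_one = FALSE, midp = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  pool <- .pool_pair(table_A, table_B)
  seed <- .resolve_seed(seed)
  obs <- .two_group_delta(pool$values, matrix(as.numeric(pool$in_A)),
                          pool$m, pool$n, detection_threshold)
  delta_A <- drop(obs$delta_A)
  delta_B <- drop(obs$delta_B)
  obs_diff <- abs(delta_A - delta_B)

  ind <- .perm_indicator(ncol(pool$values), pool$m, n_perm)
  sim <- .two_group_delta(pool$values, ind, pool$m, pool$n,
                          detection_threshold)
  diff_k <- abs(sim$delta_A - sim$delta_B)
  if (midp) {
    tied <- abs(diff_k - obs_diff) < 1e-12
    T_cnt <- rowSums(diff_k > obs_diff & !tied) + 0.5 * rowSums(tied)
  } else {
    T_cnt <- rowSums(diff_k > obs_diff)
  }
  pseudo_p <- if (plus_one) (T_cnt + 1) / (n_perm + 1) else T_cnt / n_perm
  q_value <- fdr_adjust(pseudo_p)
  category <- classify_taxon(delta_A, delta_B,
                             if (use_fdr) q_value else pseudo_p, alpha)
  res <- data.frame(taxon = rownames(pool$values),
                    delta_A = delta_A, delta_B = delta_B,
                    obs_diff = obs_diff, T = T_cnt,
                    pseudo_p = pseudo_p, q_value = q_value,
                    category = category, row.names = NULL)
  structure(res, class = c("sp_result", "data.frame"),
            n_perm = n_perm, alpha = alpha, seed = seed,
            use_fdr = use_fdr, m = pool$m, n = pool$n,
            dropped = pool$dropped)
}

# The six assemblage categories scored by the SDP test. "significant" is
# the union of the four US/ES categories; "all" is every retained taxon.
.sdp_categories <- c("US_A", "US_B", "ES_A", "ES_B", "significant", "all")

#' Specificity-diversity permutation (SDP) test
#'
#' Assemblage-level companion of [sp_test()]: for each of six species
#' categories (unique in A, unique in B, enriched in A, enriched in B,
#' all significantly different, all taxa) and each diversity order q, the
#' observed statistic is `|qSD_A - qSD_B|`, the absolute difference of
#' the specificity-diversity Hill numbers of the two treatments' own
#' specificity lists restricted to the category. Category memberships are
#' FIXED from the observed SP classification; each permutation re-splits
#' the pooled samples, recomputes both specificity lists, and re-evaluates
#' both Hill numbers on the fixed membership. Pseudo-p is again the
#' fraction of permutations strictly exceeding the observed difference.
#'
#' At q = 0 the US and ES rows are structurally trivial (for a US
#' category the absent treatment's richness is 0; for ES both richness
#' values are equal); these rows are flagged `trivial = TRUE`.
#'
#' @inheritParams sp_test
#' @param sp_result the `sp_result` computed on the same pair of tables;
#'   defines the category memberships.
#' @param orders diversity orders to test (default 0:4).
#' @return data.frame of class `sdp_result` with one row per category x
#'   order: `category`, `q`, `n_taxa`, `sd_A`, `sd_B`, `obs_diff`,
#'   `T`, `pseudo_p`, `q_value`, `applicable`, `trivial`. Empty
#'   categories yield rows with `applicable = FALSE` and NA statistics.
#' @export
sdp_test <- function(table_A, table_B, sp_result, orders = 0:4,
                     n_perm = 1000, seed = NULL, alpha = 0.05,
                     detection_threshold = 0) {
  stopifnot(inherits(sp_result, "sp_result"))
  if (any(orders < 0)) stop("diversity orders must be >= 0")
  pool <- .pool_pair(table_A, table_B)
  if (!identical(sp_result$taxon, rownames(pool$values)))
    stop("sp_result does not match this pair of tables (taxon sets differ)")
  seed <- .resolve_seed(seed)

  members <- list(
    US_A = sp_result$category == "US_A",
    US_B = sp_result$category == "US_B",
    ES_A = sp_result$category == "ES_A",
    ES_B = sp_result$category == "ES_B",
    significant = sp_result$category != "indifferent",
    all = rep(TRUE, nrow(sp_result)))

  obs <- .two_group_delta(pool$values, matrix(as.numeric(pool$in_A)),
                          pool$m, pool$n, detection_threshold)
  ind <- .perm_indicator(ncol(pool$values), pool$m, n_perm)
  sim <- .two_group_delta(pool$values, ind, pool$m, pool$n,
                          detection_threshold)

  rows <- lapply(.sdp_categories, function(cat) {
    sel <- members[[cat]]
    if (!any(sel)) {
      return(data.frame(category = cat, q = orders, n_taxa = 0L,
                        sd_A = NA_real_, sd_B = NA_real_,
                        obs_diff = NA_real_, T = NA_integer_,
                        pseudo_p = NA_real_,
                        applicable = FALSE))
    }
    sd_A <- .hill_cols(obs$delta_A[sel, , drop = FALSE], orders)[, 1]
    sd_B <- .hill_cols(obs$delta_B[sel, , drop = FALSE], orders)[, 1]
    d_obs <- abs(sd_A - sd_B)
    dA_k <- .hill_cols(sim$delta_A[sel, , drop = FALSE], orders)
    dB_k <- .hill_cols(sim$delta_B[sel, , drop = FALSE], orders)
    T_cnt <- rowSums(abs(dA_k - dB_k) > d_obs)
    data.frame(category = cat, q = orders, n_taxa = sum(sel),
               sd_A = sd_A, sd_B = sd_B, obs_diff = d_obs,
               T = as.integer(T_cnt), pseudo_p = T_cnt / n_perm,
               applicable = TRUE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  ok <- res$applicable
  res$q_value[ok] <- fdr_adjust(res$pseudo_p[ok])
  res$trivial <- res$q == 0 &
    res$category %in% c("US_A", "US_B", "ES_A", "ES_B")
  rownames(res) <- NULL
  structure(res, class = c("sdp_result", "data.frame"),
            n_perm = n_perm, alpha = alpha, seed = seed,
            m = pool$m, n = pool$n)
}

#' Exclusively unique species catalogue (presence XOR)
#'
#' A taxon is exclusively unique to habitat h when it is detected in at
#' least one sample of h and in no sample of any other habitat at the
#' chosen level -- an XOR over the per-habitat presence sets across the
#' whole landscape. The per-habitat lists are therefore pairwise
#' disjoint. This is a landscape-wide, test-free catalogue, distinct from
#' the pairwise unique-species calls of [sp_test()].
#'
#' @param table an `ssd_table`.
#' @param map a `habitat_map`.
#' @param detection_threshold presence cutoff (default 0).
#' @return named list (class `eus_catalogue`), one character vector of
#'   taxon ids per habitat.
#' @export
exclusively_unique_species <- function(table, map, detection_threshold = 0) {
  chk <- .check_map(table, map)
  pres <- .group_prevalence(table$values, chk$labels, chk$habitats,
                            detection_threshold) > 0
  n_hab <- rowSums(pres)
  out <- lapply(chk$habitats, function(h)
    rownames(pres)[pres[, h] & n_hab == 1])
  names(out) <- chk$habitats
  structure(out, class = "eus_catalogue")
}

#' @export
print.eus_catalogue <- function(x, ...) {
  sizes <- lengths(unclass(x))
  cat(sprintf("eus_catalogue: %d exclusively unique taxa over %d habitats\n",
              sum(sizes), length(sizes)))
  for (h in names(x)) cat(sprintf("  %s: %d\n", h, sizes[[h]]))
  invisible(x)
}

#' Volcano table from an SP test
#'
#' Plot-ready table: x = log10 fold change of specificity
#' (treatment A over treatment B), y = -log10 pseudo-p, coloured by
#' category. Taxa whose denominator specificity is zero have an infinite
#' fold change and are flagged in `fc_class` (`plus_inf` / `minus_inf` /
#' `undefined`) rather than forced to a number; the significance
#' reference line is at -log10(alpha) (1.301 for alpha = 0.05).
#'
#' @param sp_result an `sp_result`.
#' @return data.frame with `taxon`, `log10_fc`, `neg_log10_p`,
#'   `category`, `fc_class`; attribute `ref_line` holds -log10(alpha).
#' @export
volcano_table <- function(sp_result) {
  stopifnot(inherits(sp_result, "sp_result"))
  a <- sp_result$delta_A
  b <- sp_result$delta_B
  fc_class <- rep("finite", length(a))
  fc_class[b == 0 & a > 0] <- "plus_inf"
  fc_class[a == 0 & b > 0] <- "minus_inf"
  fc_class[a == 0 & b == 0] <- "undefined"
  log10_fc <- ifelse(fc_class == "finite", log10(a / b), NA_real_)
  structure(data.frame(taxon = sp_result$taxon,
                       log10_fc = log10_fc,
                       neg_log10_p = -log10(sp_result$pseudo_p),
                       category = sp_result$category,
                       fc_class = fc_class),
            ref_line = -log10(attr(sp_result, "alpha")),
            class = c("volcano_table", "data.frame"))
}
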