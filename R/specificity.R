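#' Per-habitat prevalence of each taxon
#'
#' `A[i, h]` is the fraction of habitat `h`'s samples in which taxon `i`
#' is detected (abundance strictly above `detection_threshold`, which
#' defaults to 0: any positive abundance counts as presence).
#'
#' @param table a normalized `ssd_table`.
#' @param map a `habitat_map`.
#' @param detection_threshold presence cutoff; a sample counts toward
#'   prevalence when abundance > threshold.
#' @return taxa x habitats numeric matrix with entries in \[0, 1\].
#' @export
habitat_prevalence <- function(table, map, detection_threshold = 0) {
  chk <- .check_map(table, map)
  .group_prevalence(table$values, chk$labels, chk$habitats,
                    detection_threshold)
}

.group_prevalence <- function(values, labels, habitats, thr = 0) {
  out <- vapply(habitats, function(h) {
    cols <- labels == h
    if (!any(cols)) stop("habitat with zero samples: ", h)
    rowMeans(values[, cols, drop = FALSE] > thr)
  }, numeric(nrow(values)))
  out <- matrix(out, nrow = nrow(values),
                dimnames = list(rownames(values), habitats))
  out
}

#' Per-habitat mean abundance of each taxon
#'
#' The arithmetic mean of relative abundance over all samples of the
#' habitat, zeros included (samples where the taxon is absent pull the
#' mean down; they are part of the habitat).
#'
#' @inheritParams habitat_prevalence
#' @return taxa x habitats matrix of mean relative abundances.
#' @export
habitat_mean_abundance <- function(table, map) {
  chk <- .check_map(table, map)
  .group_means(table$values, chk$labels, chk$habitats)
}

.group_means <- function(values, labels, habitats) {
  out <- vapply(habitats, function(h) {
    cols <- labels == h
    if (!any(cols)) stop("habitat with zero samples: ", h)
    rowMeans(values[, cols, drop = FALSE])
  }, numeric(nrow(values)))
  matrix(out, nrow = nrow(values),
         dimnames = list(rownames(values), habitats))
}

#' Species specificity: prevalence times abundance share
#'
#' For taxon i and habitat h, specificity is
#' \deqn{\Delta_{ih} = A_{ih} \times B_{ih}}
#' where \eqn{A_{ih}} is the prevalence of i in h (fraction of h's samples
#' where i is detected) and \eqn{B_{ih} = \langle a_i\rangle_h / \sum_h
#' \langle a_i\rangle_h} is habitat h's share of the taxon's summed mean
#' abundances across all habitats. \eqn{\Delta_{ih} \in [0, 1]}: 0 means
#' absent from h, 1 means the taxon is found in every sample of h and
#' nowhere else (a perfect indicator / extreme specialist). An extreme
#' generalist (prevalence 1, equal abundance everywhere) scores 1/H.
#'
#' Taxa whose mean abundance is zero in every habitat have an undefined
#' share; their specificity is set to 0 in all habitats and their ids are
#' returned in `zero_total`, so downstream entropy code never sees NaN.
#'
#' @param table an `ssd_table`; normalized automatically unless
#'   `normalize = FALSE` (the abundance-share term is only comparable
#'   across habitats after per-sample normalization).
#' @param map a `habitat_map` with at least two habitats.
#' @param detection_threshold presence cutoff for the prevalence term.
#' @param normalize call [normalize_relative()] first (default TRUE).
#' @return object of class `specificity_matrix`: list with `delta`, `A`,
#'   `B` (taxa x habitats matrices), `zero_total` (taxon ids with zero
#'   total abundance), `level`.
#' @export
compute_specificity <- function(table, map, detection_threshold = 0,
                                normalize = TRUE) {
  chk <- .check_map(table, map)
  if (length(chk$habitats) < 2)
    stop("specificity requires H >= 2 habitats (alternative habitats needed)")
  if (normalize && !table$normalized)
    table <- suppressWarnings(normalize_relative(table))
  A <- .group_prevalence(table$values, chk$labels, chk$habitats,
                         detection_threshold)
  m <- .group_means(table$values, chk$labels, chk$habitats)
  tot <- rowSums(m)
  B <- m / ifelse(tot > 0, tot, 1)
  B[tot == 0, ] <- 0
  delta <- A * B
  structure(list(delta = delta, A = A, B = B,
                 zero_total = rownames(delta)[tot == 0],
                 level = map$level),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("specificity_matrix: %d taxa x %d habitats (level '%s')\n",
              nrow(x$delta), ncol(x$delta), x$level))
  if (length(x$zero_total))
    cat(sprintf("  %d taxa with zero total abundance (delta = 0 everywhere)\n",
                length(x$zero_total)))
  invisible(x)
}

#' Write a specificity matrix as a long TSV
#'
#' One row per (taxon, habitat): `taxon_id`, `habitat`, `A`, `B`, `delta`.
#' @param spec a `specificity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specificity <- function(spec, path) {
  stopifnot(inherits(spec, "specificity_matrix"))
  df <- data.frame(
    taxon_id = rep(rownames(spec$delta), times = ncol(spec$delta)),
    habitat = rep(colnames(spec$delta), each = nrow(spec$delta)),
    A = as.vector(spec$A), B = as.vector(spec$B),
    delta = as.vector(spec$delta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Two-group specificity lists, vectorized over many permutation splits.
#
# values: taxa x samples matrix (already per-sample normalized).
# indA:   samples x K 0/1 indicator of membership in group A per split.
# m, n:   group sizes (constant over splits).
# thr:    detection threshold.
# Returns list(delta_A, delta_B): taxa x K matrices. This is the engine
# behind sp_test/sdp_test: prevalence and mean terms for every split are
# obtained with two matrix products instead of a per-permutation loop.
.two_group_delta <- function(values, indA, m, n, thr = 0) {
  # both groups go through the same product so that relabeling A and B
  # (with equal sizes) is bit-exact -- important because strict-exceedance
  # tie handling is sensitive to last-ulp differences
  P <- (values > thr) * 1
  presA <- P %*% indA
  presB <- P %*% (1 - indA)
  sumA <- values %*% indA
  sumB <- values %*% (1 - indA)
  A_A <- presA / m
  A_B <- presB / n
  meanA <- sumA / m
  meanB <- sumB / n
  tot <- meanA + meanB
  tot[tot == 0] <- 1  # zero-total taxa: shares (and deltas) stay 0
  list(delta_A = A_A * (meanA / tot),
       delta_B = A_B * (meanB / tot))
}
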