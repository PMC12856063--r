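#' Fit the phylogenetic-timeline vs specificity-diversity power law
#'
#' Fits \eqn{PT = a \cdot SD^{b}} through its log-log linear form
#' \eqn{\ln PT = \ln a + b \ln SD} by ordinary least squares (natural
#' logarithms). PT is the host taxon's evolutionary age in million years;
#' a negative exponent b means more modern hosts carry higher specificity
#' diversity. Pairs with non-positive or missing PT or SD cannot be
#' log-transformed; they are excluded and reported in the `excluded`
#' attribute.
#'
#' @param pt positive phylogenetic-timeline values (million years), named
#'   or parallel to `sd`.
#' @param sd positive specificity-diversity values, same length.
#' @param group label for this fit (a diet type, or "combined").
#' @return object of class `ptsd_fit`: list with `ln_a`, `b`, `se_ln_a`,
#'   `se_b`, `p_slope` (two-sided), `r_squared`, `n`, `group`, and the
#'   underlying `lm` fit; `attr(, "excluded")` lists dropped indices.
#' @export
fit_ptsd <- function(pt, sd, group = "combined") {
  if (length(pt) != length(sd)) stop("pt and sd must have the same length")
  bad <- !is.finite(pt) | !is.finite(sd) | pt <= 0 | sd <= 0
  pt_u <- pt[!bad]
  sd_u <- sd[!bad]
  if (length(pt_u) < 3)
    stop("need at least 3 usable (PT, SD) pairs after exclusions; have ",
         length(pt_u))
  fit <- stats::lm(log(pt_u) ~ log(sd_u))
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(ln_a = unname(co[1, 1]), b = unname(co[2, 1]),
                 se_ln_a = unname(co[1, 2]), se_b = unname(co[2, 2]),
                 p_slope = unname(co[2, 4]),
                 r_squared = sm$r.squared,
                 n = length(pt_u), group = group, lm = fit),
            excluded = which(bad), class = "ptsd_fit")
}

#' @export
print.ptsd_fit <- function(x, ...) {
  cat(sprintf("ptsd_fit [%s]: PT = %.4g * SD^%.4g  (n = %d)\n",
              x$group, exp(x$ln_a), x$b, x$n))
  cat(sprintf("  ln a = %.4f (se %.4f), b = %.4f (se %.4f), p = %.3g, R2 = %.3f\n",
              x$ln_a, x$se_ln_a, x$b, x$se_b, x$p_slope, x$r_squared))
  invisible(x)
}

#' Predict PT from SD under a fitted power law
#'
#' @param fit a `ptsd_fit`.
#' @param sd positive specificity-diversity value(s).
#' @return predicted PT, `exp(ln_a) * sd^b`.
#' @export
predict_pt <- function(fit, sd) {
  stopifnot(inherits(fit, "ptsd_fit"))
  if (any(!is.finite(sd) | sd <= 0)) stop("sd must be positive")
  exp(fit$ln_a) * sd^fit$b
}

#' Per-host specificity diversity
#'
#' For a specificity matrix computed at host-species level, the
#' specificity-diversity Hill number of each host's assemblage of
#' specificity values (its column of the delta matrix) at order q. Hosts
#' with no detected taxa (sd = 0) are reported but should be excluded
#' from power-law fits, which [fit_ptsd()] does automatically.
#'
#' @param spec a `specificity_matrix` whose habitats are host species.
#' @param q diversity order (default 1).
#' @return data.frame with `host_species` and `sd`.
#' @export
per_species_sd <- function(spec, q = 1) {
  stopifnot(inherits(spec, "specificity_matrix"))
  sd <- apply(spec$delta, 2, specificity_diversity, q = q)
  data.frame(host_species = colnames(spec$delta), sd = unname(sd),
             row.names = NULL)
}

#' Fit the power law per group plus a combined fit
#'
#' One [fit_ptsd()] per group label (typically the three diet types)
#' followed by a combined fit over all hosts. Groups left with fewer than
#' 3 usable pairs are skipped with a message.
#'
#' @param pt named numeric vector of PT values (names = host species).
#' @param sd_table data.frame from [per_species_sd()].
#' @param groups named character vector mapping host species to a group
#'   label (e.g., diet type), or NULL for a combined fit only.
#' @return named list of `ptsd_fit` (one per group and `"combined"`).
#' @export
fit_ptsd_groups <- function(pt, sd_table, groups = NULL) {
  hosts <- intersect(sd_table$host_species, names(pt))
  sd_v <- stats::setNames(sd_table$sd, sd_table$host_species)[hosts]
  pt_v <- pt[hosts]
  fits <- list()
  if (!is.null(groups)) {
    for (g in sort(unique(unname(groups[hosts])))) {
      sel <- hosts[groups[hosts] == g & !is.na(groups[hosts])]
      f <- tryCatch(fit_ptsd(pt_v[sel], sd_v[sel], group = g),
                    error = function(e) {
                      message("skipping group '", g, "': ", conditionMessage(e))
                      NULL
                    })
      if (!is.null(f)) fits[[g]] <- f
    }
  }
  fits[["combined"]] <- fit_ptsd(pt_v, sd_v, group = "combined")
  fits
}

#' Summarise power-law fits as a table
#' @param fits list of `ptsd_fit` (e.g., from [fit_ptsd_groups()]).
#' @return data.frame with group, n, ln_a, b, se_b, p_slope, r_squared.
#' @export
ptsd_summary <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(group = f$group, n = f$n, ln_a = f$ln_a, b = f$b,
               se_b = f$se_b, p_slope = f$p_slope,
               r_squared = f$r_squared, row.names = NULL)))
}
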