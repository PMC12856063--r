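#' Relative specificities of an assemblage
#'
#' Rescales a vector of specificity values to sum to 1:
#' \eqn{\lambda_i = \Delta_i / \sum_i \Delta_i}. If every specificity is
#' zero the assemblage is degenerate and an all-zero vector is returned
#' with attribute `degenerate = TRUE`.
#'
#' @param delta numeric vector of non-negative specificity values.
#' @return numeric vector summing to 1 (or all zeros when degenerate),
#'   with a logical `degenerate` attribute.
#' @export
relative_specificities <- function(delta) {
  if (anyNA(delta) || any(delta < 0))
    stop("specificity values must be non-negative and non-missing")
  s <- sum(delta)
  if (s == 0) return(structure(delta, degenerate = TRUE))
  structure(delta / s, degenerate = FALSE)
}

#' Specificity diversity (Hill number of a specificity distribution)
#'
#' The Hill number of order `q` of the relative specificities
#' \eqn{\lambda_i}:
#' \deqn{{}^qSD = \Big(\sum_{\lambda_i > 0} \lambda_i^q\Big)^{1/(1-q)}}
#' with the Shannon limit \eqn{\exp(-\sum \lambda_i \ln \lambda_i)} at
#' q = 1. Zero terms are dropped (0 ln 0 := 0). At q = 0 this is the
#' count of taxa with positive specificity (richness); increasing q
#' weights high-specificity taxa more, so the profile is non-increasing
#' in q. An all-zero assemblage has diversity 0 by convention, so empty
#' treatment sides remain representable.
#'
#' @param delta non-negative specificity values of the assemblage.
#' @param q diversity order, a non-negative real.
#' @return the effective number of taxa (a single non-negative real).
#' @export
specificity_diversity <- function(delta, q) {
  if (length(q) != 1 || is.na(q) || q < 0) stop("q must be a single real >= 0")
  lam <- relative_specificities(delta)
  if (attr(lam, "degenerate")) return(0)
  lam <- lam[lam > 0]
  if (q == 0) return(length(lam))
  # near q = 1 the closed form is numerically unstable; use the limit
  if (abs(q - 1) < 1e-10) return(exp(-sum(lam * log(lam))))
  sum(lam^q)^(1 / (1 - q))
}

#' Specificity-diversity profile over a grid of orders
#'
#' @param delta non-negative specificity values.
#' @param orders vector of diversity orders (default 0:4).
#' @return data.frame of class `sd_profile` with columns `q` and `sd`, and
#'   attributes `assemblage_size` (S, including zero-specificity taxa) and
#'   `n_positive` (taxa with positive specificity).
#' @export
sd_profile <- function(delta, orders = 0:4) {
  sd <- vapply(orders, function(q) specificity_diversity(delta, q),
               numeric(1))
  structure(data.frame(q = orders, sd = sd),
            assemblage_size = length(delta),
            n_positive = sum(delta > 0),
            class = c("sd_profile", "data.frame"))
}

# Hill numbers column-wise over a delta matrix (taxa x K), one value per
# column per order. Used by the permutation engine, where K = n_perm.
.hill_cols <- function(delta_mat, orders) {
  s <- colSums(delta_mat)
  pos <- s > 0
  lam <- sweep(delta_mat, 2, ifelse(pos, s, 1), "/")
  out <- matrix(0, nrow = length(orders), ncol = ncol(delta_mat),
                dimnames = list(as.character(orders), NULL))
  for (r in seq_along(orders)) {
    q <- orders[r]
    if (q == 0) {
      v <- colSums(delta_mat > 0)
    } else if (abs(q - 1) < 1e-10) {
      ll <- lam * log(lam)
      ll[lam == 0] <- 0
      v <- exp(-colSums(ll))
    } else {
      v <- colSums(lam^q)^(1 / (1 - q))
    }
    v[!pos] <- 0
    out[r, ] <- v
  }
  out
}
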