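# Genetic parameters derived from variance components and breeding values:
# direct, maternal and total heritabilities; EBV-based genetic correlations
# (Calo-type); phenotypic correlations on fixed-effect-adjusted records; and
# predicted direct and relative correlated responses to selection.

#' Heritabilities from variance components
#'
#' Direct heritability `h2a = s2a / s2p`, maternal heritability
#' `h2m = s2m / s2p`, and total heritability `h2T = (s2a + 0.5 s2m) / s2p`
#' (Willham's total under `Cov(a, m) = 0`), with `s2p = s2a + s2m + s2e`.
#' Standard errors, when a component covariance matrix is supplied (or the
#' fit carries one), follow by the delta method.
#'
#' @param vc either a `buf_reml` fit, or a named numeric/list with
#'   `sigma2_a`, `sigma2_m`, `sigma2_e` (missing maternal treated as 0).
#' @param vcov optional 3x3 covariance matrix of `(s2a, s2m, s2e)` for
#'   delta-method SEs; taken from the fit when available.
#' @return data.frame with one row: `h2_direct`, `h2_maternal`, `h2_total`,
#'   `sigma2_p`, and `se_*` columns (NA without a covariance).
#' @examples
#' heritabilities(c(sigma2_a = 260.172, sigma2_m = 503.610, sigma2_e = 16.163))
#' @export
heritabilities <- function(vc, vcov = NULL) {
  if (inherits(vc, "buf_reml")) {
    s2a <- vc$sigma2[["a"]]
    s2m <- if (vc$maternal) vc$sigma2[["m"]] else 0
    s2e <- vc$sigma2[["e"]]
    if (is.null(vcov) && !is.null(vc$vcov_components)) {
      vcov <- matrix(0, 3, 3)
      cn <- colnames(vc$vcov_components)
      for (i in seq_along(cn)) for (j in seq_along(cn)) {
        ii <- match(cn[i], c("a", "m", "e"))
        jj <- match(cn[j], c("a", "m", "e"))
        vcov[ii, jj] <- vc$vcov_components[i, j]
      }
    }
  } else {
    vc <- unlist(vc)
    s2a <- vc[["sigma2_a"]]
    s2m <- if ("sigma2_m" %in% names(vc) && !is.na(vc[["sigma2_m"]]))
      vc[["sigma2_m"]] else 0
    s2e <- vc[["sigma2_e"]]
  }
  s2p <- s2a + s2m + s2e
  if (!is.finite(s2p) || s2p <= 0) stop("phenotypic variance must be > 0")
  h2a <- s2a / s2p
  h2m <- s2m / s2p
  h2t <- (s2a + 0.5 * s2m) / s2p
  se <- c(NA_real_, NA_real_, NA_real_)
  if (!is.null(vcov)) {
    grads <- list(
      h2a = c(s2p - s2a, -s2a, -s2a) / s2p^2,
      h2m = c(-s2m, s2p - s2m, -s2m) / s2p^2,
      h2t = c(s2p - (s2a + 0.5 * s2m), 0.5 * s2p - (s2a + 0.5 * s2m),
              -(s2a + 0.5 * s2m)) / s2p^2)
    se <- vapply(grads, function(g) sqrt(max(drop(t(g) %*% vcov %*% g), 0)),
                 numeric(1))
  }
  data.frame(h2_direct = h2a, h2_maternal = h2m, h2_total = h2t,
             sigma2_p = s2p, se_h2_direct = se[1], se_h2_maternal = se[2],
             se_h2_total = se[3])
}

#' Genetic correlation from estimated breeding values
#'
#' Calo-type approximation: the genetic correlation between two traits is
#' taken as the Pearson correlation of their EBVs over the animals common to
#' both tables (the covariance of paired EBVs over the geometric mean of the
#' EBV variances), clamped to `[-1, 1]`.  Significance is the usual t-test
#' for a correlation coefficient at the common-animal n.
#'
#' @param ebv_x,ebv_y either [blup_ebv()] tables (the `ebv_direct` column is
#'   used, matched on `animal`) or named numeric vectors of EBVs.
#' @return data.frame with `rG`, `n`, `t`, `p`, `flagged` (`TRUE` when
#'   either trait has zero EBV variance and the correlation is undefined).
#' @export
genetic_correlation_ebv <- function(ebv_x, ebv_y) {
  as_vec <- function(e) {
    if (is.data.frame(e)) stats::setNames(e$ebv_direct, e$animal) else e
  }
  x <- as_vec(ebv_x); y <- as_vec(ebv_y)
  common <- intersect(names(x), names(y))
  if (length(common) < 3) stop("fewer than 3 animals with EBVs for both traits")
  x <- x[common]; y <- y[common]
  n <- length(common)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero EBV variance in one trait; genetic correlation undefined")
    return(data.frame(rG = NA_real_, n = n, t = NA_real_, p = NA_real_,
                      flagged = TRUE))
  }
  r <- .clamp_cor(stats::cor(x, y))
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  data.frame(rG = r, n = n, t = tt, p = p, flagged = FALSE)
}

#' Phenotypic correlation on adjusted records
#'
#' Pearson correlation between two fixed-effect-adjusted trait vectors with
#' pairwise-complete deletion; two-sided p from the t distribution with
#' n - 2 df.
#'
#' @param adjusted_x,adjusted_y numeric vectors of equal length (record
#'   aligned).
#' @return data.frame with `r`, `n`, `t`, `p`, `flagged` (`TRUE` when a
#'   vector is constant over the complete pairs).
#' @export
phenotypic_correlation <- function(adjusted_x, adjusted_y) {
  stopifnot(length(adjusted_x) == length(adjusted_y))
  ok <- stats::complete.cases(adjusted_x, adjusted_y)
  x <- adjusted_x[ok]; y <- adjusted_y[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; phenotypic correlation undefined")
    return(data.frame(r = NA_real_, n = n, t = NA_real_, p = NA_real_,
                      flagged = TRUE))
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  data.frame(r = r, n = n, t = tt, p = p, flagged = FALSE)
}

#' Direct response to selection
#'
#' Expected per-generation genetic gain `dG = i * h2 * sigma_P` in trait
#' units, with selection intensity `i` (default 1) and phenotypic standard
#' deviation `sigma_P = sqrt(sigma2_p)`.
#'
#' @param h2 direct heritability in `[0, 1]`.
#' @param sigma2_p phenotypic variance (>= 0, trait units squared).
#' @param intensity selection intensity (default 1).
#' @return numeric gain in trait units.
#' @examples
#' direct_response(0.334, 779.945)   # body-weight gain, kg
#' @export
direct_response <- function(h2, sigma2_p, intensity = 1) {
  stopifnot(h2 >= 0, h2 <= 1, sigma2_p >= 0)
  intensity * h2 * sqrt(sigma2_p)
}

#' Relative correlated response to selection
#'
#' Response in trait i when selection is applied to trait j, relative to
#' direct selection on i: `CR = rG * h_j / h_i` with `h = sqrt(h2)`.
#'
#' @param rG genetic correlation between the traits, in `[-1, 1]`.
#' @param h2_selected heritability of the selected (auxiliary) trait j.
#' @param h2_correlated heritability of the responding trait i; must be
#'   positive (a zero-heritability responding trait makes the ratio
#'   infinite).
#' @return dimensionless relative response; its sign equals `sign(rG)`.
#' @export
correlated_response <- function(rG, h2_selected, h2_correlated) {
  stopifnot(rG >= -1, rG <= 1, h2_selected >= 0, h2_selected <= 1,
            h2_correlated <= 1)
  if (h2_correlated <= 0)
    stop("responding trait has zero heritability: relative correlated ",
         "response is unbounded (direct response on it is nil); ",
         "interpret such traits by their absolute response instead")
  rG * sqrt(h2_selected) / sqrt(h2_correlated)
}

#' Matrix of direct and relative correlated selection responses
#'
#' Diagonal: direct response `i * h2 * sigma_P` for each trait (trait units
#' per generation).  Off-diagonal `[j, i]`: relative correlated response in
#' trait i (column) when selection is applied to auxiliary trait j (row).
#'
#' @param h2 named numeric vector of direct heritabilities.
#' @param sigma2_p named numeric vector of phenotypic variances (same
#'   order).
#' @param rG symmetric genetic-correlation matrix (same trait order).
#' @param intensity selection intensity (default 1).
#' @return matrix with rows = selected trait, columns = responding trait.
#' @export
response_matrix <- function(h2, sigma2_p, rG, intensity = 1) {
  traits <- names(h2)
  stopifnot(!is.null(traits), length(sigma2_p) == length(h2),
            all(dim(rG) == length(h2)))
  out <- matrix(NA_real_, length(h2), length(h2),
                dimnames = list(selected = traits, response = traits))
  for (j in seq_along(traits)) for (i in seq_along(traits)) {
    out[j, i] <- if (i == j)
      direct_response(h2[i], sigma2_p[i], intensity)
    else
      correlated_response(rG[j, i], h2[j], h2[i])
  }
  class(out) <- c("buf_response_matrix", class(out))
  out
}

#' @export
print.buf_response_matrix <- function(x, digits = 4, ...) {
  cat("Selection responses: direct on the diagonal (trait units),\n")
  cat("relative correlated response off-diagonal",
      "(row = selected, column = responding)\n")
  print(round(unclass(x), digits))
  invisible(x)
}
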