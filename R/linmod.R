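# Fixed-effects least-squares analysis of the age-standardized phenotypes:
# an additive model of farm, birth season, sex, dam-age class and
# birth-weight class with sum-to-zero effect coding, partial-SS ANOVA,
# least-square means, Tukey multiple comparisons, and fixed-effect-adjusted
# phenotypes for the downstream correlation and SNP analyses.

#' Drop farms with too few usable records
#'
#' Keeps only farms contributing at least `min_group_size` records with a
#' non-missing value of the modeled trait (the per-trait version of the
#' "at least four animals per farm" rule).
#'
#' @param data phenotype data.frame containing `farm_col` and `trait`.
#' @param trait trait column name.
#' @param min_group_size minimum usable records per farm (default 4).
#' @param farm_col name of the farm column (default `"farm"`).
#' @return filtered data.frame; dropped farm counts are reported via
#'   `message()` and attached as attribute `"dropped_farms"`.
#' @export
filter_farms <- function(data, trait, min_group_size = 4, farm_col = "farm") {
  stopifnot(farm_col %in% names(data), trait %in% names(data),
            min_group_size >= 1)
  usable <- !is.na(data[[trait]])
  counts <- table(data[[farm_col]][usable])
  keep_farms <- names(counts)[counts >= min_group_size]
  out <- data[data[[farm_col]] %in% keep_farms & usable, , drop = FALSE]
  dropped <- setdiff(unique(as.character(data[[farm_col]])), keep_farms)
  if (nrow(out) == 0L)
    stop("no farm reaches ", min_group_size, " usable records for ", trait,
         "; lower min_group_size")
  if (length(dropped))
    message(length(dropped), " farm(s) dropped for ", trait, " (< ",
            min_group_size, " usable records): ",
            paste(dropped, collapse = ", "))
  attr(out, "dropped_farms") <- dropped
  out
}

#' Fit the additive fixed-effects model
#'
#' Least-squares fit of `trait ~ factor_1 + ... + factor_k` with sum-to-zero
#' effect coding, so each level's coefficient is its deviation from the
#' overall mean and least-square means follow directly.  The ANOVA uses
#' partial (adjusted) sums of squares: for a purely additive model these are
#' the Type II = Type III marginal tests (`F = MS_factor / MS_error`).
#'
#' @param data phenotype data.frame.
#' @param trait response column name.
#' @param factors character vector of categorical factor columns (order kept).
#' @return object of class `buf_fixed_fit`: list with `lm` (the underlying
#'   fit), `mu` (intercept = overall mean under sum-to-zero coding),
#'   `effects` (per factor, named vector of level effects summing to zero),
#'   `anova` (factor, df, sum_sq, mean_sq, F, p), `sigma2` (MS_error),
#'   `df_residual`, `trait`, `factors`, `data`.
#' @export
fit_fixed_model <- function(data, trait, factors) {
  stopifnot(length(factors) >= 1, trait %in% names(data),
            all(factors %in% names(data)))
  d <- data[stats::complete.cases(data[c(trait, factors)]), , drop = FALSE]
  for (f in factors) {
    d[[f]] <- droplevels(factor(d[[f]]))
    if (nlevels(d[[f]]) < 2)
      stop("factor '", f, "' has fewer than 2 observed levels")
  }
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fml <- stats::reformulate(factors, response = trait)
  fit <- stats::lm(fml, data = d, contrasts = contr)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design: aliased coefficients ", paste(bad, collapse = ", "),
         " (confounded factor levels)")
  }
  mu <- unname(stats::coef(fit)[1L])
  # expand sum-to-zero coefficients into complete per-level effect vectors
  effects <- lapply(factors, function(f) {
    lev <- levels(d[[f]])
    cf <- stats::coef(fit)[paste0(f, seq_len(length(lev) - 1L))]
    e <- c(cf, -sum(cf))
    names(e) <- lev
    e
  })
  names(effects) <- factors

  rss <- sum(stats::residuals(fit)^2)
  dfe <- fit$df.residual
  sigma2 <- rss / dfe
  degenerate <- sigma2 < .Machine$double.eps * max(1, stats::var(d[[trait]]))
  if (degenerate)
    warning("residual mean square is (numerically) zero; ",
            "F statistics undefined")
  dr <- if (degenerate) suppressWarnings(stats::drop1(fit, scope = fml,
                                                      test = "F")) else
    stats::drop1(fit, scope = fml, test = "F")
  an <- data.frame(factor = factors,
                   df = dr$Df[-1L],
                   sum_sq = dr$`Sum of Sq`[-1L],
                   stringsAsFactors = FALSE)
  an$mean_sq <- an$sum_sq / an$df
  an$F <- if (degenerate) NaN else an$mean_sq / sigma2
  an$p <- stats::pf(an$F, an$df, dfe, lower.tail = FALSE)
  structure(list(lm = fit, mu = mu, effects = effects, anova = an,
                 sigma2 = sigma2, df_residual = dfe, trait = trait,
                 factors = factors, data = d),
            class = "buf_fixed_fit")
}

#' @export
print.buf_fixed_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects fit: %s ~ %s  (n = %d)\n", x$trait,
              paste(x$factors, collapse = " + "), nrow(x$data)))
  cat(sprintf("overall mean %.4f, MS_error %.4f on %d df\n",
              x$mu, x$sigma2, x$df_residual))
  an <- x$anova
  an$sig <- sig_stars(an$p)
  print(an, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Least-square means for a model factor
#'
#' Model-based level means averaged with equal weight over the levels of all
#' other factors (computed via \pkg{emmeans}); standard errors come from the
#' coefficient covariance matrix.  Non-estimable levels are dropped with a
#' warning.
#'
#' @param fit a [fit_fixed_model()] result.
#' @param factor factor name.
#' @return data.frame with columns `level`, `n`, `estimate`, `SE`.
#' @export
ls_means <- function(fit, factor) {
  stopifnot(inherits(fit, "buf_fixed_fit"), factor %in% fit$factors)
  emm <- emmeans::emmeans(fit$lm, specs = factor, data = fit$data)
  s <- as.data.frame(emm)
  out <- data.frame(level = as.character(s[[1L]]),
                    n = as.integer(table(fit$data[[factor]])[as.character(s[[1L]])]),
                    estimate = s$emmean, SE = s$SE,
                    stringsAsFactors = FALSE)
  bad <- is.na(out$estimate)
  if (any(bad)) {
    warning("non-estimable level(s) dropped for ", factor, ": ",
            paste(out$level[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Tukey letter groupings for a model factor
#'
#' Tukey HSD comparisons of the least-square means (studentized-range
#' adjusted p-values via \pkg{emmeans}), summarized as a compact letter
#' display by insert-and-absorb.  Letters are assigned greatest-mean-first:
#' the highest least-square mean always carries the letter "a", matching the
#' superscript convention of livestock least-square-means tables; levels
#' sharing a letter do not differ at `alpha`.
#'
#' @param fit a [fit_fixed_model()] result.
#' @param factor factor name with at least two levels.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with `level`, `estimate`, `letters`, ordered by
#'   decreasing least-square mean.
#' @export
tukey_groups <- function(fit, factor, alpha = 0.05) {
  stopifnot(inherits(fit, "buf_fixed_fit"), factor %in% fit$factors)
  if (fit$sigma2 <= 0 || !is.finite(fit$sigma2) ||
      fit$sigma2 < .Machine$double.eps)
    stop("MS_error is zero; Tukey comparisons undefined")
  emm <- emmeans::emmeans(fit$lm, specs = factor, data = fit$data)
  lm_tab <- as.data.frame(emm)
  lev <- as.character(lm_tab[[1L]])
  est <- lm_tab$emmean
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  k <- length(lev)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  pair_names <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  for (r in seq_len(nrow(prs))) {
    a <- pair_names[[r]][1L]; b <- pair_names[[r]][2L]
    # emmeans may prefix numeric-looking levels; strip to match
    a <- sub("^\\(|\\)$", "", a); b <- sub("^\\(|\\)$", "", b)
    if (prs$p.value[r] < alpha) sig[a, b] <- sig[b, a] <- TRUE
  }
  ord <- order(est, decreasing = TRUE)
  letters_vec <- .cld_insert_absorb(sig[ord, ord, drop = FALSE])
  data.frame(level = lev[ord], estimate = est[ord], letters = letters_vec,
             stringsAsFactors = FALSE)
}

# Insert-and-absorb compact letter display. `sig` is a logical significance
# matrix over levels ordered by decreasing mean; returns a letter string per
# level so that two levels share a letter iff they are not declared different.
#' @noRd
.cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))              # start: one letter containing all
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      if (all(c(i, j) %in% cols[[ci]])) {
        c1 <- setdiff(cols[[ci]], j)
        c2 <- setdiff(cols[[ci]], i)
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]]) && length(cols[[a]]) < length(cols[[b]]))
        keep[a] <- FALSE
      if (a != b && keep[a] && keep[b] && identical(cols[[a]], cols[[b]]) && a > b)
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order letters by first (highest-mean) member
  cols <- cols[order(vapply(cols, min, 1L))]
  out <- character(k)
  for (ci in seq_along(cols))
    for (m in cols[[ci]]) out[m] <- paste0(out[m], letters[ci])
  out
}

#' Fixed-effect-adjusted phenotypes
#'
#' Removes the estimated effects of the (by default, significant) factors
#' from each record: `adjusted = y - sum(effects) + mean(sum(effects))`, so
#' the adjusted data keep the raw grand mean while factor-level differences
#' are equalized.  Only factors with ANOVA `p < alpha` are removed when
#' `which = "significant"` (the adjusted data used for phenotypic
#' correlations and SNP tests); `which = "all"` removes every fitted factor.
#'
#' @param fit a [fit_fixed_model()] result.
#' @param alpha significance gate for `which = "significant"` (default 0.05).
#' @param which `"significant"` (default) or `"all"`.
#' @return the fit's model frame with an added column
#'   `<trait>_adj`; attribute `"adjusted_for"` lists the factors removed.
#' @export
adjust_phenotypes <- function(fit, alpha = 0.05,
                              which = c("significant", "all")) {
  stopifnot(inherits(fit, "buf_fixed_fit"))
  which <- match.arg(which)
  sel <- if (which == "all") fit$factors else
    fit$anova$factor[!is.na(fit$anova$p) & fit$anova$p < alpha]
  d <- fit$data
  s <- numeric(nrow(d))
  for (f in sel) s <- s + fit$effects[[f]][as.character(d[[f]])]
  adj <- d[[fit$trait]] - s + mean(s)
  d[[paste0(fit$trait, "_adj")]] <- adj
  attr(d, "adjusted_for") <- sel
  d
}
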