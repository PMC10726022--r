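# Candidate-SNP summaries and genotype-effect tests on adjusted phenotypes.
# Genotype calls are unordered allele pairs ("TC" == "CT"); loci are assumed
# biallelic SNPs.

#' @noRd
.normalize_genotypes <- function(calls) {
  calls <- toupper(as.character(calls))
  calls[calls %in% c("", "NA", "--", "./.")] <- NA_character_
  ok <- !is.na(calls)
  if (any(!grepl("^[ACGT][ACGT]$", calls[ok])))
    stop("genotype calls must be two-letter allele pairs from {A,C,G,T}")
  split <- strsplit(calls[ok], "")
  calls[ok] <- vapply(split, function(a) paste(sort(a), collapse = ""), "")
  calls
}

#' Summarize genotypes at a biallelic SNP
#'
#' Counts genotype classes, computes genotype and allele frequencies, flags
#' monomorphic loci, and (as a QC extension beyond the class-means analysis)
#' reports an exact Hardy-Weinberg equilibrium test p-value.
#'
#' @param calls character vector of genotype calls per animal (e.g. `"TT"`,
#'   `"TC"`; order-insensitive; missing allowed as `NA` or `""`).
#' @return list with `counts` (named integer), `genotype_freq`,
#'   `allele_freq` (named numeric, sums to 1), `n` (animals with calls),
#'   `monomorphic` (logical), `hwe_p` (NA for monomorphic loci).
#' @examples
#' genotype_summary(rep(c("TT", "TC"), c(227, 9)))
#' @export
genotype_summary <- function(calls) {
  calls <- .normalize_genotypes(calls)
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) stop("no genotype calls")
  counts <- table(calls)
  alleles <- sort(unique(unlist(strsplit(names(counts), ""))))
  if (length(alleles) > 2)
    stop("more than two alleles observed (", paste(alleles, collapse = ","),
         "); biallelic SNP expected")
  n <- length(calls)
  allele_counts <- stats::setNames(numeric(length(alleles)), alleles)
  for (g in names(counts)) {
    a <- strsplit(g, "")[[1]]
    allele_counts[a[1]] <- allele_counts[a[1]] + counts[[g]]
    allele_counts[a[2]] <- allele_counts[a[2]] + counts[[g]]
  }
  allele_freq <- allele_counts / (2 * n)
  mono <- length(alleles) == 1L
  hwe_p <- NA_real_
  if (!mono) {
    het <- paste(alleles, collapse = "")
    hom1 <- paste0(alleles[1], alleles[1])
    hom2 <- paste0(alleles[2], alleles[2])
    getc <- function(g) if (g %in% names(counts)) counts[[g]] else 0L
    hwe_p <- hwe_exact(getc(hom1), getc(het), getc(hom2))
  }
  list(counts = c(counts), genotype_freq = c(counts) / n,
       allele_freq = allele_freq, n = n, monomorphic = mono, hwe_p = hwe_p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test for a biallelic locus: the two-sided p-value sums
#' the conditional probabilities (given allele counts) of all heterozygote
#' counts no more probable than the observed one.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts.
#' @return p-value.
#' @export
hwe_exact <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n1 <- 2 * n_hom1 + n_het            # copies of allele 1
  rare <- min(n1, 2 * n - n1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    a <- (rare - h) / 2               # rare-allele homozygotes
    b <- n - a - h                    # common homozygotes
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- min(n_het, rare)
  min(1, sum(prob[prob <= prob[match(obs, hets)] * (1 + 1e-9)]))
}

#' One-way ANOVA of genotype effects on an adjusted phenotype
#'
#' Standard one-way decomposition of a fixed-effect-adjusted trait over
#' genotype classes.  Classes with fewer than `min_class_size` animals are
#' reported but excluded from the F test so the error mean square stays
#' defined; with fewer than two usable classes the test is skipped (as for
#' monomorphic loci).
#'
#' @param adjusted numeric vector of adjusted phenotypes.
#' @param genotype character vector of genotype calls, aligned with
#'   `adjusted`.
#' @param min_class_size smallest class entering the F test (default 2).
#' @return list with `groups` (data.frame of genotype, n, mean, sd,
#'   included), `F`, `df`, `p`, and `tested` (FALSE when the test was
#'   skipped, with `reason`).
#' @export
genotype_anova <- function(adjusted, genotype, min_class_size = 2) {
  stopifnot(length(adjusted) == length(genotype))
  genotype <- .normalize_genotypes(genotype)
  ok <- !is.na(adjusted) & !is.na(genotype)
  y <- adjusted[ok]; g <- genotype[ok]
  tab <- data.frame(genotype = names(table(g)),
                    n = as.integer(table(g)),
                    stringsAsFactors = FALSE)
  tab$mean <- vapply(tab$genotype, function(k) mean(y[g == k]), 1)
  tab$sd <- vapply(tab$genotype, function(k) stats::sd(y[g == k]), 1)
  tab$included <- tab$n >= min_class_size
  if (any(!tab$included))
    message("genotype class(es) below n = ", min_class_size,
            " excluded from the F test: ",
            paste(tab$genotype[!tab$included], collapse = ", "))
  use <- g %in% tab$genotype[tab$included]
  if (sum(tab$included) < 2) {
    return(list(groups = tab, F = NA_real_, df = c(NA, NA), p = NA_real_,
                tested = FALSE,
                reason = "fewer than two usable genotype classes"))
  }
  fit <- stats::lm(y[use] ~ factor(g[use]))
  an <- stats::anova(fit)
  list(groups = tab, F = an$`F value`[1], df = an$Df, p = an$`Pr(>F)`[1],
       tested = TRUE, reason = NULL)
}
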