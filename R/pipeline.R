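# End-to-end orchestration: age standardization -> fixed-effects analysis per
# trait -> animal-model REML and BLUP per trait -> genetic parameters ->
# candidate-SNP association, with publication-shaped report tables.

#' @noRd
.load_input <- function(x, reader = .read_delim_auto) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file not found: ", x)
    reader(x)
  } else x
}

#' Pipeline configuration
#'
#' @param pedigree a [pedigree()] or path to a pedigree file.
#' @param measurements long measurement table (`animal`, `trait`,
#'   `age_days`, `value`) or path.
#' @param covariates per-animal classification table (`animal`, `farm`,
#'   `birth_season`, `sex`, `dam_age_class`, `birth_weight_class`) or path.
#' @param genotypes optional long genotype table (`animal`, `locus`,
#'   `genotype`) or path.
#' @param traits traits to analyze (default: all trait columns found).
#' @param factors fixed-effect factors for the least-squares model.
#' @param min_farm_n minimum usable records per farm (default 4).
#' @param alpha significance gate for adjustment and reporting (default
#'   0.05).
#' @param target_age standardization age in days (default 365).
#' @param maternal include maternal genetic effects in REML (default TRUE).
#' @param reml_tol,reml_max_iter,reml_accelerate REML settings.
#' @param out_dir optional directory; every stage output is persisted there
#'   as tab-separated text.
#' @return list of class `buf_pipeline_config`.
#' @export
pipeline_config <- function(pedigree, measurements, covariates,
                            genotypes = NULL, traits = NULL,
                            factors = c("farm", "birth_season", "sex",
                                        "dam_age_class",
                                        "birth_weight_class"),
                            min_farm_n = 4, alpha = 0.05, target_age = 365,
                            maternal = TRUE, reml_tol = 1e-8,
                            reml_max_iter = 2000, reml_accelerate = TRUE,
                            out_dir = NULL) {
  stopifnot(min_farm_n >= 1, alpha > 0, alpha < 1, reml_tol > 0)
  for (nm in c("pedigree", "measurements", "covariates")) {
    x <- get(nm)
    if (is.character(x) && !file.exists(x))
      stop("configuration invalid: ", nm, " file not found: ", x)
  }
  structure(list(pedigree = pedigree, measurements = measurements,
                 covariates = covariates, genotypes = genotypes,
                 traits = traits, factors = factors, min_farm_n = min_farm_n,
                 alpha = alpha, target_age = target_age, maternal = maternal,
                 reml_tol = reml_tol, reml_max_iter = reml_max_iter,
                 reml_accelerate = reml_accelerate, out_dir = out_dir),
            class = "buf_pipeline_config")
}

#' @noRd
.persist <- function(obj, name, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(obj, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: standardize measurements to the target age, merge
#' per-animal covariates, per trait filter farms / fit the fixed model /
#' adjust phenotypes, per trait estimate variance components by EM-REML
#' (fixed effects = the factors significant in the least-squares ANOVA) and
#' predict breeding values, derive heritabilities, EBV-based genetic and
#' adjusted-data phenotypic correlations and selection responses, and test
#' SNP genotype effects on the adjusted phenotypes.  A failing stage aborts
#' with the stage name; all completed stage outputs are already persisted
#' when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return list ("report bundle") with elements `standardized`, `fits`,
#'   `adjusted`, `reml`, `ebv`, `heritability`, `genetic_cor`,
#'   `phenotypic_cor`, `responses`, `snp`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "buf_pipeline_config"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ped <- stage("inputs", {
    p <- config$pedigree
    if (is.character(p)) read_pedigree(p) else p
  })
  meas <- stage("inputs", .load_input(config$measurements))
  cov <- stage("inputs", .load_input(config$covariates))
  note("inputs: %d pedigree entries, %d measurement rows, %d animals with covariates",
       nrow(ped), nrow(meas), nrow(cov))

  std <- stage("agestd", standardize_table(meas, config$target_age))
  .persist(std, "standardized", config$out_dir)
  traits <- config$traits
  if (is.null(traits)) traits <- setdiff(names(std), "animal")
  pheno <- stage("agestd", merge(std, cov, by = "animal"))
  note("agestd: %d animals standardized for %d trait(s)", nrow(std),
       length(traits))

  fits <- list(); adjusted <- list(); lsm <- list()
  for (tr in traits) {
    fits[[tr]] <- stage("linmod", {
      d <- filter_farms(pheno, tr, config$min_farm_n)
      fit_fixed_model(d, tr, config$factors)
    })
    adjusted[[tr]] <- stage("linmod",
                            adjust_phenotypes(fits[[tr]], config$alpha))
    lsm[[tr]] <- stage("linmod", {
      do.call(rbind, lapply(config$factors, function(f) {
        m <- ls_means(fits[[tr]], f)
        g <- tukey_groups(fits[[tr]], f, config$alpha)
        m$letters <- g$letters[match(m$level, g$level)]
        p <- fits[[tr]]$anova$p[fits[[tr]]$anova$factor == f]
        cbind(trait = tr, factor = f, m,
              factor_p = p, sig = sig_stars(p))
      }))
    })
    note("linmod[%s]: n = %d, significant factors: %s", tr,
         nrow(fits[[tr]]$data),
         paste(attr(adjusted[[tr]], "adjusted_for"), collapse = ", "))
  }
  lsmeans_table <- do.call(rbind, lsm)
  .persist(lsmeans_table, "lsmeans", config$out_dir)

  reml_fits <- list(); ebv <- list(); h2 <- list()
  for (tr in traits) {
    sig_factors <- attr(adjusted[[tr]], "adjusted_for")
    reml_fits[[tr]] <- stage("reml",
      em_reml(fits[[tr]]$data, tr, ped,
              fixed = if (length(sig_factors)) sig_factors else NULL,
              maternal = config$maternal, tol = config$reml_tol,
              max_iter = config$reml_max_iter,
              accelerate = config$reml_accelerate))
    ebv[[tr]] <- stage("reml", blup_ebv(reml_fits[[tr]],
                                        pev = nrow(ped) <= 600))
    h2[[tr]] <- stage("genpar", heritabilities(reml_fits[[tr]]))
    note("reml[%s]: sigma2 = (%.4g, %.4g, %.4g), h2a = %.3f, %d iterations",
         tr, reml_fits[[tr]]$sigma2[["a"]],
         reml_fits[[tr]]$sigma2[["m"]], reml_fits[[tr]]$sigma2[["e"]],
         h2[[tr]]$h2_direct, reml_fits[[tr]]$n_iterations)
  }
  h2_table <- cbind(trait = traits, do.call(rbind, h2))
  .persist(h2_table, "variance_components", config$out_dir)

  k <- length(traits)
  gcor <- diag(1, k); pcor <- diag(1, k)
  gp <- matrix(NA_real_, k, k); pp <- matrix(NA_real_, k, k)
  dimnames(gcor) <- dimnames(pcor) <- dimnames(gp) <- dimnames(pp) <-
    list(traits, traits)
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      g <- stage("genpar",
                 genetic_correlation_ebv(ebv[[traits[i]]], ebv[[traits[j]]]))
      gcor[i, j] <- gcor[j, i] <- g$rG
      gp[i, j] <- gp[j, i] <- g$p
      ai <- adjusted[[traits[i]]]
      aj <- adjusted[[traits[j]]]
      common <- intersect(ai$animal, aj$animal)
      ph <- stage("genpar", phenotypic_correlation(
        ai[[paste0(traits[i], "_adj")]][match(common, ai$animal)],
        aj[[paste0(traits[j], "_adj")]][match(common, aj$animal)]))
      pcor[i, j] <- pcor[j, i] <- ph$r
      pp[i, j] <- pp[j, i] <- ph$p
    }
  }
  responses <- stage("genpar", {
    h2v <- stats::setNames(vapply(h2, function(x) x$h2_direct, 1), traits)
    s2p <- stats::setNames(vapply(h2, function(x) x$sigma2_p, 1), traits)
    ok <- h2v > 0
    response_matrix(h2v[ok], s2p[ok], gcor[ok, ok, drop = FALSE])
  })

  snp_results <- NULL
  if (!is.null(config$genotypes)) {
    geno <- stage("inputs", .load_input(config$genotypes))
    snp_results <- stage("snp", {
      lapply(split(geno, geno$locus), function(gl) {
        summ <- genotype_summary(gl$genotype)
        assoc <- NULL
        if (!summ$monomorphic) {
          tr <- traits[1L]
          ad <- adjusted[[tr]]
          m <- match(ad$animal, gl$animal)
          assoc <- genotype_anova(ad[[paste0(tr, "_adj")]][!is.na(m)],
                                  gl$genotype[m[!is.na(m)]])
        }
        list(summary = summ, anova = assoc)
      })
    })
    for (loc in names(snp_results))
      note("snp[%s]: %s", loc,
           if (snp_results[[loc]]$summary$monomorphic) "monomorphic"
           else sprintf("F test p = %.3g",
                        snp_results[[loc]]$anova$p %||% NA))
  }

  bundle <- list(standardized = std, fits = fits, adjusted = adjusted,
                 lsmeans = lsmeans_table, reml = reml_fits, ebv = ebv,
                 heritability = h2_table, genetic_cor = gcor,
                 genetic_cor_p = gp, phenotypic_cor = pcor,
                 phenotypic_cor_p = pp, responses = responses,
                 snp = snp_results, log = log, config = config)
  class(bundle) <- "buf_pipeline_result"
  if (!is.null(config$out_dir)) render_tables(bundle, config$out_dir)
  bundle
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.buf_pipeline_result <- function(x, ...) {
  traits <- rownames(x$genetic_cor)
  cat(sprintf("Pipeline result: %d trait(s) [%s], %d animals standardized\n",
              length(traits), paste(traits, collapse = ", "),
              nrow(x$standardized)))
  for (tr in traits) {
    fit <- x$reml[[tr]]
    cat(sprintf("  %s: h2a = %.3f, h2m = %.3f, h2T = %.3f (%d EM iterations)\n",
                tr, x$heritability$h2_direct[x$heritability$trait == tr],
                x$heritability$h2_maternal[x$heritability$trait == tr],
                x$heritability$h2_total[x$heritability$trait == tr],
                fit$n_iterations))
  }
  if (!is.null(x$snp))
    cat(sprintf("SNP loci tested: %s\n", paste(names(x$snp), collapse = ", ")))
  cat("Tables via render_tables(); stage log in $log\n")
  invisible(x)
}

#' Render publication-shaped report tables
#'
#' Produces the human-readable tables of the analysis: least-square means
#' with Tukey letters and significance stars, variance components with
#' direct/maternal/total heritabilities (boundary components annotated),
#' the combined correlation matrix (genetic above, phenotypic below the
#' diagonal, with stars), and the selection-response matrix (direct
#' responses on the diagonal).
#'
#' @param bundle a [run_pipeline()] result (or a compatible list).
#' @param out_dir optional directory for tab-separated copies.
#' @return named list of data.frames / character matrices.
#' @export
render_tables <- function(bundle, out_dir = NULL) {
  traits <- rownames(bundle$genetic_cor)
  k <- length(traits)
  corr <- matrix("-", k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j)
      corr[i, j] <- sprintf("%.2f %s", bundle$genetic_cor[i, j],
                            sig_stars(bundle$genetic_cor_p[i, j]))
    if (i > j)
      corr[i, j] <- sprintf("%.2f %s", bundle$phenotypic_cor[i, j],
                            sig_stars(bundle$phenotypic_cor_p[i, j]))
  }
  h2t <- bundle$heritability
  comp_rows <- lapply(seq_len(nrow(h2t)), function(r) {
    tr <- h2t$trait[r]
    fit <- bundle$reml[[tr]]
    se_of <- function(u) if (is.null(fit$se)) NA_real_ else fit$se[[u]]
    fmt <- function(v, s, b) sprintf("%.3f ± %.3f%s", v,
                                     if (is.na(s)) 0 else s,
                                     if (isTRUE(b)) " (boundary)" else "")
    data.frame(trait = tr, n = nrow(fit$model$data),
               sigma2_a = fmt(fit$sigma2[["a"]], se_of("a"),
                              fit$boundary[["a"]]),
               sigma2_m = fmt(fit$sigma2[["m"]], se_of("m"),
                              fit$boundary[["m"]]),
               sigma2_e = fmt(fit$sigma2[["e"]], se_of("e"),
                              fit$boundary[["e"]]),
               sigma2_p = fmt(fit$sigma2_p, se_of("p"), FALSE),
               h2_direct = fmt(h2t$h2_direct[r], h2t$se_h2_direct[r], FALSE),
               h2_maternal = fmt(h2t$h2_maternal[r], h2t$se_h2_maternal[r],
                                 FALSE),
               h2_total = fmt(h2t$h2_total[r], h2t$se_h2_total[r], FALSE),
               stringsAsFactors = FALSE)
  })
  tables <- list(
    lsmeans = bundle$lsmeans,
    components = do.call(rbind, comp_rows),
    correlations = corr,
    responses = round(unclass(bundle$responses), 4))
  if (!is.null(out_dir)) {
    for (nm in names(tables)) {
      x <- tables[[nm]]
      if (is.matrix(x)) x <- data.frame(trait = rownames(x), x,
                                        check.names = FALSE)
      .persist(x, paste0("table_", nm), out_dir)
    }
  }
  tables
}
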