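# Synthetic herd generator.  Emulates the statistical structure the analysis
# assumes: a farm-structured cohort of yearling calves with additive +
# maternal genetic covariance drawn through the pedigree relationship
# matrix, fixed effects sized like the published sex/season contrasts,
# repeated measurements bracketing 365 d of age, and biallelic SNP genotypes
# gene-dropped at skewed founder allele frequencies.  Every stage is
# reproducible from a single seed via a split-stream scheme.

#' @noRd
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic-herd
#' generator.  Defaults emulate the study herd: 313 calves across 36 farms,
#' variance components and trait means from the published per-trait
#' estimates, fixed-effect sizes from the published sex and birth-season
#' contrasts, and SNP founder frequencies matching the published LCORL /
#' HMGA2 genotype counts.
#'
#' @param n_sires,n_dams,n_calves founder sires, founder dams, and recorded
#'   calves (defaults 25, 280, 313).
#' @param n_farms number of farms (default 36).
#' @param traits trait codes to simulate (default `c("BW", "WH")`; any
#'   subset of [buffalo_traits()], or arbitrary names when `components` is
#'   supplied).
#' @param components data.frame with `trait`, `sigma2_a`, `sigma2_m`,
#'   `sigma2_e` (defaults: published values for `traits`).
#' @param true_rG genetic-correlation matrix among `traits` (defaults:
#'   published matrix subset); must be positive semidefinite.
#' @param true_rE residual (environmental) correlation matrix among
#'   `traits`; defaults to `true_rG`, mirroring the study's phenotypic
#'   correlations, which closely track the genetic ones.
#' @param mu named trait means (defaults: published least-square means).
#' @param sex_effect,season_effect named per-trait full contrasts (male -
#'   female, spring - summer; defaults: published contrasts).  Set to 0 for
#'   effect-free data.
#' @param farm_sd named per-trait between-farm SD (default
#'   `0.5 * sqrt(sigma2_p)`, a strong herd effect as observed).
#' @param measurement_ages day offsets at which repeated measurements are
#'   taken (default `c(280, 340, 400)`, bracketing 365 d).
#' @param measurement_noise_sd named per-trait within-series measurement
#'   noise SD (default `0.05 * sqrt(sigma2_p)`).
#' @param growth_rate named per-trait daily growth slope (default
#'   `0.5 * mu / 365`).
#' @param snp_allele_freqs named per-locus founder frequency of the common
#'   allele (defaults: frequencies implied by the published counts).
#' @param snp_alleles named list of 2-letter allele pairs per locus
#'   (common allele first).
#' @param snp_effects named per-locus additive effect (trait units per copy
#'   of the rare allele) applied to the first trait; default 0.
#' @param generations pedigree depth knob (default 1: founders + calves).
#' @param seed integer master seed.
#' @return list of class `buf_sim_config`.
#' @export
sim_config <- function(n_sires = 25, n_dams = 280, n_calves = 313,
                       n_farms = 36, traits = c("BW", "WH"),
                       components = NULL, true_rG = NULL, true_rE = NULL,
                       mu = NULL,
                       sex_effect = NULL, season_effect = NULL,
                       farm_sd = NULL, measurement_ages = c(280, 340, 400),
                       measurement_noise_sd = NULL, growth_rate = NULL,
                       snp_allele_freqs = NULL, snp_alleles = NULL,
                       snp_effects = NULL, generations = 1, seed = 1) {
  stopifnot(n_sires > 0, n_dams > 0, n_calves > 0, n_farms > 0,
            length(traits) >= 1)
  pub <- buffalo_variance_components()
  if (is.null(components)) {
    if (!all(traits %in% pub$trait))
      stop("no published components for trait(s) ",
           paste(setdiff(traits, pub$trait), collapse = ", "),
           "; supply `components`")
    components <- pub[match(traits, pub$trait),
                      c("trait", "sigma2_a", "sigma2_m", "sigma2_e")]
  }
  stopifnot(all(traits %in% components$trait),
            all(components$sigma2_a >= 0), all(components$sigma2_m >= 0),
            all(components$sigma2_e >= 0))
  components <- components[match(traits, components$trait), , drop = FALSE]
  s2p <- components$sigma2_a + components$sigma2_m + components$sigma2_e
  names(s2p) <- traits
  if (is.null(true_rG)) {
    if (all(traits %in% buffalo_traits())) {
      true_rG <- buffalo_genetic_correlations()[traits, traits, drop = FALSE]
    } else true_rG <- diag(1, length(traits))
    dimnames(true_rG) <- list(traits, traits)
  }
  ev <- eigen(true_rG, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("true_rG is not positive semidefinite")
  if (is.null(true_rE)) true_rE <- true_rG
  dimnames(true_rE) <- list(traits, traits)
  evE <- eigen(true_rE, symmetric = TRUE, only.values = TRUE)$values
  if (min(evE) < -1e-8) stop("true_rE is not positive semidefinite")
  pick <- function(x, default) {
    if (is.null(x)) default
    else if (length(x) == 1L && is.null(names(x)))
      stats::setNames(rep(x, length(traits)), traits)
    else x[traits]
  }
  pubc <- buffalo_fixed_effect_contrasts()
  pubm <- buffalo_trait_means()
  in_pub <- traits %in% pubc$trait
  mu <- pick(mu, {
    m <- stats::setNames(rep(100, length(traits)), traits)
    m[in_pub] <- pubm[traits[in_pub]]
    m
  })
  sex_effect <- pick(sex_effect, {
    s <- stats::setNames(rep(0, length(traits)), traits)
    s[in_pub] <- pubc$sex_diff[match(traits[in_pub], pubc$trait)]
    s
  })
  season_effect <- pick(season_effect, {
    s <- stats::setNames(rep(0, length(traits)), traits)
    s[in_pub] <- pubc$season_diff[match(traits[in_pub], pubc$trait)]
    s
  })
  farm_sd <- pick(farm_sd, 0.5 * sqrt(s2p))
  measurement_noise_sd <- pick(measurement_noise_sd, 0.05 * sqrt(s2p))
  growth_rate <- pick(growth_rate, 0.5 * mu / 365)
  if (is.null(snp_allele_freqs))
    snp_allele_freqs <- c(LCORL = 463 / 472, HMGA2 = 394 / 470)
  stopifnot(all(snp_allele_freqs > 0), all(snp_allele_freqs <= 1))
  if (is.null(snp_alleles))
    snp_alleles <- list(LCORL = c("T", "C"), HMGA2 = c("C", "T"))[
      intersect(c("LCORL", "HMGA2"), names(snp_allele_freqs))]
  if (is.null(snp_effects))
    snp_effects <- stats::setNames(rep(0, length(snp_allele_freqs)),
                                   names(snp_allele_freqs))
  structure(list(n_sires = n_sires, n_dams = n_dams, n_calves = n_calves,
                 n_farms = n_farms, traits = traits, components = components,
                 sigma2_p = s2p, true_rG = true_rG, true_rE = true_rE,
                 mu = mu,
                 sex_effect = sex_effect, season_effect = season_effect,
                 farm_sd = farm_sd, measurement_ages = measurement_ages,
                 measurement_noise_sd = measurement_noise_sd,
                 growth_rate = growth_rate,
                 snp_allele_freqs = snp_allele_freqs,
                 snp_alleles = snp_alleles, snp_effects = snp_effects,
                 generations = generations, seed = as.integer(seed)),
            class = "buf_sim_config")
}

#' Simulate a herd pedigree
#'
#' Founder sires and dams plus recorded calves with randomly assigned
#' parents (dams re-used across calves, giving maternal half/full-sib
#' structure).  With `generations > 1` each intermediate generation becomes
#' the parent pool of the next.
#'
#' @param cfg a [sim_config()].
#' @return a [pedigree()] with calves identifiable by the `"C"` id prefix of
#'   the final generation; attribute `"calves"` lists the recorded cohort.
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(.stage_seed(cfg$seed, "pedigree"))
  sires <- sprintf("S%03d", seq_len(cfg$n_sires))
  dams <- sprintf("D%04d", seq_len(cfg$n_dams))
  animal <- c(sires, dams)
  sire <- dam <- rep(NA_character_, length(animal))
  for (g in seq_len(cfg$generations)) {
    last <- g == cfg$generations
    n_off <- if (last) cfg$n_calves else cfg$n_sires + cfg$n_dams
    prefix <- if (last) "C" else sprintf("G%d_", g)
    off <- sprintf("%s%04d", prefix, seq_len(n_off))
    off_sire <- sample(sires, n_off, replace = TRUE)
    off_dam <- sample(dams, n_off, replace = TRUE)
    animal <- c(animal, off)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    if (!last) {
      half <- seq_len(floor(n_off / 2))
      sires <- off[half]
      dams <- off[setdiff(seq_len(n_off), half)]
    }
  }
  ped <- pedigree(animal, sire, dam)
  attr(ped, "calves") <- grep("^C", ped$animal, value = TRUE)
  ped
}

#' Simulate 365-day phenotypes with known truth
#'
#' Draws additive and maternal genetic values for every pedigree animal from
#' the matrix-normal `N(0, Sigma_g (x) A)` via the Cholesky factor of A and
#' the symmetric square root of the genetic covariance among traits,
#' attaches each record's maternal value through its dam, adds farm / sex /
#' season fixed effects and residuals correlated across traits per
#' `true_rE`, and returns the phenotype table along with the simulated truth
#' (breeding values, maternal values, farm effects).
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg the [sim_config()] used to build it.
#' @param dosage optional animals-by-loci matrix of rare-allele counts (see
#'   [simulate_genotypes()]); `cfg$snp_effects` is applied to the first
#'   trait.
#' @return list with `pheno` (data.frame: `animal`, `farm`, `birth_season`,
#'   `sex`, `dam_age_class`, `birth_weight_class`, one column per trait) and
#'   `truth` (list: `bv`, `mv` matrices over all pedigree animals,
#'   `farm_effects`, per-record `fixed`).
#' @export
simulate_phenotypes <- function(ped, cfg, dosage = NULL) {
  set.seed(.stage_seed(cfg$seed, "phenotypes"))
  calves <- attr(ped, "calves")
  if (is.null(calves)) calves <- ped$animal[!is.na(ped$dam)]
  n_all <- nrow(ped)
  traits <- cfg$traits
  Tn <- length(traits)
  A <- relationship_matrix(ped)
  Ua <- chol(A)
  dsa <- sqrt(cfg$components$sigma2_a)
  dsm <- sqrt(cfg$components$sigma2_m)
  # symmetric PSD square root (tolerates zero-variance traits)
  msqrt <- function(S) {
    es <- eigen(S, symmetric = TRUE)
    es$vectors %*% (t(es$vectors) * sqrt(pmax(es$values, 0)))
  }
  Sg <- function(d, R) diag(d, Tn) %*% R %*% diag(d, Tn)
  draw <- function(S) {
    Z <- matrix(stats::rnorm(n_all * Tn), n_all, Tn)
    out <- crossprod(Ua, Z) %*% msqrt(S)
    dimnames(out) <- list(ped$animal, traits)
    out
  }
  bv <- draw(Sg(dsa, cfg$true_rG))
  mv <- draw(Sg(dsm, cfg$true_rG))

  n <- length(calves)
  farm <- sprintf("F%02d", sample(seq_len(cfg$n_farms), n, replace = TRUE))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  season <- sample(c("spring", "summer"), n, replace = TRUE)
  dam_age <- sample(c("le6", "gt6"), n, replace = TRUE)
  bw_class <- sample(c("lt33", "ge33"), n, replace = TRUE)
  farm_effects <- matrix(stats::rnorm(cfg$n_farms * Tn), cfg$n_farms, Tn) *
    rep(cfg$farm_sd[traits], each = cfg$n_farms)
  dimnames(farm_effects) <- list(sprintf("F%02d", seq_len(cfg$n_farms)),
                                 traits)
  dam_of <- ped$dam[match(calves, ped$animal)]
  emat <- matrix(stats::rnorm(n * Tn), n, Tn) %*%
    msqrt(Sg(sqrt(cfg$components$sigma2_e), cfg$true_rE))
  pheno <- data.frame(animal = calves, farm = farm, birth_season = season,
                      sex = sex, dam_age_class = dam_age,
                      birth_weight_class = bw_class, stringsAsFactors = FALSE)
  fixed <- matrix(0, n, Tn, dimnames = list(calves, traits))
  for (t in seq_len(Tn)) {
    tr <- traits[t]
    fe <- farm_effects[farm, tr] +
      ifelse(sex == "male", 0.5, -0.5) * cfg$sex_effect[[tr]] +
      ifelse(season == "spring", 0.5, -0.5) * cfg$season_effect[[tr]]
    y <- cfg$mu[[tr]] + fe + bv[calves, tr] + mv[dam_of, tr] + emat[, t]
    if (!is.null(dosage) && t == 1L) {
      for (loc in colnames(dosage)) {
        eff <- cfg$snp_effects[[loc]]
        if (!is.null(eff) && eff != 0)
          y <- y + eff * dosage[calves, loc]
      }
    }
    pheno[[tr]] <- y
    fixed[, t] <- fe
  }
  list(pheno = pheno,
       truth = list(bv = bv, mv = mv, farm_effects = farm_effects,
                    fixed = fixed))
}

#' Simulate repeated measurement series around 365 days
#'
#' Produces long-format repeated measurements on linear growth trajectories
#' through each animal's 365-day value, so that age standardization must
#' recover that value (exactly at zero noise).
#'
#' @param pheno phenotype table from [simulate_phenotypes()] (`$pheno`).
#' @param cfg the [sim_config()].
#' @return long data.frame `animal`, `trait`, `age_days`, `value`.
#' @export
simulate_measurement_series <- function(pheno, cfg) {
  set.seed(.stage_seed(cfg$seed, "measurements"))
  traits <- cfg$traits
  ages <- cfg$measurement_ages
  out <- expand.grid(animal = pheno$animal, trait = traits, age_days = ages,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y365 <- as.matrix(pheno[traits])
  rownames(y365) <- pheno$animal
  base <- y365[cbind(out$animal, out$trait)]
  slope <- cfg$growth_rate[out$trait]
  noise <- stats::rnorm(nrow(out)) * cfg$measurement_noise_sd[out$trait]
  out$value <- base + slope * (out$age_days - 365) + noise
  out
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder allele pairs are drawn at the configured common-allele frequency;
#' each descendant inherits one uniformly chosen allele from each parent
#' (alleles for unknown parents are drawn from the founder frequency).
#'
#' @param ped pedigree (parents-first).
#' @param cfg the [sim_config()].
#' @return long data.frame `animal`, `locus`, `genotype` (sorted allele
#'   pairs); attribute `"dosage"` holds the animals-by-loci rare-allele
#'   count matrix.
#' @export
simulate_genotypes <- function(ped, cfg) {
  set.seed(.stage_seed(cfg$seed, "genotypes"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  loci <- names(cfg$snp_allele_freqs)
  res <- vector("list", length(loci))
  dosage <- matrix(0L, n, length(loci), dimnames = list(ped$animal, loci))
  for (k in seq_along(loci)) {
    p <- cfg$snp_allele_freqs[[loci[k]]]
    al <- cfg$snp_alleles[[loci[k]]]
    if (is.null(al)) al <- c("A", "B")
    a1 <- a2 <- integer(n)            # 1 = common allele, 2 = rare
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      founder_draw <- function() 1L + (stats::runif(1) > p)
      a1[i] <- if (is.na(s)) founder_draw() else
        sample(c(a1[idx[[s]]], a2[idx[[s]]]), 1L)
      a2[i] <- if (is.na(d)) founder_draw() else
        sample(c(a1[idx[[d]]], a2[idx[[d]]]), 1L)
    }
    geno <- vapply(seq_len(n), function(i)
      paste(sort(c(al[a1[i]], al[a2[i]])), collapse = ""), "")
    dosage[, k] <- (a1 == 2L) + (a2 == 2L)
    res[[k]] <- data.frame(animal = ped$animal, locus = loci[k],
                           genotype = geno, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "dosage") <- dosage
  out
}
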