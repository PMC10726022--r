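# Univariate animal model with an uncorrelated maternal genetic effect:
#
#   y = X b + Za a + Zm m + e,   a ~ N(0, A s2a),  m ~ N(0, A s2m),
#   e ~ N(0, I s2e),  Cov(a, m) = 0,
#
# where A is the numerator relationship matrix over all pedigree animals,
# Za links each record to its animal and Zm to the record's dam.  Variance
# components are estimated by EM-REML; breeding values by BLUP from
# Henderson's mixed-model equations at the REML optimum.
#
# The EM expectation step runs on the sparse mixed-model equations
# (src/reml_core.cpp): each iteration refactorizes
#   C* = W'W/s2e + blockdiag(0, Ainv/s2a, Ainv/s2m),  W = [X, Za, Zm],
# by sparse LDL', takes the solution for u-hat, and obtains the exact
# tr(Ainv C_uu) terms from the Takahashi selected inverse of C* on the
# Ainv pattern, giving the classical updates
#   s2u <- (u-hat' Ainv u-hat + tr(Ainv C_uu)) / q
#   s2e <- y'(y - W theta-hat) / (n - rank(X))
# with the restricted log-likelihood (monotone under EM) from
#   -2 logL = (n-p) log 2pi + log|R| + log|G| + log|C*| + y'Py.

# ---- model assembly ---------------------------------------------------------

# Resolve records against the pedigree; augment the pedigree with dummy
# founder dams where a record's dam is unknown but a maternal effect is
# requested.
#' @noRd
.build_model <- function(data, trait, pedigree, fixed = NULL, maternal = TRUE,
                         intercept = TRUE) {
  stopifnot("animal" %in% names(data), trait %in% names(data))
  keep <- !is.na(data[[trait]])
  if (!is.null(fixed))
    keep <- keep & stats::complete.cases(data[fixed])
  d <- data[keep, , drop = FALSE]
  d$animal <- as.character(d$animal)
  miss <- setdiff(d$animal, pedigree$animal)
  if (length(miss))
    stop("recorded animal(s) absent from pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  ped <- pedigree
  dam_of <- ped$dam[match(d$animal, ped$animal)]
  if (maternal && any(is.na(dam_of))) {
    orphan <- d$animal[is.na(dam_of)]
    dummies <- paste0(".dummy_dam_", orphan)
    message(length(orphan),
            " record(s) with unknown dam: dummy founder dams added")
    ped <- pedigree(c(ped$animal, unique(dummies)),
                    c(ped$sire, rep(NA, length(unique(dummies)))),
                    c(ped$dam, rep(NA, length(unique(dummies)))))
    dam_of[is.na(dam_of)] <- dummies
  }
  ia <- match(d$animal, ped$animal)
  idam <- if (maternal) match(dam_of, ped$animal) else NULL

  if (is.null(fixed) || length(fixed) == 0L) {
    X <- if (intercept) matrix(1, nrow(d), 1,
                               dimnames = list(NULL, "(Intercept)")) else
      matrix(0, nrow(d), 0)
  } else {
    for (f in fixed) d[[f]] <- droplevels(factor(d[[f]]))
    contr <- stats::setNames(rep(list("contr.sum"), length(fixed)), fixed)
    X <- stats::model.matrix(stats::reformulate(fixed, intercept = intercept),
                             data = d, contrasts.arg = contr)
  }
  if (ncol(X) > 0 && qr(X)$rank < ncol(X)) stop("fixed-effect design is singular")
  list(data = d, ped = ped, ia = ia, idam = idam, X = X,
       y = d[[trait]], n = nrow(d), p = ncol(X))
}

# Sparse pieces of the mixed-model equations in variance-inverse scaling.
# Returns the component matrices over the full theta dimension p + nb*q.
#' @noRd
.mme_pieces <- function(mod, maternal) {
  n <- mod$n; p <- mod$p; q <- nrow(mod$ped)
  X <- Matrix::Matrix(mod$X, sparse = TRUE)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = mod$ia, x = 1, dims = c(n, q))
  W <- if (maternal) {
    Zm <- Matrix::sparseMatrix(i = seq_len(n), j = mod$idam, x = 1,
                               dims = c(n, q))
    cbind(X, Za, Zm)
  } else cbind(X, Za)
  A <- relationship_matrix(mod$ped)
  Ai <- ainverse(mod$ped, A)
  dim <- p + (1 + maternal) * q
  shift <- function(M, off) {
    Tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
    Matrix::sparseMatrix(i = Tm@i + 1L + off, j = Tm@j + 1L + off, x = Tm@x,
                         dims = c(dim, dim))
  }
  Mww <- as(Matrix::crossprod(W), "generalMatrix")
  Mww <- Matrix::sparseMatrix(
    i = as(Mww, "TsparseMatrix")@i + 1L,
    j = as(Mww, "TsparseMatrix")@j + 1L,
    x = as(Mww, "TsparseMatrix")@x, dims = c(dim, dim))
  Ma <- shift(Ai, p)
  Mm <- if (maternal) shift(Ai, p + q) else NULL
  list(W = W, Mww = Mww, Ma = Ma, Mm = Mm, Ai = Ai,
       logdetA = attr(Ai, "logdet"), dim = dim,
       Wy = as.vector(Matrix::crossprod(W, mod$y)), yty = sum(mod$y^2),
       blocks = list(beta = seq_len(p), a = p + seq_len(q),
                     m = if (maternal) p + q + seq_len(q)))
}

#' EM-REML variance components for the animal model
#'
#' Estimates additive genetic, maternal genetic and residual variance for a
#' trait under the univariate animal model with numerator-relationship
#' covariance and `Cov(a, m) = 0`, by expectation-maximization REML on the
#' sparse mixed-model equations.  The restricted log-likelihood is
#' non-decreasing at every iteration; components that collapse are pinned at
#' a small positive boundary and flagged.  With `accelerate = TRUE` a
#' squared-extrapolation step is attempted each cycle and accepted only when
#' it does not decrease the restricted likelihood, preserving monotonicity
#' while converging in far fewer sweeps.
#'
#' @param data data.frame with an `animal` column, the trait column, and any
#'   fixed-effect factor columns.
#' @param trait trait column name.
#' @param pedigree a [pedigree()]; every recorded animal must appear in it.
#' @param fixed character vector of fixed-effect factor columns (sum-to-zero
#'   coded), or `NULL` for an intercept-only model.
#' @param maternal include the maternal genetic effect (default `TRUE`);
#'   records with unknown dams get dummy founder dams.
#' @param intercept include an intercept (default `TRUE`; `FALSE` with
#'   `fixed = NULL` fits a known zero mean).
#' @param start optional named numeric `c(a=, m=, e=)` starting values;
#'   default splits `var(y)` equally over the fitted components.
#' @param tol relative-change convergence tolerance on all components
#'   (default 1e-8).
#' @param loglik_tol additional convergence requirement on the restricted
#'   log-likelihood change (default 1e-10).
#' @param max_iter maximum EM iterations (default 2000).
#' @param accelerate use the monotonicity-guarded accelerated scheme
#'   (default `FALSE`).
#' @return object of class `buf_reml`: list with `sigma2` (named `a`, `m`,
#'   `e`), `sigma2_p`, `se` (component standard errors, see [reml_se()]),
#'   `vcov_components`, `loglik`, `loglik_trace`, `converged`,
#'   `n_iterations`, `boundary` (logical per component), `non_identifiable`,
#'   plus the model frame needed by [blup_ebv()].
#' @export
em_reml <- function(data, trait, pedigree, fixed = NULL, maternal = TRUE,
                    intercept = TRUE, start = NULL, tol = 1e-8,
                    loglik_tol = 1e-10, max_iter = 2000, accelerate = FALSE) {
  mod <- .build_model(data, trait, pedigree, fixed, maternal, intercept)
  q <- nrow(mod$ped)
  n <- mod$n; p <- mod$p
  y <- mod$y
  vary <- stats::var(y)
  if (!is.finite(vary) || vary <= 0)
    stop("trait has no variance; components not identifiable")
  # boundary floor: small enough to be "zero" for any h2 purpose, large
  # enough that the determinant terms in the restricted likelihood keep
  # ~8 significant digits (a 1e-12 floor costs the identity its precision)
  pin <- 1e-8 * vary

  pieces <- .mme_pieces(mod, maternal)

  rec <- mod$ped[mod$ia, ]
  non_ident <- !maternal && all(is.na(rec$sire) & is.na(rec$dam)) &&
    !anyDuplicated(mod$data$animal)
  if (non_ident)
    warning("no pedigree links among recorded animals: additive and ",
            "residual variance are confounded (likelihood flat); ",
            "returning a boundary result")

  k_split <- if (maternal) 3 else 2
  sig0 <- if (!is.null(start)) {
    pmax(c(e = unname(start[["e"]]), a = unname(start[["a"]]),
           if (maternal) c(m = unname(start[["m"]]))), pin)
  } else {
    s <- vary / k_split
    c(e = s, a = s, if (maternal) c(m = s))
  }
  if (non_ident) sig0 <- c(e = vary, a = pin)

  arrays <- .engine_arrays(pieces, maternal)
  res <- .em_reml_cpp(
    arrays$Cp, arrays$Ci, arrays$vww, arrays$va, arrays$vm, arrays$perm,
    pieces$Wy, pieces$yty, n, p, q, if (maternal) 2L else 1L,
    pieces$logdetA,
    arrays$tra_r, arrays$tra_c, arrays$tra_w,
    arrays$trm_r, arrays$trm_c, arrays$trm_w,
    arrays$qfa_i, arrays$qfa_j, arrays$qfa_w,
    arrays$qfm_i, arrays$qfm_j, arrays$qfm_w,
    unname(sig0), tol, loglik_tol, if (non_ident) 0L else as.integer(max_iter),
    accelerate, pin)

  sig <- res$sigma2                # order: e, a, m
  boundary <- sig <= pin * (1 + 1e-9)
  sigma2 <- c(a = sig[2], m = if (maternal) sig[3] else NA_real_, e = sig[1])
  fit <- structure(list(sigma2 = sigma2,
                        sigma2_p = sum(sig),
                        loglik = res$loglik, loglik_trace = res$loglik_trace,
                        converged = res$converged && !non_ident,
                        n_iterations = res$n_iterations,
                        boundary = c(a = boundary[2],
                                     m = if (maternal) boundary[3] else NA,
                                     e = boundary[1]),
                        non_identifiable = non_ident, maternal = maternal,
                        trait = trait, fixed = fixed, model = mod,
                        theta = res$theta, .pieces = pieces),
                   class = "buf_reml")
  se <- tryCatch(reml_se(fit), error = function(e) NULL)
  if (!is.null(se)) {
    fit$se <- se$se
    fit$vcov_components <- se$vcov
  }
  fit
}

# Build the permuted upper-CSC union pattern plus aligned value arrays and
# the Takahashi trace / quadratic-form index sets for the C++ engine.
#' @noRd
.engine_arrays <- function(pieces, maternal) {
  dim <- pieces$dim
  S <- pieces$Mww + pieces$Ma
  if (maternal) S <- S + pieces$Mm
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(S), LDL = TRUE,
                         super = FALSE, perm = TRUE)
  perm <- Ch@perm + 1L              # permuted i holds original perm[i]
  ip <- integer(dim)
  ip[perm] <- seq_len(dim)

  upper_arrays <- function(M) {
    Tm <- as(as(M, "TsparseMatrix"), "generalMatrix")
    i <- ip[Tm@i + 1L]; j <- ip[Tm@j + 1L]; x <- Tm@x
    keep <- i <= j
    list(i = i[keep], j = j[keep], x = x[keep])
  }
  comps <- list(upper_arrays(pieces$Mww), upper_arrays(pieces$Ma),
                if (maternal) upper_arrays(pieces$Mm))
  keys <- lapply(comps[!vapply(comps, is.null, TRUE)],
                 function(a) (a$j - 1) * dim + a$i)
  ukey <- sort(unique(unlist(keys)))
  uj <- (ukey - 1) %/% dim + 1
  ui <- ukey - (uj - 1) * dim
  Cp <- c(0L, cumsum(tabulate(uj, nbins = dim)))
  align <- function(a) {
    v <- numeric(length(ukey))
    if (!is.null(a)) v[match((a$j - 1) * dim + a$i, ukey)] <- a$x
    v
  }
  # trace entries: Ainv pattern at the block offset, permuted, one
  # orientation per unordered pair, off-diagonals doubled
  trace_arrays <- function(off) {
    Tm <- as(as(pieces$Ai, "TsparseMatrix"), "generalMatrix")
    i <- ip[Tm@i + 1L + off]; j <- ip[Tm@j + 1L + off]; x <- Tm@x
    keep <- i >= j
    list(r = i[keep] - 1L, c = j[keep] - 1L,
         w = x[keep] * ifelse(i[keep] == j[keep], 1, 2))
  }
  qf_arrays <- function(off) {
    Tm <- as(as(pieces$Ai, "TsparseMatrix"), "generalMatrix")
    list(i = Tm@i + off, j = Tm@j + off, w = Tm@x)   # 0-based theta coords
  }
  p <- length(pieces$blocks$beta)
  qn <- length(pieces$blocks$a)
  tra <- trace_arrays(p)
  qfa <- qf_arrays(p)
  if (maternal) {
    trm <- trace_arrays(p + qn)
    qfm <- qf_arrays(p + qn)
  } else {
    trm <- list(r = integer(0), c = integer(0), w = numeric(0))
    qfm <- list(i = integer(0), j = integer(0), w = numeric(0))
  }
  list(Cp = as.integer(Cp), Ci = as.integer(ui - 1L),
       vww = align(comps[[1]]), va = align(comps[[2]]),
       vm = if (maternal) align(comps[[3]]) else numeric(0),
       perm = as.integer(perm - 1L),
       tra_r = as.integer(tra$r), tra_c = as.integer(tra$c), tra_w = tra$w,
       trm_r = as.integer(trm$r), trm_c = as.integer(trm$c), trm_w = trm$w,
       qfa_i = as.integer(qfa$i), qfa_j = as.integer(qfa$j), qfa_w = qfa$w,
       qfm_i = as.integer(qfm$i), qfm_j = as.integer(qfm$j), qfm_w = qfm$w)
}

#' @export
print.buf_reml <- function(x, ...) {
  cat(sprintf("Animal-model EM-REML for %s (%s maternal effect)\n", x$trait,
              if (x$maternal) "with" else "without"))
  comp <- c("a", if (x$maternal) "m", "e")
  for (u in comp) {
    se <- if (!is.null(x$se)) sprintf(" +/- %.4g", x$se[[u]]) else ""
    b <- if (isTRUE(x$boundary[[u]])) " [boundary]" else ""
    cat(sprintf("  sigma2_%s = %.6g%s%s\n", u, x$sigma2[[u]], se, b))
  }
  cat(sprintf("  sigma2_p = %.6g\n", x$sigma2_p))
  cat(sprintf("loglik %.6f after %d iterations (%sconverged)\n", x$loglik,
              x$n_iterations, if (x$converged) "" else "NOT "))
  if (x$non_identifiable) cat("flag: non-identifiable variance split\n")
  invisible(x)
}

#' Standard errors from an information matrix
#'
#' Utility: square roots of the diagonal of the inverse information matrix.
#'
#' @param info positive-definite information matrix.
#' @return numeric vector of standard errors.
#' @export
information_se <- function(info) sqrt(diag(solve(info)))

#' Average-information standard errors at the REML optimum
#'
#' Computes the average-information matrix `AI[i,j] = 0.5 y'P Ki P Kj P y`
#' over the free variance components at the optimum of an [em_reml()] fit
#' (with `Ka = Za A Za'`, `Km = Zm A Zm'`, `Ke = I`) and returns standard
#' errors from its inverse.  `P`-products are evaluated through the sparse
#' mixed-model equations: `P w = (w - W thetahat_w)/s2e`.  Components on the
#' zero boundary are excluded from the information matrix; their SE is
#' reported as 0 with the boundary flag.  The SE of the phenotypic variance
#' follows from the summed covariance.
#'
#' @param fit a converged (or final-state) `buf_reml` object.
#' @return list with `se` (named `a`, `m`, `e`, `p`), `vcov` (component
#'   covariance over all components, zero rows/cols for boundary ones), and
#'   `boundary` flags.
#' @export
reml_se <- function(fit) {
  stopifnot(inherits(fit, "buf_reml"))
  pieces <- fit$.pieces
  if (is.null(pieces)) stop("fit does not carry its model matrices")
  mod <- fit$model
  s2 <- fit$sigma2
  s2e <- s2[["e"]]
  Cs <- pieces$Mww / s2e + pieces$Ma / s2[["a"]]
  if (fit$maternal) Cs <- Cs + pieces$Mm / s2[["m"]]
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Cs), LDL = TRUE,
                         super = FALSE, perm = TRUE)
  W <- pieces$W
  Pw <- function(w) {
    th <- as.vector(Matrix::solve(Ch, Matrix::crossprod(W, w) / s2e))
    (w - as.vector(W %*% th)) / s2e
  }
  Amult <- function(v) as.vector(Matrix::solve(pieces$Ai, v))
  Kmult <- function(idx, w) {
    v <- numeric(nrow(mod$ped))
    agg <- tapply(w, idx, sum)
    v[as.integer(names(agg))] <- agg
    Amult(v)[idx]
  }
  Py <- Pw(mod$y)
  comp <- c("a", if (fit$maternal) "m", "e")
  u_list <- list(a = Kmult(mod$ia, Py),
                 m = if (fit$maternal) Kmult(mod$idam, Py),
                 e = Py)
  free <- comp[!vapply(comp, function(u) isTRUE(fit$boundary[[u]]), TRUE)]
  vc <- matrix(0, length(comp), length(comp), dimnames = list(comp, comp))
  if (length(free) >= 1) {
    Pu <- lapply(free, function(u) Pw(u_list[[u]]))
    names(Pu) <- free
    AI <- matrix(0, length(free), length(free), dimnames = list(free, free))
    for (i in seq_along(free)) for (j in i:length(free)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(u_list[[free[i]]] * Pu[[free[j]]])
    }
    vc[free, free] <- solve(AI)
  }
  se <- stats::setNames(sqrt(pmax(diag(vc), 0)), comp)
  se_p <- sqrt(max(sum(vc), 0))
  list(se = c(se, p = se_p), vcov = vc, boundary = fit$boundary[comp])
}

# ---- mixed-model equations and BLUP ----------------------------------------

#' Henderson's mixed-model equations for the animal model
#'
#' Builds (and solves) the MME
#' \deqn{[W'W + diag(0, A^{-1} k_a, A^{-1} k_m)] \theta = W'y}
#' with `W = [X, Za, Zm]`, `k_a = s2e/s2a`, `k_m = s2e/s2m`.  All pedigree
#' animals are present in the genetic blocks through A-inverse, so animals
#' without records receive breeding values via their relatives.
#'
#' @inheritParams em_reml
#' @param components named numeric `c(a=, m=, e=)` variance components (the
#'   `m` entry is ignored when `maternal = FALSE`).
#' @return list with the sparse coefficient matrix `C`, right-hand side
#'   `rhs`, `solution`, index `blocks` (`beta`, `a`, `m`), the (possibly
#'   dam-augmented) `pedigree`, and `sigma2`.
#' @export
build_mme <- function(data, trait, pedigree, fixed = NULL, maternal = TRUE,
                      intercept = TRUE, components) {
  s2a <- components[["a"]]
  s2e <- components[["e"]]
  s2m <- if (maternal) components[["m"]] else NA_real_
  if (maternal && s2a <= 0 && s2m <= 0)
    stop("both genetic variances are zero; no genetic effects to predict")
  if (s2a <= 0 && !maternal)
    message("additive variance is zero: system reduces to the fixed model")
  mod <- .build_model(data, trait, pedigree, fixed, maternal, intercept)
  q <- nrow(mod$ped)
  n <- mod$n; p <- mod$p
  Ai <- ainverse(mod$ped)
  ok <- tryCatch({Matrix::Cholesky(Matrix::forceSymmetric(Ai)); TRUE},
                 error = function(e) FALSE)
  if (!ok) Ai <- Ai + Matrix::Diagonal(q, 1e-8)
  X <- Matrix::Matrix(mod$X, sparse = TRUE)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = mod$ia, x = 1,
                             dims = c(n, q))
  W <- if (maternal) {
    Zm <- Matrix::sparseMatrix(i = seq_len(n), j = mod$idam, x = 1,
                               dims = c(n, q))
    cbind(X, Za, Zm)
  } else cbind(X, Za)
  C <- Matrix::crossprod(W)
  ia_block <- p + seq_len(q)
  C[ia_block, ia_block] <- C[ia_block, ia_block] + Ai * (s2e / max(s2a, 1e-300))
  blocks <- list(beta = seq_len(p), a = ia_block)
  if (maternal) {
    im_block <- p + q + seq_len(q)
    C[im_block, im_block] <- C[im_block, im_block] + Ai * (s2e / max(s2m, 1e-300))
    blocks$m <- im_block
  }
  rhs <- as.vector(Matrix::crossprod(W, mod$y))
  sol <- as.vector(Matrix::solve(C, rhs))
  list(C = C, rhs = rhs, solution = sol, blocks = blocks,
       pedigree = mod$ped, sigma2 = c(a = s2a, m = s2m, e = s2e),
       model = mod)
}

#' Breeding values (BLUP) at the REML optimum
#'
#' Solves the mixed-model equations at a fit's estimated variance components
#' and returns per-animal predicted breeding values; prediction-error
#' variances come from the corresponding diagonal of the inverse coefficient
#' matrix times the residual variance.
#'
#' @param fit a `buf_reml` object from [em_reml()].
#' @param pev compute prediction-error variances (inverts the full MME
#'   coefficient matrix; set `FALSE` for large systems when only EBVs are
#'   needed).
#' @return data.frame with `animal`, `ebv_direct`, and when the model has a
#'   maternal effect `ebv_maternal`, plus `pev_direct` (and `pev_maternal`)
#'   when `pev = TRUE`.  Attribute `"beta"` carries the fixed-effect
#'   solutions.
#' @export
blup_ebv <- function(fit, pev = TRUE) {
  stopifnot(inherits(fit, "buf_reml"))
  comp <- c(a = fit$sigma2[["a"]],
            m = if (fit$maternal) fit$sigma2[["m"]] else NA_real_,
            e = fit$sigma2[["e"]])
  mme <- build_mme(fit$model$data, fit$trait, fit$model$ped,
                   fixed = fit$fixed, maternal = fit$maternal,
                   intercept = fit$model$p > 0 &&
                     colnames(fit$model$X)[1] == "(Intercept)",
                   components = comp)
  ids <- mme$pedigree$animal
  out <- data.frame(animal = ids,
                    ebv_direct = mme$solution[mme$blocks$a],
                    stringsAsFactors = FALSE)
  if (fit$maternal) out$ebv_maternal <- mme$solution[mme$blocks$m]
  if (pev) {
    Ci <- as.matrix(Matrix::solve(mme$C))
    s2e <- comp[["e"]]
    out$pev_direct <- pmax(diag(Ci)[mme$blocks$a] * s2e, 0)
    if (fit$maternal)
      out$pev_maternal <- pmax(diag(Ci)[mme$blocks$m] * s2e, 0)
  }
  attr(out, "beta") <- mme$solution[mme$blocks$beta]
  out
}
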