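# Pedigree handling and the numerator relationship matrix.
#
# The additive (numerator) relationship matrix A holds twice the kinship
# coefficients among pedigree members; its diagonal is 1 + F_i where F_i is
# the inbreeding coefficient.  A enters the animal model as the covariance
# structure of both the direct and the maternal genetic effect.

#' Construct a validated pedigree
#'
#' Builds a pedigree object from animal/sire/dam identifier vectors.  Unknown
#' parents may be given as `NA`, `""`, or `"0"`.  Parents that appear only in
#' the sire or dam column are added as founder entries (with a warning).  The
#' returned pedigree is topologically sorted so that parents always precede
#' their offspring, the ordering required by the tabular method.
#'
#' @param animal,sire,dam character vectors of equal length; identifiers are
#'   treated as opaque strings.
#' @return a `data.frame` of class `buf_pedigree` with columns
#'   `animal`, `sire`, `dam` (parents `NA` when unknown), sorted parents-first.
#' @examples
#' pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  stopifnot(length(animal) == length(sire), length(animal) == length(dam))
  sire[.is_missing_id(sire)] <- NA_character_
  dam[.is_missing_id(dam)] <- NA_character_
  if (any(.is_missing_id(animal)))
    stop("missing animal identifier in pedigree")
  if (anyDuplicated(animal))
    stop("duplicate animal id(s) in pedigree: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  self <- !is.na(sire) & sire == animal | !is.na(dam) & dam == animal
  if (any(self))
    stop("animal is its own parent (cycle): ",
         paste(animal[self], collapse = ", "))

  # auto-add undeclared parents as founders
  parents <- unique(stats::na.omit(c(sire, dam)))
  undeclared <- setdiff(parents, animal)
  if (length(undeclared)) {
    warning(length(undeclared), " parent id(s) absent from the animal column; ",
            "added as founders: ", paste(undeclared, collapse = ", "))
    animal <- c(animal, undeclared)
    sire <- c(sire, rep(NA_character_, length(undeclared)))
    dam <- c(dam, rep(NA_character_, length(undeclared)))
  }

  ord <- .topo_sort(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(ped) <- c("buf_pedigree", "data.frame")
  ped
}

# Kahn's algorithm; errors on cycles naming an involved animal.
#' @noRd
.topo_sort <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), NA_integer_, idx[sire])
  di <- ifelse(is.na(dam), NA_integer_, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n)
    stop("pedigree contains a cycle involving: ",
         paste(animal[setdiff(seq_len(n), out)], collapse = ", "))
  out
}

#' Read a pedigree file
#'
#' Reads a delimited text file (comma or tab, auto-detected) with a header
#' containing `animal`, `sire` and `dam` columns and returns a validated,
#' topologically sorted [pedigree()].  Unknown parents may be encoded as an
#' empty field, `0` or `NA`.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects.
#' @return a `buf_pedigree`.
#' @export
read_pedigree <- function(path, sep = NULL) {
  d <- .read_delim_auto(path, sep)
  names(d) <- tolower(names(d))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(d)))
    stop("pedigree file must have columns animal, sire, dam")
  pedigree(d$animal, d$sire, d$dam)
}

# parents-first check used by downstream consumers given a bare data.frame
#' @noRd
.check_sorted <- function(ped) {
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    if (any(pos[p[known]] >= pos[ped$animal[known]]))
      stop("pedigree is not sorted parents-first; use pedigree() to sort")
  }
  invisible(TRUE)
}

#' Numerator relationship matrix (tabular method)
#'
#' Computes the additive relationship matrix A by the recursive tabular
#' method: for animal i with parents s and d (unknown parents contribute 0),
#' `A[i, j] = 0.5 * (A[j, s] + A[j, d])` for previously processed j, and
#' `A[i, i] = 1 + 0.5 * A[s, d]`.  Founders are assumed unrelated and
#' non-inbred.
#'
#' @param ped a [pedigree()] (or a data.frame already sorted parents-first
#'   with columns animal/sire/dam; an unsorted one is an error).
#' @return symmetric numeric matrix with dimnames = animal ids; the diagonal
#'   equals 1 + F.
#' @export
relationship_matrix <- function(ped) {
  .check_sorted(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients from a relationship matrix
#'
#' @param A a numerator relationship matrix as returned by
#'   [relationship_matrix()].
#' @return named numeric vector `F = diag(A) - 1`.
#' @export
inbreeding <- function(A) {
  f <- diag(A) - 1
  if (any(f < -1e-10)) stop("invalid relationship matrix: diagonal below 1")
  pmax(f, 0)
}

#' Inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules with the
#' inbreeding correction: each animal contributes the outer product of
#' (1, -0.5, -0.5) on (animal, sire, dam), scaled by the inverse Mendelian
#' sampling variance `m_i = 1 - 0.25 * (A_ss + A_dd)` (unknown-parent
#' terms omitted).  Identical to inverting the dense tabular A, but O(n) in
#' storage and time, which matters inside the mixed-model equations for
#' simulated herds of a few thousand animals.
#'
#' @param ped a [pedigree()].
#' @param A optional precomputed [relationship_matrix()] (re-used for the
#'   parental diagonal terms); computed if missing.
#' @return sparse symmetric `Matrix::dsCMatrix` with dimnames = animal ids.
#' @export
ainverse <- function(ped, A = NULL) {
  .check_sorted(ped)
  if (is.null(A)) A <- relationship_matrix(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  dA <- diag(A)
  ii <- jj <- integer(9L * n); xx <- numeric(9L * n)
  mend <- numeric(n)                 # Mendelian sampling variances
  k <- 0L
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    m <- 1 - 0.25 * ((if (!is.na(s)) dA[s] else 0) +
                     (if (!is.na(d)) dA[d] else 0))
    mend[i] <- m
    w <- 1 / m
    trio <- c(i, s, d)
    coef <- c(1, -0.5, -0.5)
    keep <- !is.na(trio)
    trio <- trio[keep]; coef <- coef[keep]
    nt <- length(trio)
    pos <- k + seq_len(nt * nt)
    ii[pos] <- rep(trio, times = nt)
    jj[pos] <- rep(trio, each = nt)
    xx[pos] <- w * as.vector(outer(coef, coef))
    k <- k + nt * nt
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Ai <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                             dimnames = list(ped$animal, ped$animal))
  Ai <- Matrix::forceSymmetric(Ai)
  # det(A) = prod of Mendelian sampling variances (useful for likelihoods)
  attr(Ai, "logdet") <- sum(log(mend))
  Ai
}

#' @export
print.buf_pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("Pedigree: %d animals (%d founders), parents-first order\n",
              nrow(x), founders))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
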