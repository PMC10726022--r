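# Shared fixtures: small pedigrees and data sets built in code.

# 2 sires, 4 dams, 8 calves over two sire families
toy_ped <- function() {
  pedigree(
    c("S1", "S2", "D1", "D2", "D3", "D4",
      "C1", "C2", "C3", "C4", "C5", "C6", "C7", "C8"),
    c(NA, NA, NA, NA, NA, NA, "S1", "S1", "S1", "S2", "S2", "S2", "S1", "S2"),
    c(NA, NA, NA, NA, NA, NA, "D1", "D1", "D2", "D2", "D3", "D3", "D4", "D4"))
}

# phenotypes on the toy pedigree's calves with known generative components
toy_records <- function(seed = 7, s2a = 4, s2m = 1, s2e = 2, mu = 10) {
  set.seed(seed)
  ped <- toy_ped()
  A <- relationship_matrix(ped)
  U <- chol(A)
  a <- as.vector(crossprod(U, rnorm(nrow(ped)))) * sqrt(s2a)
  m <- as.vector(crossprod(U, rnorm(nrow(ped)))) * sqrt(s2m)
  calves <- paste0("C", 1:8)
  ia <- match(calves, ped$animal)
  idam <- match(ped$dam[ia], ped$animal)
  y <- mu + a[ia] + m[idam] + rnorm(8, 0, sqrt(s2e))
  list(ped = ped, data = data.frame(animal = calves, y = y),
       A = A, ia = ia, idam = idam)
}

# random valid pedigree of <= n_max animals (founders + random matings)
random_ped <- function(n_max = 10, seed = 1) {
  set.seed(seed)
  n_founder <- sample(2:4, 1)
  ids <- sprintf("A%02d", seq_len(n_max))
  sire <- dam <- rep(NA_character_, n_max)
  for (i in (n_founder + 1):n_max) {
    pool <- ids[seq_len(i - 1)]
    sire[i] <- sample(pool, 1)
    dam[i] <- sample(setdiff(pool, sire[i]), 1)
  }
  pedigree(ids, sire, dam)
}

# unbalanced two-factor data set for the fixed-model oracle tests
two_factor_data <- function(seed = 21, n = 8) {
  set.seed(seed)
  d <- data.frame(
    f1 = factor(c("a", "a", "a", "b", "b", "b", "b", "a"))[seq_len(n)],
    f2 = factor(c("x", "y", "x", "y", "x", "y", "y", "y"))[seq_len(n)])
  d$y <- 5 + 2 * (d$f1 == "b") - 1.5 * (d$f2 == "y") + rnorm(n, 0, 0.7)
  d$farm <- "F1"
  d$animal <- sprintf("An%02d", seq_len(n))
  d
}
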