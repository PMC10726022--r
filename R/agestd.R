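# Age standardization: project each animal's successive measurements onto a
# common target age (365 d) by two-point linear interpolation, or linear
# extrapolation from the two measurements nearest the target when the target
# lies outside the observed range.

#' Estimate a trait value at a target age
#'
#' Linear interpolation between the two measurements flanking `target_age`,
#' or linear extrapolation from the two measurements nearest the target when
#' it falls outside the observed age range.  A single measurement is returned
#' as-is and flagged unstandardized.
#'
#' @param age_days integer vector of measurement ages (days, > 0).
#' @param value numeric vector of measurements at those ages.
#' @param target_age target age in days (default 365).
#' @return list with elements `value` (numeric), `method` (one of
#'   `"exact"`, `"interpolated"`, `"extrapolated"`, `"single"`), and
#'   `extrapolation_days` (0 when the target is bracketed; otherwise the
#'   distance from the target to the nearest measurement).
#' @examples
#' value_at_age(c(335, 395), c(100, 160))        # -> 130
#' value_at_age(c(300, 330), c(100, 130))        # -> 165 (extrapolated)
#' @export
value_at_age <- function(age_days, value, target_age = 365) {
  if (length(age_days) == 0L) stop("empty measurement series")
  stopifnot(length(age_days) == length(value))
  if (any(!is.finite(value))) stop("non-finite measurement value")
  ord <- order(age_days)
  age_days <- as.numeric(age_days[ord])
  value <- value[ord]
  dup <- duplicated(age_days)
  if (any(dup)) {
    for (a in unique(age_days[dup])) {
      v <- value[age_days == a]
      if (max(v) - min(v) > 0)
        stop("two measurements at age ", a, " days with different values")
    }
    value <- value[!dup]
    age_days <- age_days[!dup]
  }
  n <- length(age_days)
  hit <- which(age_days == target_age)
  if (length(hit))
    return(list(value = value[hit[1L]], method = "exact",
                extrapolation_days = 0))
  if (n == 1L)
    return(list(value = value, method = "single",
                extrapolation_days = abs(target_age - age_days)))
  if (target_age > min(age_days) && target_age < max(age_days)) {
    lo <- max(which(age_days < target_age))
    hi <- lo + 1L
    method <- "interpolated"
    extrap <- 0
  } else {
    # two points nearest the target (= the two at the near end of the range)
    nearest <- order(abs(age_days - target_age))[1:2]
    lo <- min(nearest); hi <- max(nearest)
    method <- "extrapolated"
    extrap <- min(abs(target_age - age_days))
  }
  slope <- (value[hi] - value[lo]) / (age_days[hi] - age_days[lo])
  list(value = value[lo] + slope * (target_age - age_days[lo]),
       method = method, extrapolation_days = extrap)
}

#' Standardize a long-format measurement table to a target age
#'
#' Applies [value_at_age()] per animal and trait, producing one row per
#' animal with one column per trait.  Per-cell QC information (method and
#' extrapolation distance) is attached as the `"qc"` attribute; cells whose
#' extrapolation distance exceeds `max_extrapolation_days` are flagged but
#' kept.
#'
#' @param raw data.frame with columns `animal`, `trait`, `age_days`, `value`.
#' @param target_age target age in days (default 365).
#' @param max_extrapolation_days QC threshold in days (default 90).
#' @return wide data.frame (`animal` + trait columns) with attribute `qc`, a
#'   long data.frame of `animal`, `trait`, `method`, `extrapolation_days`,
#'   `flagged`.
#' @export
standardize_table <- function(raw, target_age = 365,
                              max_extrapolation_days = 90) {
  need <- c("animal", "trait", "age_days", "value")
  if (!all(need %in% names(raw)))
    stop("raw table must have columns ", paste(need, collapse = ", "))
  raw$animal <- as.character(raw$animal)
  raw$trait <- as.character(raw$trait)
  animals <- unique(raw$animal)
  traits <- unique(raw$trait)
  wide <- data.frame(animal = animals, stringsAsFactors = FALSE)
  qc <- expand.grid(animal = animals, trait = traits,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qc$method <- NA_character_
  qc$extrapolation_days <- NA_real_
  key <- paste(raw$animal, raw$trait, sep = "\r")
  split_idx <- split(seq_len(nrow(raw)), key)
  for (tr in traits) wide[[tr]] <- NA_real_
  for (k in seq_len(nrow(qc))) {
    rows <- split_idx[[paste(qc$animal[k], qc$trait[k], sep = "\r")]]
    if (is.null(rows)) next
    est <- value_at_age(raw$age_days[rows], raw$value[rows], target_age)
    wide[wide$animal == qc$animal[k], qc$trait[k]] <- est$value
    qc$method[k] <- est$method
    qc$extrapolation_days[k] <- est$extrapolation_days
  }
  qc$flagged <- !is.na(qc$extrapolation_days) &
    (qc$extrapolation_days > max_extrapolation_days | qc$method == "single")
  attr(wide, "qc") <- qc
  wide
}
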