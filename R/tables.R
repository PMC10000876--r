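## Categorical vocabularies for crown morphotype scoring. Raw scoring
## tokens ("V-shape", "no spur", "-") are decoded to canonical states; "-"
## marks the unremarkable state (V profile / spur present / c1 normal) and
## an empty cell marks an unscored (missing) side.
.morpho_vocab <- list(
  m1_c1c2_profile = c("V", "U", "missing"),
  m2_spur = c("present", "absent", "missing"),
  m3_c1 = c("normal", "reduced", "big", "missing")
)

decode_morpho_token <- function(trait, token) {
  tok <- trimws(token)
  lut <- switch(
    trait,
    m1_c1c2_profile = stats::setNames(
      c("V", "U", "V", "U", "V", "missing"),
      c("V-shape", "U-shape", "V", "U", "-", "")),
    m2_spur = stats::setNames(
      c("present", "absent", "present", "absent", "missing"),
      c("-", "no spur", "present", "absent", "")),
    m3_c1 = stats::setNames(
      c("normal", "normal", "reduced", "big", "missing"),
      c("-", "normal", "reduced", "big", "")),
    stop("unknown trait: ", trait)
  )
  out <- lut[match(tok, names(lut))]
  if (anyNA(out))
    stop(sprintf("unknown %s token: '%s'", trait, tok[is.na(out)][1L]))
  unname(out)
}

decode_cohort <- function(token) {
  tok <- trimws(token)
  out <- ifelse(tok %in% c("WT", "wt"), "WT",
         ifelse(tok %in% c("mutant", "Jag1fl/fl", "K14Cre;Jag1fl/fl"),
                "mutant", NA))
  if (anyNA(out)) stop("unknown cohort token: '", tok[is.na(out)][1L], "'")
  out
}

#' Read a crown morphotype table
#'
#' Reads per-specimen categorical crown trait scores in long form: one row
#' per specimen-side with columns `specimen`, `cohort`, `side`,
#' `m1_c1c2` (V/U profile of the c1-c2 interconnection on the upper first
#' molar), `m2_spur` (vestibular spur of c1 on the second upper molar),
#' `m3_c1` (state of c1 on the third upper molar) and `abnormal_cusp`
#' (free-text code, optional). Raw scoring tokens are decoded: `"-"` means
#' the unremarkable state (V-shape profile, spur present, c1 normal),
#' `"no spur"` means absent, and an empty cell means unscored.
#'
#' @param path path to the CSV file.
#' @return data frame of class `morphotype_table` with canonical columns
#'   `specimen`, `cohort` (WT/mutant), `side` (right/left),
#'   `m1_c1c2_profile`, `m2_spur`, `m3_c1`, `abnormal_cusp`.
#' @export
read_morphotype_table <- function(path) {
  if (!file.exists(path)) stop("morphotype table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  need <- c("specimen", "cohort", "side", "m1_c1c2", "m2_spur", "m3_c1")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  side <- tolower(trimws(raw$side))
  if (!all(side %in% c("right", "left")))
    stop("side must be 'right' or 'left'")
  out <- data.frame(
    specimen = trimws(raw$specimen),
    cohort = decode_cohort(raw$cohort),
    side = side,
    m1_c1c2_profile = decode_morpho_token("m1_c1c2_profile", raw$m1_c1c2),
    m2_spur = decode_morpho_token("m2_spur", raw$m2_spur),
    m3_c1 = decode_morpho_token("m3_c1", raw$m3_c1),
    abnormal_cusp = if ("abnormal_cusp" %in% names(raw))
      sub("^-$", "", trimws(raw$abnormal_cusp)) else "",
    stringsAsFactors = FALSE
  )
  class(out) <- c("morphotype_table", "data.frame")
  out
}

#' Path to the packaged upper-molar morphotype fixture
#'
#' A transcription of the published per-specimen scoring of upper-molar
#' crown variants in 21 wild-type and 33 *K14Cre;Jagged1-fl/fl* mice (108
#' specimen-sides), shipped with the package so frequency computations can
#' be reproduced without external data.
#'
#' @return file path to the CSV.
#' @export
morphotype_fixture_path <- function() {
  system.file("extdata", "upper_molar_morphotypes.csv",
              package = "odontomorph", mustWork = TRUE)
}

#' Read a linear measurement table
#'
#' Columns: `specimen`, `cohort`, `tooth`, and any of the measurement
#' columns `L`, `W`, `d1`..`d5` in mm. Present values must be strictly
#' positive and finite; empty cells are allowed and read as `NA`.
#'
#' @param path path to the CSV file.
#' @return data frame of class `measurement_table`.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("measurement table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "cohort", "tooth")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  raw$cohort <- decode_cohort(raw$cohort)
  meas <- intersect(c("L", "W", paste0("d", 1:5)), names(raw))
  if (!length(meas)) stop("no measurement columns found")
  for (m in meas) {
    v <- suppressWarnings(as.numeric(raw[[m]]))
    if (any(!is.na(raw[[m]]) & raw[[m]] != "" & is.na(v)))
      stop("non-numeric value in column ", m)
    if (any(v[!is.na(v)] <= 0) || any(is.nan(v) | is.infinite(v)))
      stop("measurements must be strictly positive and finite (", m, ")")
    raw[[m]] <- v
  }
  class(raw) <- c("measurement_table", "data.frame")
  raw
}
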