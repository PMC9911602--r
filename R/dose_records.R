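## Ingestion of literature dose tables and combination of duplicate records.

#' Confidence that a no-survivor result demonstrates a target efficacy
#'
#' Probability that at least one survivor would have been observed among `n`
#' independently treated insects if the per-insect kill probability were
#' exactly `target_efficacy`:
#' \deqn{C = 1 - \mathrm{efficacy}^{n}.}
#' A reported minimum effective dose backed by a large confirmatory sample
#' (e.g. the probit-9 standard of 93,613 insects for 99.9968% efficacy at
#' 95% confidence) carries a confidence near 1; a dose backed by a dozen
#' insects carries almost none. These confidences are the weights used when
#' combining multiple reported doses for one species and when constructing
#' censored intervals.
#'
#' @param n number of specimens treated with no survivors (non-negative
#'   integer, vectorized).
#' @param target_efficacy per-insect kill probability being demonstrated,
#'   strictly between 0 and 1 (default 0.9999, i.e. probit-8.72).
#' @return confidence value(s) in \[0, 1\]; `NA` where `n` is `NA`.
#' @seealso [prob_no_survivors()] for the complementary probability.
#' @examples
#' confidence_of_efficacy(93613, 0.999968) # ~0.95: the probit-9 standard
#' confidence_of_efficacy(12, 0.9999)      # tiny: 12 insects prove little
#' @export
confidence_of_efficacy <- function(n, target_efficacy = 0.9999) {
  if (length(target_efficacy) != 1L || !is.finite(target_efficacy) ||
      target_efficacy <= 0 || target_efficacy >= 1) {
    stop("target_efficacy must be strictly between 0 and 1", call. = FALSE)
  }
  if (any(n < 0, na.rm = TRUE)) stop("n must be non-negative", call. = FALSE)
  # log-scale evaluation keeps precision at the n ~ 1e5 typical of
  # confirmatory phytosanitary trials
  -expm1(n * log(target_efficacy))
}

#' Efficacy policy for combining reported doses
#'
#' Bundles the two probabilities governing record combination: the efficacy
#' level whose demonstration is being weighed (`target_efficacy`) and the
#' confidence above which a reported dose is considered fully proven
#' (`retention_confidence`). When several records for one species exceed the
#' retention confidence, only the lowest such dose is kept; otherwise records
#' are merged by a confidence-weighted geometric mean.
#'
#' @param target_efficacy per-insect kill probability, in (0, 1).
#' @param retention_confidence confidence threshold in (0, 1) above which the
#'   lowest qualifying dose is retained outright.
#' @return a list of class `"efficacy_policy"`.
#' @export
efficacy_policy <- function(target_efficacy = 0.9999,
                            retention_confidence = 0.9999) {
  for (v in c(target_efficacy, retention_confidence)) {
    if (!is.finite(v) || v <= 0 || v >= 1) {
      stop("policy probabilities must lie strictly between 0 and 1",
        call. = FALSE)
    }
  }
  structure(list(target_efficacy = target_efficacy,
    retention_confidence = retention_confidence), class = "efficacy_policy")
}

#' Combine multiple reported doses for one species into a single SSD input
#'
#' Given every literature record for a single species, returns the one dose
#' that enters the SSD fit. If any record's confidence exceeds the policy's
#' retention threshold, the lowest such dose is returned (those doses are
#' individually proven; the lowest is the least conservative of them).
#' Otherwise the records are merged by the geometric mean of the reported
#' doses weighted by their efficacy confidences:
#' \deqn{\exp\!\left(\sum_i C_i \log D_i \Big/ \sum_i C_i\right).}
#'
#' Records with missing `n_treated` carry no confidence and are excluded
#' from the weighted combination (with a warning) unless every record lacks
#' `n`, in which case the unweighted geometric mean is used as a fallback.
#'
#' @param records data frame with columns `species`, `dose_gy` and
#'   (optionally) `n_treated`, all rows belonging to the same species.
#' @param policy an [efficacy_policy()].
#' @return one-row data frame with columns `species`, `dose_gy`,
#'   `confidence` (of the returned dose, i.e. max over used records) and
#'   `n_records`.
#' @examples
#' recs <- data.frame(species = "Hypothenemus hampei",
#'                    dose_gy = c(100, 75), n_treated = c(6598, 138))
#' combine_species_doses(recs)  # ~99.15 Gy
#' @export
combine_species_doses <- function(records, policy = efficacy_policy()) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  sp <- unique(trimws(as.character(records$species)))
  if (length(sp) != 1L) {
    stop("all records must belong to one species; got: ",
      paste(sp, collapse = ", "), call. = FALSE)
  }
  d <- records$dose_gy
  if (any(!is.finite(d) | d <= 0)) stop("doses must be positive", call. = FALSE)
  n <- if ("n_treated" %in% names(records)) records$n_treated else rep(NA_real_, nrow(records))
  conf <- ifelse(is.na(n), NA_real_,
    confidence_of_efficacy(ifelse(is.na(n), 0, n), policy$target_efficacy))

  out <- function(dose, confidence) {
    data.frame(species = sp, dose_gy = dose, confidence = confidence,
      n_records = nrow(records), stringsAsFactors = FALSE)
  }
  if (nrow(records) == 1L) return(out(d, conf))

  proven <- !is.na(conf) & conf > policy$retention_confidence
  if (any(proven)) {
    i <- which(proven)[which.min(d[proven])]
    return(out(d[i], conf[i]))
  }
  usable <- !is.na(conf) & conf > 0
  if (any(is.na(conf)) && any(usable)) {
    warning("dropping ", sum(is.na(conf)), " record(s) with missing n for ",
      sp, " from the weighted combination", call. = FALSE)
  }
  if (!any(usable)) {
    warning("no usable confidence weights for ", sp,
      "; falling back to the unweighted geometric mean", call. = FALSE)
    return(out(exp(mean(log(d))), NA_real_))
  }
  w <- conf[usable]
  dose <- exp(sum(w * log(d[usable])) / sum(w))
  out(dose, max(w))
}

#' Combine a whole dose table species by species
#'
#' Applies [combine_species_doses()] to every species in a record table and
#' returns the per-species doses that form the SSD input. Species matching is
#' exact string match after whitespace normalization.
#'
#' @param records data frame of dose records (see [read_dose_table()]).
#' @param policy an [efficacy_policy()].
#' @return data frame with one row per species: `species`, `dose_gy`,
#'   `confidence`, `n_records`, ordered as first encountered.
#' @export
combine_dose_table <- function(records, policy = efficacy_policy()) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  sp <- trimws(as.character(records$species))
  pieces <- lapply(unique(sp), function(s) {
    combine_species_doses(records[sp == s, , drop = FALSE], policy)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

## Column schema shared by the reader and writer.
.dose_cols <- c("species", "family", "dose_gy", "n_treated",
  "highest_fail_dose_gy", "source")

#' Read a literature dose table from CSV
#'
#' Expected columns (extra columns are preserved): `species`, `dose_gy`, and
#' optionally `family`, `n_treated` (specimens treated at the reported dose),
#' `highest_fail_dose_gy` (highest tested dose with at least one survivor)
#' and `source`. Empty cells, `-` and `NA` denote missing values; missing
#' `n_treated` stays missing, never 0. Column names can be remapped via
#' `col_map`, e.g. `c(dose_gy = "Dose")` when the file calls the dose column
#' `Dose`.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @return data frame of dose records with canonical column names.
#' @export
read_dose_table <- function(path, col_map = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
    na.strings = c("", "-", "–", "NA"))
  if (nrow(raw) == 0L) stop("dose table is empty: ", path, call. = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(raw))
      if (is.na(j)) {
        stop("mapped column not found in file: ", col_map[[canon]],
          call. = FALSE)
      }
      names(raw)[j] <- canon
    }
  }
  for (required in c("species", "dose_gy")) {
    if (!required %in% names(raw)) {
      stop("required column missing: ", required, call. = FALSE)
    }
  }
  for (col in intersect(c("dose_gy", "n_treated", "highest_fail_dose_gy"), names(raw))) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "', row ", bad[1],
        ": '", vals[bad[1]], "'", call. = FALSE)
    }
    raw[[col]] <- num
  }
  bad <- which(is.na(raw$dose_gy) | raw$dose_gy <= 0)
  if (length(bad)) {
    stop("dose_gy must be positive: row ", bad[1], call. = FALSE)
  }
  if ("highest_fail_dose_gy" %in% names(raw)) {
    bad <- which(!is.na(raw$highest_fail_dose_gy) &
      raw$highest_fail_dose_gy >= raw$dose_gy)
    if (length(bad)) {
      stop("highest_fail_dose_gy must be below dose_gy: row ", bad[1],
        call. = FALSE)
    }
  }
  raw$species <- trimws(raw$species)
  raw
}

#' Write dose records to CSV
#'
#' Inverse of [read_dose_table()]: missing values are written as empty cells
#' so a round trip reproduces the records.
#'
#' @param records data frame of dose records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

## Packaged fixture helper.
#' Packaged literature dose tables
#'
#' Convenience loader for the two transcribed literature review tables that
#' ship with the package: `"curculionidae"` (31 records, 28 species of
#' weevils and bark beetles; endpoint: failure of F1 development) and
#' `"tephritidae"` (15 combined per-species sterilizing doses for fruit
#' flies; endpoint: prevention of normal adult emergence).
#'
#' @param taxon `"curculionidae"` or `"tephritidae"`.
#' @return data frame of dose records.
#' @export
example_dose_table <- function(taxon = c("curculionidae", "tephritidae")) {
  taxon <- match.arg(taxon)
  file <- switch(taxon,
    curculionidae = "curculionidae_table1.csv",
    tephritidae = "tephritidae_table3.csv")
  read_dose_table(system.file("extdata", file, package = "phytoSSD",
    mustWork = TRUE))
}
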