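#' RatioChann: resected fraction statistic for marked channels
#'
#' `RatioChann(ev) = (#ChannRem - #ChannNonRem) / (#ChannRem + #ChannNonRem)`
#' for channels marked by a modality `ev`: +1 means every marked channel was
#' resected, -1 that none was.
#'
#' @param n_removed marked channels removed at surgery.
#' @param n_nonremoved marked channels not removed.
#' @param modality optional modality label carried in the result.
#' @return list `modality`, `n_removed`, `n_nonremoved`, `value` in `[-1, 1]`.
#' @export
ratio_chann <- function(n_removed, n_nonremoved, modality = NA_character_) {
  if (n_removed < 0 || n_nonremoved < 0)
    stop_hfoloc("hfoloc_invalid_argument", "counts must be non-negative")
  if (n_removed + n_nonremoved == 0)
    stop_hfoloc("hfoloc_undefined_ratio",
                "RatioChann undefined: no marked channels")
  list(modality = modality, n_removed = n_removed, n_nonremoved = n_nonremoved,
       value = (n_removed - n_nonremoved) / (n_removed + n_nonremoved))
}

#' Classify an Engel outcome class as good or poor
#'
#' Class I (seizure-free) is a good postsurgical outcome; classes II and III
#' (recurrent seizures) are poor.
#'
#' @param engel character vector of Engel classes (`"I"`, `"II"`, `"III"`).
#' @return Character vector of `"good"` / `"poor"`.
#' @export
classify_outcome <- function(engel) {
  engel <- trimws(as.character(engel))
  bad <- setdiff(unique(engel), c("I", "II", "III"))
  if (length(bad) > 0)
    stop_hfoloc("hfoloc_invalid_argument",
                "unknown Engel class: %s", paste(bad, collapse = ", "))
  ifelse(engel == "I", "good", "poor")
}

#' Two-sided Fisher's exact test (probability method)
#'
#' Exact p-value for a 2x2 table by enumeration of all tables with the
#' observed margins: the sum of hypergeometric probabilities not exceeding
#' that of the observed table.
#'
#' @param table 2x2 non-negative integer matrix (rows: condition yes/no;
#'   columns: seizure-free / not).
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_hfoloc("hfoloc_invalid_argument", "table must hold non-negative integers")
  if (sum(table) == 0)
    stop_hfoloc("hfoloc_invalid_argument", "table total must be positive")
  m <- sum(table[1, ]); nn <- sum(table[2, ]); k <- sum(table[, 1])
  x <- max(0, k - nn):min(m, k)
  pr <- stats::dhyper(x, m, nn, k)
  p_obs <- stats::dhyper(table[1, 1], m, nn, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided rank-sum p via dynamic programming over doubled midranks:
# distribution of the sum of n_a ranks chosen from the pooled multiset.
rank_sum_exact <- function(r2, n_a, w_obs2) {
  N <- length(r2)
  total <- sum(r2)
  # dp[[k]][s+1] = number of k-subsets with doubled-rank sum s
  dp <- vector("list", n_a + 1)
  dp[[1]] <- c(1, numeric(total))
  for (k in seq_len(n_a)) dp[[k + 1]] <- numeric(total + 1)
  for (item in r2) {
    for (k in rev(seq_len(n_a))) {
      shifted <- c(numeric(item), dp[[k]][seq_len(total + 1 - item)])
      dp[[k + 1]] <- dp[[k + 1]] + shifted
    }
  }
  counts <- dp[[n_a + 1]]
  n_tot <- sum(counts)
  s <- 0:total
  p_le <- sum(counts[s <= w_obs2 + 1e-9]) / n_tot
  p_ge <- sum(counts[s >= w_obs2 - 1e-9]) / n_tot
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation distribution (midranks for ties) when
#' `length(a) + length(b) <= exact_limit`; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_limit pooled-size threshold for the exact path.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 20) {
  if (length(a) == 0 || length(b) == 0)
    stop_hfoloc("hfoloc_invalid_argument", "both groups must be non-empty")
  pooled <- c(a, b)
  N <- length(pooled)
  r <- rank(pooled)                      # midranks
  w <- sum(r[seq_along(a)])
  if (N <= exact_limit) {
    r2 <- as.integer(round(2 * r))       # doubled midranks are integers
    return(rank_sum_exact(r2, length(a), round(2 * w)))
  }
  n_a <- length(a); n_b <- length(b)
  mu <- n_a * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- w - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)   # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Region-set parsing ---------------------------------------------------------

#' Parse a printed region-label field into a set
#'
#' `"/"` means the modality is missing (`NULL`); `"Normal"` means examined
#' with no abnormality (empty set). Labels are comma-split, trimmed,
#' uppercased, and parenthetical annotations like `"(#)"` or `"(*)"` are
#' stripped.
#'
#' @param s character scalar as printed in a cohort table.
#' @return Character vector of labels, `character(0)` for "Normal", or
#'   `NULL` for missing.
#' @export
parse_region_set <- function(s) {
  if (is.na(s)) return(NULL)
  s <- trimws(s)
  if (s == "/" || s == "") return(NULL)
  if (toupper(s) == "NORMAL") return(character(0))
  labs <- strsplit(s, ",", fixed = TRUE)[[1]]
  labs <- gsub("\\(.*?\\)", "", labs)
  labs <- toupper(gsub("[[:space:]]", "", labs))
  unique(labs[nzchar(labs)])
}

#' Read a cohort table from CSV
#'
#' Expects the standard columns (`Patient`, `PET-MRI`, `FLAWS`, `HFOs`,
#' `Overlapped`, `Removing`, `Outcome`, ...). Region columns are parsed into
#' list columns of label sets (`pet_set`, `flaws_set`, `hfo_set`,
#' `overlap_set`, `removed_set`).
#'
#' @param path CSV path.
#' @return data.frame with added list columns.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("PET-MRI", "FLAWS", "HFOs", "Removing", "Outcome")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_hfoloc("hfoloc_format_error", "cohort table missing columns: %s",
                paste(miss, collapse = ", "))
  df$pet_set <- lapply(df[["PET-MRI"]], parse_region_set)
  df$flaws_set <- lapply(df[["FLAWS"]], parse_region_set)
  df$hfo_set <- lapply(df[["HFOs"]], parse_region_set)
  if ("Overlapped" %in% names(df))
    df$overlap_set <- lapply(df[["Overlapped"]], parse_region_set)
  df$removed_set <- lapply(df[["Removing"]], parse_region_set)
  df
}

#' Packaged 15-patient cohort fixture
#' @return Parsed cohort data.frame (see [read_cohort_csv()]).
#' @export
table1_cohort <- function() {
  read_cohort_csv(system.file("extdata", "table1_patients.csv",
                              package = "hfoloc", mustWork = TRUE))
}

#' Packaged outcome-association contingency panels
#'
#' The published 2x2 counts relating complete removal of marked areas (per
#' modality, and multimodally) to seizure freedom.
#'
#' @return Named list of 2x2 matrices (rows yes/no, columns
#'   seizure-free / non-seizure-free).
#' @export
table2_panels <- function() {
  df <- utils::read.csv(system.file("extdata", "table2_outcome.csv",
                                    package = "hfoloc", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  out <- list()
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, ]
    m <- matrix(c(sub$seizure_free[sub$answer == "yes"],
                  sub$non_seizure_free[sub$answer == "yes"],
                  sub$seizure_free[sub$answer == "no"],
                  sub$non_seizure_free[sub$answer == "no"]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("yes", "no"),
                                c("seizure_free", "non_seizure_free")))
    out[[cond]] <- m
  }
  out
}

modality_column <- function(modality) {
  switch(modality,
         "PET-MRI" = "pet_set", "FLAWS" = "flaws_set", "HFOs" = "hfo_set",
         stop_hfoloc("hfoloc_invalid_argument", "unknown modality %s", modality))
}

#' Cross-modality consistency of marked regions
#'
#' For each patient with both modalities available (`"/"` rows excluded;
#' `"Normal"` counts as an empty, evaluable set), checks whether the two
#' label sets share at least one region (exact string match) and whether
#' they are identical.
#'
#' @param cohort parsed cohort (see [read_cohort_csv()]).
#' @param modality_a,modality_b two of `"PET-MRI"`, `"FLAWS"`, `"HFOs"`.
#' @return list `n_evaluable`, `n_at_least_one`, `pct_at_least_one`,
#'   `n_complete`, `pct_complete`.
#' @export
consistency <- function(cohort, modality_a, modality_b) {
  sa <- cohort[[modality_column(modality_a)]]
  sb <- cohort[[modality_column(modality_b)]]
  if (all(vapply(sa, is.null, TRUE)) || all(vapply(sb, is.null, TRUE)))
    stop_hfoloc("hfoloc_invalid_argument",
                "modality absent from every row")
  eval_rows <- !vapply(sa, is.null, TRUE) & !vapply(sb, is.null, TRUE)
  n_eval <- sum(eval_rows)
  at_least <- mapply(function(x, y) length(intersect(x, y)) > 0,
                     sa[eval_rows], sb[eval_rows])
  complete <- mapply(function(x, y) setequal(x, y) && length(x) > 0 ||
                       (length(x) == 0 && length(y) == 0),
                     sa[eval_rows], sb[eval_rows])
  list(n_evaluable = n_eval,
       n_at_least_one = sum(at_least),
       pct_at_least_one = 100 * sum(at_least) / n_eval,
       n_complete = sum(complete),
       pct_complete = 100 * sum(complete) / n_eval)
}

#' Region-level confusion counts for one modality
#'
#' Outcome-anchored bookkeeping: for good-outcome (Engel I) patients, every
#' marked-and-removed region is a true positive, every marked-but-retained
#' region a false positive, and the unmarked remainder contributes one true
#' negative per patient. For poor-outcome patients, marked-and-removed
#' regions are true positives and the residual epileptogenic tissue
#' contributes one false negative per patient; poor-outcome patients with
#' non-removed marked regions are excluded entirely (their retained marks
#' cannot be classified). Region-unit granularity is a convention; see the
#' methods vignette.
#'
#' @param cohort parsed cohort.
#' @param modality one of `"PET-MRI"`, `"FLAWS"`, `"HFOs"`.
#' @return list `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `excluded` (patient ids).
#' @export
confusion_counts <- function(cohort, modality) {
  sets <- cohort[[modality_column(modality)]]
  tp <- fp <- tn <- fn <- 0L
  excluded <- c()
  for (i in seq_len(nrow(cohort))) {
    marked <- sets[[i]]
    removed <- cohort$removed_set[[i]]
    if (is.null(marked)) next                   # modality missing for patient
    if (is.null(removed)) { excluded <- c(excluded, cohort$Patient[i]); next }
    good <- classify_outcome(cohort$Outcome[i]) == "good"
    n_rem <- length(intersect(marked, removed))
    n_nonrem <- length(setdiff(marked, removed))
    if (good) {
      tp <- tp + n_rem
      fp <- fp + n_nonrem
      tn <- tn + 1L
    } else {
      if (n_nonrem > 0) { excluded <- c(excluded, cohort$Patient[i]); next }
      tp <- tp + n_rem
      fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       excluded = excluded)
}

#' Multimodal condition flag
#'
#' True iff the intracranial electrodes covered all suspicious areas
#' indicated by neuroimaging AND the HFO-marked areas were completely
#' removed.
#'
#' @param electrodes_cover_all_imaging,hfo_completely_removed logical flags.
#' @return Logical.
#' @export
multimodal_flag <- function(electrodes_cover_all_imaging,
                            hfo_completely_removed) {
  if (anyNA(electrodes_cover_all_imaging) || anyNA(hfo_completely_removed))
    stop_hfoloc("hfoloc_invalid_argument", "missing component flag")
  electrodes_cover_all_imaging & hfo_completely_removed
}

condition_flag <- function(cohort, condition) {
  subset_removed <- function(set_col) {
    mapply(function(m, r) {
      if (is.null(m) || is.null(r)) NA
      else length(setdiff(m, r)) == 0 && length(m) > 0
    }, cohort[[set_col]], cohort$removed_set)
  }
  switch(condition,
    pet_complete = subset_removed("pet_set"),
    flaws_complete = subset_removed("flaws_set"),
    hfo_complete = {
      if ("hfo_completely_removed" %in% names(cohort))
        cohort$hfo_completely_removed
      else subset_removed("hfo_set")
    },
    multimodal = multimodal_flag(cohort$electrodes_cover_all_imaging,
                                 cohort$hfo_completely_removed),
    stop_hfoloc("hfoloc_invalid_argument", "unknown condition %s", condition))
}

#' Association between a completeness condition and seizure freedom
#'
#' Builds the 2x2 table (condition yes/no by seizure-free/not) over the
#' evaluable rows and returns the exact two-sided Fisher p-value. Rows where
#' the condition cannot be computed are dropped.
#'
#' @param cohort parsed cohort.
#' @param condition `"pet_complete"`, `"flaws_complete"`, `"hfo_complete"`,
#'   or `"multimodal"`.
#' @return list `table` (2x2 matrix), `p`, `n_dropped`.
#' @export
outcome_association <- function(cohort,
                                condition = c("hfo_complete", "pet_complete",
                                              "flaws_complete", "multimodal")) {
  condition <- match.arg(condition)
  flag <- condition_flag(cohort, condition)
  keep <- !is.na(flag)
  if (!any(keep))
    stop_hfoloc("hfoloc_invalid_argument", "condition computable for no row")
  sf <- classify_outcome(cohort$Outcome[keep]) == "good"
  fl <- flag[keep]
  tab <- matrix(c(sum(fl & sf), sum(fl & !sf),
                  sum(!fl & sf), sum(!fl & !sf)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("yes", "no"),
                                c("seizure_free", "non_seizure_free")))
  list(table = tab, p = fisher_exact_two_sided(tab), n_dropped = sum(!keep))
}
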