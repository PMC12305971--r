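#' Build stride pairs from a cohort
#'
#' A stride pair couples an ipsilateral (affected-side) stride with the
#' contralateral stride that starts within it: for each ipsilateral stride,
#' the earliest not-yet-used contralateral stride whose foot strike falls
#' inside the ipsilateral stride interval is paired with it; contralateral
#' strides are never reused. Patients without any valid pair are dropped
#' with a warning.
#'
#' @param cohort an `sms_cohort`.
#' @return tibble with columns `patient_id`, `pair` (index within
#'   patient), `ipsi_stride`, `contra_stride`.
#' @export
build_stride_pairs <- function(cohort) {
  ev <- cohort$events
  out <- list()
  dropped <- character()
  for (pid in unique(ev$patient_id)) {
    ei <- ev[ev$patient_id == pid & ev$side == "ipsi", ]
    ec <- ev[ev$patient_id == pid & ev$side == "contra", ]
    ei <- ei[order(ei$foot_strike_s), ]
    ec <- ec[order(ec$foot_strike_s), ]
    used <- logical(nrow(ec))
    pairs <- list()
    for (j in seq_len(nrow(ei))) {
      ok <- which(!used &
                    ec$foot_strike_s >= ei$foot_strike_s[j] &
                    ec$foot_strike_s < ei$next_foot_strike_s[j])
      if (length(ok)) {
        used[ok[1]] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(ei$stride[j], ec$stride[ok[1]])
      }
    }
    if (!length(pairs)) {
      dropped <- c(dropped, pid)
      next
    }
    m <- do.call(rbind, pairs)
    out[[pid]] <- tibble::tibble(
      patient_id = pid, pair = seq_len(nrow(m)),
      ipsi_stride = m[, 1], contra_stride = m[, 2]
    )
  }
  if (length(dropped))
    warning("patient(s) without a valid stride pair dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  dplyr::bind_rows(out)
}

#' Stratified patient-grouped train/test split
#'
#' Partitions patients (never individual stride pairs) into training and
#' test sets, stratified by the total SMS: within each SMS stratum the test
#' share is as close to `test_fraction` as integer counts allow
#' (largest-remainder allocation across strata); strata holding a single
#' patient go to training. Deterministic under a fixed seed.
#'
#' @param features a feature table (or any data frame) with columns
#'   `patient_id` and `sms`.
#' @param test_fraction target test share of patients (default 0.30).
#' @param seed integer seed for the within-stratum draw.
#' @return tibble `patient_id`, `split` (`"train"` or `"test"`).
#' @export
stratified_patient_split <- function(features, test_fraction = 0.30,
                                     seed = 1L) {
  pts <- dplyr::distinct(features, .data$patient_id, .data$sms)
  if (!nrow(pts)) stop("empty dataset", call. = FALSE)
  withr_seed(seed, {
    strata <- split(pts$patient_id, pts$sms)
    sizes <- lengths(strata)
    eligible <- sizes >= 2L
    quota <- ifelse(eligible, test_fraction * sizes, 0)
    base <- floor(quota)
    total <- round(sum(quota))
    extra <- total - sum(base)
    rem <- quota - base
    # largest remainders first; ties broken toward larger strata
    ord <- order(-rem, -sizes)
    take <- base
    if (extra > 0) {
      give <- ord[rem[ord] > 0 & take[ord] < sizes[ord]]
      give <- give[seq_len(min(extra, length(give)))]
      take[give] <- take[give] + 1L
    }
    take <- pmin(take, ifelse(eligible, sizes, 0L))
    test_ids <- unlist(lapply(seq_along(strata), function(i) {
      if (take[i] == 0L) return(character())
      ids <- strata[[i]]
      ids[sample.int(length(ids), take[i])]
    }))
    tibble::tibble(
      patient_id = pts$patient_id,
      split = ifelse(pts$patient_id %in% test_ids, "test", "train")
    )
  })
}

#' Bias-correcting stride-pair weights
#'
#' Weighs each training stride pair against two biases: the imbalanced
#' distribution of subscore labels and the unequal number of stride pairs
#' per patient. The weight of pair i is the ratio of the greatest number
#' of pairs sharing any one label to the number of pairs sharing pair i's
#' label, divided by the number of pairs from pair i's patient:
#' `w_i = (max_s N_s / N_s(i)) / M_p(i)`.
#'
#' @param data data frame of training pairs with a `patient_id` column and
#'   the label column named by `target`.
#' @param target label column name (a subscore or `"sms"`).
#' @return numeric weight vector, one per row of `data`, all positive.
#' @export
compute_weights <- function(data, target) {
  lab <- data[[target]]
  if (is.null(lab)) stop("no label column `", target, "`", call. = FALSE)
  n_s <- table(lab)
  m_p <- table(data$patient_id)
  as.numeric(max(n_s) / n_s[as.character(lab)]) /
    as.numeric(m_p[data$patient_id])
}

#' Assemble the weighted, split dataset
#'
#' Adds the stratified patient-grouped split flag and, for every target
#' (six subscores plus the SMS), the per-pair training weights (test pairs
#' carry `NA` weights; they are never used for fitting).
#'
#' @param features feature table from [extract_features()].
#' @inheritParams stratified_patient_split
#' @return the feature table with columns `split` and `weight_<target>`.
#' @export
assemble_dataset <- function(features, test_fraction = 0.30, seed = 1L) {
  split <- stratified_patient_split(features, test_fraction, seed)
  out <- dplyr::left_join(features, split, by = "patient_id")
  train <- out$split == "train"
  for (target in c(sms_subscores(), "sms")) {
    w <- rep(NA_real_, nrow(out))
    w[train] <- compute_weights(out[train, ], target)
    out[[paste0("weight_", target)]] <- w
  }
  out
}
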