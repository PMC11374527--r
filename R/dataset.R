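# Event-record dataset I/O and exclusion accounting (NONMEM dialect).

DATASET_COLS <- c("ID", "TIME", "DAY", "AMT", "RATE", "EVID", "MDV", "DV",
                  "BLQ", "OCC", COV_COLS, "SEX", "RACE", "STUDY")

validate_dataset <- function(data) {
  miss <- setdiff(setdiff(DATASET_COLS, c("DAY", "RACE")), names(data))
  if (length(miss))
    stop("dataset is missing required columns: ", paste(miss, collapse = ", "))
  bad <- which(!data$EVID %in% c(0L, 1L))
  if (length(bad))
    stop("invalid EVID value (must be 0 or 1) in rows: ",
         paste(head(bad, 5), collapse = ", "))
  dose <- data$EVID == 1
  bad <- which(dose & (is.na(data$AMT) | data$AMT <= 0))
  if (length(bad))
    stop("dose rows must have AMT > 0; offending rows: ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(dose & !is.na(data$DV))
  if (length(bad))
    stop("dose rows must not carry DV; offending rows: ",
         paste(head(bad, 5), collapse = ", "))
  for (id in unique(data$ID)) {
    tt <- data$TIME[data$ID == id]
    if (is.unsorted(tt))
      stop("TIME is not non-decreasing within subject ", id)
  }
  obs <- data$EVID == 0
  for (cc in COV_COLS) {
    bad <- which(is.na(data[[cc]]))
    if (length(bad))
      stop("covariate column ", cc, " has missing values in rows: ",
           paste(head(bad, 5), collapse = ", "))
  }
  invisible(data)
}

#' Read and write event-record PK datasets
#'
#' CSV round-trip of the NONMEM-dialect rectangular table produced by
#' [simulate_trial()] (columns `ID`, `TIME`, `AMT`, `RATE`, `EVID`, `MDV`,
#' `DV`, `BLQ`, `OCC`, covariates, `SEX`, `RACE`, `STUDY`). Reading
#' validates the table (required columns, EVID codes, dose-row consistency,
#' monotone TIME within subject, complete covariates) and reports offending
#' row numbers.
#'
#' @param path File path of the CSV dataset.
#' @param data Dataset to write.
#' @param lloq Lower limit of quantification attached to the read dataset.
#' @return `read_pk_dataset()` returns the validated `data.frame` (class
#'   `"pk_trial"`); `write_pk_dataset()` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path, lloq = 0.2) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(data)
  attr(data, "lloq") <- lloq
  class(data) <- c("pk_trial", "data.frame")
  data
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(data, path) {
  validate_dataset(data)
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude unquantifiable observations before fitting
#'
#' Removes below-LLOQ observation rows from the fitting set (the M1 method:
#' BLQ records are dropped, not modelled), together with negative
#' concentrations, and optionally flags spuriously high values (observations
#' exceeding `peak_multiple` times the subject's maximum population-predicted
#' concentration, which requires a `PRED` column). Excluded rows are retained
#' in an exclusion log with reason codes.
#'
#' @param data Event-record dataset.
#' @param lloq Lower limit of quantification (ug/mL).
#' @param peak_multiple If the dataset has a `PRED` column, observations with
#'   `DV > peak_multiple * max(PRED)` within subject are excluded as
#'   spuriously high; `NULL` disables the rule.
#' @return A list with `retained` (dataset without excluded observation
#'   rows), `log` (data frame `row`, `ID`, `TIME`, `DV`, `reason`),
#'   `n_obs` (observation rows before exclusion), `n_retained`,
#'   `blq_fraction`.
#' @examples
#' pop <- generate_population(population_spec(n_1015 = 1, n_3035 = 2), seed = 1)
#' trial <- simulate_trial(pop, pk_params(), seed = 2)
#' apply_exclusions(trial)$blq_fraction
#' @export
apply_exclusions <- function(data, lloq = 0.2, peak_multiple = NULL) {
  obs <- which(data$EVID == 0)
  if (!length(obs)) stop("dataset has no observation rows")
  if (any(is.na(data$DV[obs])))
    stop("observation rows must carry DV")
  dv <- data$DV[obs]
  reason <- rep(NA_character_, length(obs))
  reason[dv < lloq] <- "BLQ"
  reason[dv < 0] <- "negative_DV"
  if (!is.null(peak_multiple) && "PRED" %in% names(data)) {
    for (id in unique(data$ID)) {
      sel <- data$ID[obs] == id
      peak <- max(data$PRED[obs][sel], na.rm = TRUE)
      hi <- sel & dv > peak_multiple * peak & is.na(reason)
      reason[hi] <- "spurious_high"
    }
  }
  drop <- obs[!is.na(reason)]
  log <- data.frame(row = drop,
                    ID = data$ID[drop], TIME = data$TIME[drop],
                    DV = data$DV[drop], reason = reason[!is.na(reason)])
  retained <- if (length(drop)) data[-drop, , drop = FALSE] else data
  n_blq <- sum(log$reason == "BLQ")
  if (sum(retained$EVID == 0) == 0)
    stop("all observations excluded; nothing left to fit")
  for (a in c("lloq", "seed")) attr(retained, a) <- attr(data, a)
  class(retained) <- class(data)
  list(retained = retained, log = log,
       n_obs = length(obs), n_retained = sum(retained$EVID == 0),
       blq_fraction = n_blq / length(obs))
}
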