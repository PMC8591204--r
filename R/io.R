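#' Read a longitudinal PK dataset (NONMEM-style CSV)
#'
#' Expected columns: `ID`, `TIME` (h), `AMT` (mg), `RATE` (mg/h), `EVID`,
#' `MDV`, `DV` (mg/L), `CRCL` (ml/min), `LPM` (L/min), `BLQ`; dose rows have
#' `EVID = 1` and empty `DV`, observation rows `EVID = 0`. Additional
#' columns (e.g. extra covariates) are preserved. Validation failures report
#' the offending row and column.
#'
#' @param path Path to a CSV file.
#' @return A `pk_dataset` data.frame.
#' @export
read_pk_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ID", "TIME", "AMT", "RATE", "EVID", "MDV", "DV", "CRCL", "LPM", "BLQ")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("dataset is missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0 || length(unique(df$ID)) == 0) stop("dataset contains no subjects")
  validate_pk_dataset(df)
  if (!"trunc" %in% names(df)) df$trunc <- FALSE
  n_obs <- sum(df$EVID == 0)
  message(sprintf("Loaded %d subjects, %d observation rows, %d dosing rows",
                  length(unique(df$ID)), n_obs, sum(df$EVID == 1)))
  structure(df, class = c("pk_dataset", "data.frame"))
}

validate_pk_dataset <- function(df) {
  bad <- which(!is.finite(df$TIME) | df$TIME < 0)
  if (length(bad)) stop(sprintf("row %d: negative or missing TIME", bad[1]))
  for (id in unique(df$ID)) {
    tt <- df$TIME[df$ID == id]
    if (is.unsorted(tt)) stop(sprintf("subject %s: TIME not sorted", id))
    first_dose <- df$TIME[df$ID == id & df$EVID == 1]
    if (length(first_dose) == 0) {
      warning(sprintf("subject %s: no dosing record", id))
    } else if (any(tt < min(first_dose) & tt > 0)) {
      warning(sprintf("subject %s: observation before first dose", id))
    }
  }
  obs <- df$EVID == 0 & df$MDV == 0
  bad <- which(obs & !is.finite(df$DV))
  if (length(bad)) stop(sprintf("row %d: observation row (EVID=0, MDV=0) without DV", bad[1]))
  dose <- df$EVID == 1
  with_rate <- dose & is.finite(df$RATE) & df$RATE > 0
  if (any(dose & (!is.finite(df$AMT) | df$AMT <= 0))) {
    stop(sprintf("row %d: dosing row with non-positive AMT", which(dose & (!is.finite(df$AMT) | df$AMT <= 0))[1]))
  }
  invisible(TRUE)
}

#' @rdname read_pk_dataset
#' @param data A `pk_dataset` (or compatible data.frame).
#' @export
write_pk_dataset <- function(data, path) {
  keep <- setdiff(names(data), "trunc")
  utils::write.csv(as.data.frame(data)[keep], path, row.names = FALSE, na = "")
  invisible(path)
}

# Internal: split a pk_dataset into the flat arrays the C++ likelihood wants.
# Covariate matrix columns are taken from `cov_cols` (per-subject constants).
dataset_arrays <- function(data, cov_cols = c("CRCL", "LPM"), drop_blq = FALSE) {
  df <- as.data.frame(data)
  ids <- unique(df$ID)
  idx <- match(df$ID, ids) - 1L
  obs <- df$EVID == 0 & df$MDV != 1
  if (drop_blq && "BLQ" %in% names(df)) obs <- obs & df$BLQ != 1
  dose <- df$EVID == 1
  X <- matrix(0, nrow = length(ids), ncol = length(cov_cols),
              dimnames = list(NULL, cov_cols))
  for (j in seq_along(cov_cols)) {
    cc <- cov_cols[j]
    if (!cc %in% names(df)) stop("covariate column not in dataset: ", cc)
    X[, j] <- df[[cc]][match(ids, df$ID)]
  }
  dur <- ifelse(df$RATE[dose] > 0, df$AMT[dose] / df$RATE[dose], 1e-6)
  list(ids = ids, n = length(ids),
       obs_subj = idx[obs], obs_t = df$TIME[obs], obs_y = df$DV[obs],
       dose_subj = idx[dose], dose_t = df$TIME[dose],
       dose_amt = df$AMT[dose], dose_dur = dur, X = X)
}
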