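#' Validate and classify a NONMEM-layout event table
#'
#' Required columns: `ID`, `TIME` (h since the subject's first dose), `EVID`
#' (1 = dose, 0 = observation), `AMT` (mg, dose rows), `DV` (ng/ml,
#' observation rows), `MDV` (1 = DV missing), `WT` (kg, constant per
#' subject). Any further columns are carried along as covariates. Validation
#' errors cite the offending row.
#'
#' @param df a data.frame in event layout.
#' @return the same data, with class `pk_dataset`.
#' @export
as_pk_dataset <- function(df) {
  required <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV", "WT")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!df$EVID %in% c(0L, 1L))
  if (length(bad)) stop("row ", bad[1], ": unknown EVID value ", df$EVID[bad[1]])
  bad <- which(df$TIME < 0 | !is.finite(df$TIME))
  if (length(bad)) stop("row ", bad[1], ": invalid TIME")
  for (id in unique(df$ID)) {
    idx <- which(df$ID == id)
    t <- df$TIME[idx]
    if (is.unsorted(t)) {
      r <- idx[which(diff(t) < 0)[1] + 1L]
      stop("row ", r, ": TIME decreases within subject ", id)
    }
    if (length(unique(df$WT[idx])) != 1L)
      stop("row ", idx[1], ": WT not constant within subject ", id)
    if (any(df$WT[idx] <= 0))
      stop("row ", idx[1], ": non-positive WT for subject ", id)
  }
  dose <- df$EVID == 1L
  bad <- which(dose & (is.na(df$AMT) | df$AMT <= 0))
  if (length(bad)) stop("row ", bad[1], ": dose record needs AMT > 0")
  bad <- which(dose & !is.na(df$DV))
  if (length(bad)) stop("row ", bad[1], ": dose record must not carry a DV")
  obs <- df$EVID == 0L
  bad <- which(obs & df$MDV == 0L & is.na(df$DV))
  if (length(bad)) stop("row ", bad[1], ": observation with MDV=0 lacks DV")
  bad <- which(obs & !is.na(df$DV) & df$DV < 0)
  if (length(bad)) stop("row ", bad[1], ": negative DV")
  class(df) <- unique(c("pk_dataset", class(df)))
  df
}

#' Read a dataset from CSV
#'
#' Comma-separated with a mandatory header row. `"."` is the NONMEM-style
#' missing marker: a `"."` in `DV` is mapped to `NA` with `MDV` forced to 1;
#' `"."` in any other numeric column reads as `NA`.
#'
#' @param path file path.
#' @return a validated `pk_dataset`.
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, na.strings = c(".", "NA", ""), stringsAsFactors = FALSE)
  if (!"MDV" %in% names(df) && "DV" %in% names(df))
    df$MDV <- ifelse(is.na(df$DV), 1L, 0L)
  if (all(c("DV", "MDV") %in% names(df)))
    df$MDV[is.na(df$DV) & df$EVID == 0L] <- 1L
  df <- as_pk_dataset(df)
  message(sprintf("read %d rows, %d subjects, %d observations from %s",
                  nrow(df), length(unique(df$ID)),
                  sum(df$EVID == 0L & df$MDV == 0L), path))
  df
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]: missing values are written as `"."`.
#' Datasets produced by [simulate_cohort()] round-trip bit-identically
#' (their numeric columns are rounded at generation).
#'
#' @param dataset a `pk_dataset`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pk_dataset"))
  write.csv(as.data.frame(dataset), path, row.names = FALSE, na = ".",
            quote = FALSE)
  invisible(path)
}

#' Summarize a dataset in the shape of a demographics table
#'
#' @param object a `pk_dataset`.
#' @param ... unused.
#' @return list of class `pk_dataset_summary`: subject and observation
#'   counts, mean observations per subject (1 decimal), weight median/range,
#'   and per-covariate summaries (mean/SD/median/range for continuous,
#'   count for 0/1 flags).
#' @export
summary.pk_dataset <- function(object, ...) {
  obs <- object[object$EVID == 0L & object$MDV == 0L, , drop = FALSE]
  ids <- unique(object$ID)
  first <- object[!duplicated(object$ID), , drop = FALSE]
  skip <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV", "WT", "BLQ")
  covs <- setdiff(names(object), skip)
  cov_summary <- lapply(setNames(covs, covs), function(nm) {
    x <- first[[nm]]
    if (all(x %in% c(0, 1))) {
      list(type = "binary", count = sum(x), n = length(x))
    } else {
      list(type = "continuous", mean = mean(x), sd = sd(x),
           median = median(x), range = range(x))
    }
  })
  structure(list(
    n_subjects = length(ids),
    n_obs = nrow(obs),
    obs_per_subject = round(nrow(obs) / length(ids), 1),
    weight_median = median(first$WT),
    weight_range = range(first$WT),
    covariates = cov_summary), class = "pk_dataset_summary")
}

#' @export
print.pk_dataset_summary <- function(x, ...) {
  cat(sprintf("%d subjects, %d observations (mean %.1f per subject)\n",
              x$n_subjects, x$n_obs, x$obs_per_subject))
  cat(sprintf("Weight (kg): median %.2f (%.2f-%.2f)\n", x$weight_median,
              x$weight_range[1], x$weight_range[2]))
  for (nm in names(x$covariates)) {
    s <- x$covariates[[nm]]
    if (s$type == "binary")
      cat(sprintf("  %s: %d/%d\n", nm, s$count, s$n))
    else
      cat(sprintf("  %s: %.2f +/- %.2f, median %.2f (%.2f-%.2f)\n", nm,
                  s$mean, s$sd, s$median, s$range[1], s$range[2]))
  }
  invisible(x)
}
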