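#' Read an event-record dataset
#'
#' Reads the standard CSV event-record layout (one row per dose or
#' observation): `ID`, `TIME` (h postnatal age), `EVID` (1 dose, 0
#' observation), `AMT` (mg, doses only), `RATE` (mg/h, doses only), `DV`
#' (mg/L, observations only), `MDV`, and covariate columns `BW` (kg), `GA`
#' (weeks), `SD5` (0/1, audit column recomputed from `TIME`).  Extra
#' columns are carried through as subject-level covariates.
#'
#' @param path CSV file path.
#' @return A `gc_cohort` tibble.
#' @export
read_pk_dataset <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(df)
}

#' @rdname read_pk_dataset
#' @param cohort a data frame of event records to validate.
#' @export
validate_cohort <- function(cohort) {
  df <- tibble::as_tibble(cohort)
  req <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV", "BW", "GA")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_row <- function(cond, msg) {
    if (any(cond, na.rm = TRUE))
      stop(msg, " (rows ",
           paste(head(which(cond), 5), collapse = ", "), ")", call. = FALSE)
  }
  bad_row(!df$EVID %in% c(0, 1), "EVID must be 0 or 1")
  bad_row(df$TIME < 0, "negative TIME")
  dose <- df$EVID == 1
  bad_row(dose & (is.na(df$AMT) | df$AMT <= 0), "dose rows need AMT > 0")
  bad_row(dose & (is.na(df$RATE) | df$RATE <= 0), "dose rows need RATE > 0")
  bad_row(dose & !is.na(df$DV), "dose rows must not carry DV")
  bad_row(!dose & !is.na(df$AMT), "observation rows must not carry AMT")
  bad_row(!dose & df$MDV == 0 & is.na(df$DV),
          "observation rows need a DV value")
  if (any(!dose & df$MDV == 0 & df$DV < 0, na.rm = TRUE))
    warning("negative DV values present (untruncated simulated ",
            "concentrations); a real assay would report these as below ",
            "the quantification limit", call. = FALSE)
  bad_row(!is.finite(df$BW) | df$BW <= 0, "BW must be > 0")
  ord <- order(match(df$ID, unique(df$ID)), df$TIME, -df$EVID)
  if (!identical(ord, seq_len(nrow(df))))
    stop("records must be sorted by (ID, TIME, EVID descending); first ",
         "offending row: ", which(ord != seq_len(nrow(df)))[1],
         call. = FALSE)
  sd5 <- as.integer(df$TIME > DAY5_CUTOFF_H)
  if ("SD5" %in% names(df)) {
    bad_row(df$SD5 != sd5, "stored SD5 flag disagrees with TIME > 96 h")
  } else {
    df$SD5 <- sd5
  }
  structure(df, class = c("gc_cohort", class(tibble::tibble())))
}

#' Write an event-record dataset
#'
#' Inverse of [read_pk_dataset()].  Numeric fields are written with six
#' significant digits, which is lossless for generated cohorts (the
#' generator rounds to at most that precision) and makes output bytes
#' deterministic.
#'
#' @param cohort a `gc_cohort` (or compatible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    x <- signif(df[[j]], 6)
    df[[j]] <- ifelse(is.na(x), "", format(x, trim = TRUE, digits = 15,
                                           scientific = FALSE))
  }
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(df), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}
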