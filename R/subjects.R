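# internal: split an event-record cohort into per-subject design lists
# consumed by the C++ kernel.  Cohorts are kept sorted by (ID, TIME, EVID
# desc), so per-subject observation order matches the cohort row order.

CANONICAL_COLS <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV",
                    "BW", "GA", "SD5")

cohort_subjects <- function(cohort) {
  stopifnot(all(c("ID", "TIME", "EVID", "BW", "GA") %in% names(cohort)))
  ids <- unique(cohort$ID)
  extra_cols <- setdiff(names(cohort), CANONICAL_COLS)
  rows <- split(seq_len(nrow(cohort)), factor(cohort$ID, levels = ids))
  lapply(ids, function(id) {
    idx <- rows[[as.character(id)]]
    d <- cohort[idx, ]
    dose <- d[d$EVID == 1, ]
    obs <- d[d$EVID == 0, ]
    extras <- lapply(extra_cols, function(cc) d[[cc]][1])
    names(extras) <- extra_cols
    list(
      id = id,
      bw = d$BW[1],
      ga = d$GA[1],
      times = obs$TIME,
      y = obs$DV,
      dose_start = dose$TIME,
      dose_amt = dose$AMT,
      dose_dur = dose$AMT / dose$RATE,
      extras = extras
    )
  })
}

# typical values for one subject at sd5 = 0 (the day-5 step is applied by
# the solver as a clearance factor beyond 96 h); `cl_extra` multiplies
# clearance for covariate-search extensions
subject_tv_row <- function(params, s, cl_extra = 1) {
  fsize <- s$bw / KG_REF
  list(
    cl = params$cl_pop * fsize^0.75 *
      (s$ga / params$ga_median)^params$theta_cl_ga * cl_extra,
    vc = params$vc_pop * fsize,
    q = params$q_pop * fsize^0.75,
    vp = params$vp_pop * fsize
  )
}

# n x 4 typical-value matrix (TVCL at sd5 = 0, TVVc, TVQ, TVVp)
subject_tv_matrix <- function(params, subs, cl_extra = NULL) {
  n <- length(subs)
  if (is.null(cl_extra)) cl_extra <- rep(1, n)
  tv <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    r <- subject_tv_row(params, subs[[i]], cl_extra[i])
    tv[i, ] <- c(r$cl, r$vc, r$q, r$vp)
  }
  tv
}

# per-subject design lists in the exact shape cpp_cohort_ofv expects
subjects_for_cpp <- function(subs) {
  lapply(subs, function(s)
    list(times = as.numeric(s$times), y = as.numeric(s$y),
         dose_start = as.numeric(s$dose_start),
         dose_amt = as.numeric(s$dose_amt),
         dose_dur = as.numeric(s$dose_dur)))
}

omega2_vector <- function(params) {
  c(params$omega2_cl, params$omega2_vc, params$omega2_vp, params$omega2_eps)
}
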