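# fixtures built in code

params_truth <- function() gc_parameters()

small_design <- function(n = 12, profile = "external") {
  gc_design(profile, n_subjects = n)
}

small_cohort <- function(n = 12, seed = 101, params = params_truth(),
                         profile = "external") {
  generate_cohort(small_design(n, profile), params, seed = seed)
}

# one hand-built subject design (list shape used by simulate_subject)
manual_subject <- function(bw = 3.4, ga = 40,
                           times = c(25, 30, 48, 72, 100),
                           dose_times = c(6, 30, 54, 78, 102),
                           amt_per_kg = 4) {
  list(id = 1, bw = bw, ga = ga, times = times,
       y = rep(NA_real_, length(times)),
       dose_start = dose_times,
       dose_amt = rep(amt_per_kg * bw, length(dose_times)),
       dose_dur = rep(0.5, length(dose_times)),
       extras = list())
}

# doses tibble matching manual_subject
manual_doses <- function(s) {
  tibble::tibble(start_time = s$dose_start, amount = s$dose_amt,
                 duration = s$dose_dur)
}
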