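# internal helpers shared across modules

# allometric reference weight, kg
KG_REF <- 70

# postnatal age (h) beyond which the day-5 clearance increase applies;
# t = 96 h itself still belongs to the pre-day-5 period
DAY5_CUTOFF_H <- 96

# run `expr` under a temporary RNG seed, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# per-subject stream seeds derived from a master seed, so cohort order and
# parallel evaluation do not change per-subject draws
subject_seed <- function(master, id) {
  as.integer((as.numeric(master) + 104729 * as.numeric(id)) %% 2147483647L)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
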