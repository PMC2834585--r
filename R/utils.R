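# internal helpers shared across modules

# days from a reference date, as integer (all date arithmetic is whole days)
days_since <- function(dates, origin) as.integer(dates - origin)

# row-wise cumulative sum / max for a matrix (patients x visits)
row_cumsum <- function(m) {
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, cumsum))
}

row_cummax <- function(m) {
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, cummax))
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != trunc(x)) {
    abort(sprintf("`%s` must be a single positive integer", name))
  }
}

# first date in `dates` whose day offset from `origin` is nearest `target_day`;
# equidistant ties resolve to the earlier date
nearest_day <- function(days, target_day) {
  stopifnot(length(days) >= 1L)
  dist <- abs(days - target_day)
  cand <- which(dist == min(dist))
  days[cand[which.min(days[cand])]]
}
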