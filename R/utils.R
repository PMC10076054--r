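`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "paniclepipe_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## normalize a line angle (degrees) into (-90, 90]
norm_angle_deg <- function(theta) {
  out <- ((theta + 90) %% 180) - 90
  out[out <= -90] <- out[out <= -90] + 180
  out
}

## absolute angular difference between two line directions, in [0, 90]
angle_diff_deg <- function(a, b) {
  d <- abs(((a - b + 90) %% 180) - 90)
  d
}

## 2x2 counter-clockwise rotation matrix for local east/north coordinates
rot2 <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## With seed = NULL the current RNG stream is used untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## truncated-normal draw clamped into [lo, hi]
rnorm_clamped <- function(n, mean, sd, lo = 0, hi = 1) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0
is_pos <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x > 0
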