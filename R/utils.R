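# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-precision rounding with the half-up rule used for all reported
#' percentages (base R's `round()` rounds half to even, which would turn
#' 0.125 into 0.12 rather than 0.13).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_up(9.255, 2)  # 9.26, not 9.26/9.25 depending on binary repr.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so values stored as ...4999999 due to binary
  # representation of an exact decimal half still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Deterministic per-stage seed derivation: every stage of a run draws from
# its own stream derived from (master seed, stage name), so adding a stage
# never perturbs another stage's draws. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% (2^31 - 1))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# TSV helpers: all reports are plain tab-separated text so diffs stay
# reviewable.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# Condition labels are kept as (region, age_months) character pairs; this
# fixes the iteration order used by every reporting stage.
condition_grid <- function(regions = c("cortex", "hippocampus"),
                           ages = c("7", "18")) {
  data.frame(region = rep(regions, each = length(ages)),
             age = rep(ages, times = length(regions)),
             stringsAsFactors = FALSE)
}
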