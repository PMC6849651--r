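# Small shared helpers: matrix/tibble conversion, geometric means, seeded RNG.

#' Geometric mean with optional pseudocount for zeros
#'
#' Values of zero make a plain geometric mean collapse to zero (log of zero);
#' count normalization therefore adds a small pseudocount before taking logs
#' whenever any value in the vector is zero.
#'
#' @param x Non-negative numeric vector.
#' @param pseudocount Added to every value when any value is zero (default 0.5).
#' @return A single number, the geometric mean.
#' @examples
#' geo_mean(c(100, 400))  # 200
#' @export
geo_mean <- function(x, pseudocount = 0.5) {
  if (length(x) == 0L) abort("geo_mean: empty input")
  if (any(is.na(x))) abort("geo_mean: NA values")
  if (any(x < 0)) abort("geo_mean: negative values")
  if (any(x == 0)) x <- x + pseudocount
  exp(mean(log(x)))
}

# Wide counts tibble (probe + one column per sample) -> numeric matrix.
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "probe")
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$probe
  m
}

matrix_to_counts <- function(m, stage) {
  out <- tibble::as_tibble(m, rownames = "probe")
  attr(out, "stage") <- stage
  out
}

#' Processing stage of a count table
#'
#' @param counts A wide count tibble produced by [simulate_cohort()],
#'   [read_counts()] or the normalization functions.
#' @return One of `"raw"`, `"background_subtracted"`, `"normalized"` (or
#'   `NULL` if the table carries no stage marker).
#' @export
count_stage <- function(counts) attr(counts, "stage", exact = TRUE)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls do not disturb scripts.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# round() on IEEE doubles can misrepresent decimal half-way cases that arise
# as products of printed decimals (0.04225 * 10 -> 0.42250000000000004).
# A 12-significant-digit pre-clean restores decimal-faithful rounding.
round_dec <- function(x, digits) round(signif(x, 12), digits)

# Whole-percent reporting uses round-half-up (5/8 -> 63%), the convention
# of the published agreement figures.
pct <- function(x) as.integer(floor(signif(100 * x, 12) + 0.5))
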