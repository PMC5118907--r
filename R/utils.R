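# locale-independent string ordering (C collation via radix sort) so that
# canonical edge orientation and tie-breaks are reproducible everywhere

.chr_order <- function(...) order(..., method = "radix")

.chr_sort <- function(x) x[.chr_order(x)]

.chr_lt <- function(a, b) {
  # elementwise a < b under C collation: rank both against the sorted
  # unique pool, then compare integer ranks (vectorized, locale-free)
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  pool <- .chr_sort(unique(c(a, b)))
  match(a, pool) < match(b, pool)
}

.chr_pmin <- function(a, b) ifelse(.chr_lt(a, b), a, b)
.chr_pmax <- function(a, b) ifelse(.chr_lt(a, b), b, a)

#' Canonical key of an unordered pair
#'
#' Encodes unordered pairs as `"a|b"` with `a < b` under C collation, the
#' representation used for edge-set comparison throughout the package.
#'
#' @param a,b character vectors of endpoint labels.
#' @return Character vector of canonical keys.
#' @examples pairKey(c("TP53", "B"), c("AKT1", "A"))
#' @export
pairKey <- function(a, b) paste(.chr_pmin(a, b), .chr_pmax(a, b), sep = "|")

# run code under a fixed RNG state without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# numeric formatting that survives a text round trip at full precision
.fmt_num <- function(x) sprintf("%.17g", x)

.as_matrix_input <- function(x) {
  if (methods::is(x, "ExpressionMatrix")) exprsValues(x) else x
}
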