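# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators never disturb the global stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# signed (shoelace) area of a closed polygon; > 0 for counter-clockwise
polygon_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1L)
  sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2]) / 2
}

# triangle signed area from a 3x2 coordinate matrix
tri_area <- function(xy) {
  ((xy[2, 1] - xy[1, 1]) * (xy[3, 2] - xy[1, 2]) -
     (xy[3, 1] - xy[1, 1]) * (xy[2, 2] - xy[1, 2])) / 2
}

# do the open segments p1-p2 and p3-p4 properly intersect?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

# is the closed polygon simple (no crossing between non-adjacent edges)?
polygon_is_simple <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next      # adjacent through the wrap-around
      if (segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# 31-bit polynomial rolling hash of a character scalar, as 8 hex digits;
# used only to stamp outputs with a config fingerprint
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
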