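# Internal helpers: seeded sub-streams and small validators.

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream seed derived from a master seed and a string key.
# Keeps results independent of the order in which streams are consumed.
substream_seed <- function(master, ...) {
  key <- paste(..., sep = "/")
  m <- 2147483629 # large prime below 2^31
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  as.integer(((as.numeric(master) %% m) * 69621 + h) %% m) + 1L
}

is_binary01 <- function(x) {
  v <- x[!is.na(x)]
  all(v %in% c(0, 1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

# fraction rendered Table-2 style ("96.8%")
pct1 <- function(x) sprintf("%.1f%%", 100 * x)
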