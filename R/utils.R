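#' @keywords internal
"_PACKAGE"

# Open a connection that transparently handles gzip by extension.
ps_connection <- function(path, open = "r") {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

ps_stop <- function(...) stop(..., call. = FALSE)

# Evaluate expr with a temporarily fixed RNG state, restoring the caller's
# stream afterwards so generators never perturb one another.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

# Named-stream seed derivation: one substream per generator so adding a
# generator never changes the draws of the others.  Plain polynomial hash
# mod 2^31-1; exact in double arithmetic.
derive_seed <- function(seed, stream) {
  m <- 2147483647
  h <- 0
  for (ci in utf8ToInt(stream)) h <- (h * 131 + ci) %% m
  s <- (h + (seed %% m) * 48271) %% m
  as.integer(if (s == 0) 1 else s)
}

# Convert 0-based half-open peak/interval data.frame to GRanges (1-based
# closed) for overlap machinery.
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    ps_stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
}

# log-sum-exp for log-space tail accumulation
logsumexp <- function(lx) {
  if (!length(lx)) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}
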