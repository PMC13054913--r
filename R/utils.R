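# internal helpers shared across modules

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

.assertProb <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must lie in [%g, %g]", name, lo, hi), call. = FALSE)
  as.numeric(x)
}

# derive a child seed below 2^31 from a parent seed and a stage label
.childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103L + h * 12007L) %% 2147483629)
}

.zscore <- function(x) {
  s <- sd(x)
  if (s == 0) stop("cannot Z-score a constant vector", call. = FALSE)
  (x - mean(x)) / s
}

# center rows and scale to unit norm: correlation between rows becomes the
# dot product in this representation
.rowStandardize <- function(X) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  if (any(nrm == 0)) {
    bad <- rownames(X)[nrm == 0]
    if (is.null(bad)) bad <- which(nrm == 0)
    stop("constant row(s): correlation distance undefined for ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  Xc / nrm
}

# permutation p-value with the +1 correction
.permP <- function(nullStats, observed, side = c("ge", "le")) {
  side <- match.arg(side)
  hits <- if (side == "ge") sum(nullStats >= observed)
          else sum(nullStats <= observed)
  (1 + hits) / (length(nullStats) + 1)
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
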