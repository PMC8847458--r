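# Independent oracles used across the suite.

# DTW cost by explicit enumeration of all monotone alignment paths,
# written directly from the definition (no dynamic program).
bruteDtwR <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  lc <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + lc(i, j)
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# interior angle at the vertex via the law of cosines
lawOfCosinesAngle <- function(a, v, c) {
  d2 <- function(p, q) sum((p - q)^2)
  la2 <- d2(a, v); lc2 <- d2(c, v); lb2 <- d2(a, c)
  acos(min(1, max(-1, (la2 + lc2 - lb2) / (2 * sqrt(la2 * lc2))))) *
    180 / pi
}

# all sequences of the given lengths over an alphabet
enumerateSequences <- function(lengths, alphabet) {
  out <- list()
  for (len in lengths) {
    g <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ])))
  }
  out
}

# a minimal single-body-part PoseSeries from raw vectors
makeSeries <- function(x, y = rep(0, length(x)),
                       lik = rep(1, length(x)), fps = 120,
                       name = "toe") {
  PoseSeries(matrix(x, 1, dimnames = list(name, NULL)),
             matrix(y, 1), matrix(lik, 1), fps = fps)
}
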