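# Independent brute-force reference implementations used as oracles.
# They recompute everything per fragment with textbook formulas
# (stats::cor, explicit loops) and share no code with the package.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES4 <- c("A", "C", "G", "U")

randomRna <- function(n) paste(sample(BASES4, n, replace = TRUE),
                               collapse = "")
randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

.oracleSmooth <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    if (i > h && i <= n - h) mean(x[(i - h):(i + h)]) else NA_real_,
    numeric(1))
}

.oracleCenters <- function(vals, nAa, L) {
  out <- rep(NA_real_, L)
  P <- length(vals)
  if (nAa %% 2 == 1) {
    out[seq_len(P) + (3 * nAa - 1) / 2] <- vals
  } else if (P >= 2) {
    out[seq_len(P - 1) + 3 * nAa / 2] <- (vals[-P] + vals[-1]) / 2
  }
  out
}

# per-fragment re-extraction + fragment-local smoothing + stats::cor
oracleSlidingPearson <- function(rna, protein, scale, baseSet = c("C", "U"),
                                 w = 21) {
  ch <- strsplit(toupper(as.character(rna)), "")[[1]]
  ch[ch == "T"] <- "U"
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  v <- scaleValues(scale)[aa]
  x <- .oracleSmooth(v, w)
  x <- x[!is.na(x)]
  nAa <- length(aa)
  L <- length(ch)
  P <- L - 3 * nAa + 1
  Rs <- vapply(seq_len(P), function(p) {
    frag <- ch[p:(p + 3 * nAa - 1)]
    dens <- vapply(seq_len(nAa), function(j)
      mean(frag[3 * (j - 1) + 1:3] %in% baseSet), numeric(1))
    y <- .oracleSmooth(dens, w)
    y <- y[!is.na(y)]
    if (length(y) < 2 || stats::sd(y) < 1e-9 || stats::sd(x) < 1e-9)
      NA_real_ else stats::cor(x, y)
  }, numeric(1))
  .oracleCenters(Rs, nAa, L)
}

# explicit double loop over residues and bases, then boxcar mean and
# population z-scores
oracleEnergyProfile <- function(rna, protein, scales, sw = 63) {
  ch <- strsplit(toupper(as.character(rna)), "")[[1]]
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  aff <- lapply(scales, scaleValues)
  nAa <- length(aa)
  L <- length(ch)
  P <- L - 3 * nAa + 1
  E <- vapply(seq_len(P), function(p) {
    e <- 0
    for (j in seq_len(nAa)) {
      trip <- ch[p + 3 * (j - 1) + 0:2]
      for (b in BASES4)
        e <- e + aff[[b]][[aa[j]]] * sum(trip == b)
    }
    e
  }, numeric(1))
  raw <- .oracleCenters(E, nAa, L)
  def <- which(!is.na(raw))
  sm <- rep(NA_real_, L)
  sm[def] <- .oracleSmooth(raw[def], sw)
  d <- sm[!is.na(sm)]
  z <- (sm - mean(d)) / sqrt(mean((d - mean(d))^2))
  list(raw = raw, smoothed = sm, z = z)
}
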