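# Independent oracles used across the suite.

# Exhaustive formula enumerator: walks the full (c, h, o, n, s, p) grid with
# hydrogen enumerated explicitly, computes every candidate mass, and filters
# by the ppm window and the chemical rules.  Deliberately brute force and
# independent of enumerateFormulas(), which solves for H from the residual
# mass instead.  The grid (masses <= `maxMass`) is built once and cached.
.oracleCache <- new.env(parent = emptyenv())

oracleGrid <- function(maxMass = 510) {
  key <- as.character(maxMass)
  if (!is.null(.oracleCache[[key]])) return(.oracleCache[[key]])
  em <- c(c = 12, h = 1.00782503, o = 15.99491462, n = 14.00307401,
          s = 31.97207069, p = 30.97376151)
  g <- expand.grid(c = 1:min(100, floor(maxMass / em["c"])),
                   h = 1:min(250, floor(maxMass / em["h"])),
                   o = 0:min(100, floor(maxMass / em["o"])),
                   n = 0:4, s = 0:2, p = 0:1)
  g <- g[g$h <= 2 * g$c + 2 + g$n, ]
  dbe <- 1 + g$c - g$h / 2 + g$n / 2 + g$p / 2
  g <- g[dbe >= 0 & abs(dbe - round(dbe)) < 1e-9, ]
  g$mass <- g$c * em["c"] + g$h * em["h"] + g$o * em["o"] +
    g$n * em["n"] + g$s * em["s"] + g$p * em["p"]
  g <- g[g$mass <= maxMass, ]
  .oracleCache[[key]] <- g
  g
}

oracleEnumerate <- function(neutralMass, tolPpm, minOxygen = 1,
                            maxMass = 510) {
  stopifnot(neutralMass < maxMass - 1)
  g <- oracleGrid(maxMass)
  hit <- abs(g$mass - neutralMass) <= neutralMass * tolPpm * 1e-6 &
    g$o >= minOxygen
  out <- g[hit, , drop = FALSE]
  out[order(abs(out$mass - neutralMass)), , drop = FALSE]
}

# Hand-rolled Bray-Curtis for cross-checks, straight from the definition.
oracleBrayCurtis <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n))
    d[j, k] <- sum(abs(x[j, ] - x[k, ])) / sum(x[j, ] + x[k, ])
  d
}

# Random planar configuration with its exact Euclidean distance matrix.
planarConfig <- function(n, seed) {
  set.seed(seed)
  xy <- matrix(rnorm(2 * n), n, 2)
  list(xy = xy, d = as.matrix(dist(xy)))
}
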