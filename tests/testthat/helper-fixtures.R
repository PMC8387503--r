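# shared fixtures, all built in code

# three well-separated prey sources (reference-table values)
k3_sources <- function() {
  list(source_spec("ArcticKrill", NA, -18.7, 0.3, 9.3, 0.6, 28),
       source_spec("HerringEst", NA, -17.9, 0.9, 12.7, 0.6, 40),
       source_spec("NorthernKrill", NA, -19.5, 0.5, 10.7, 0.4, 110))
}

# one-group scenario over the k3 sources at a given true diet
k3_scenario <- function(p = c(0.7, 0.2, 0.1), n = 30L, seed = 1L,
                        tdf = tdf_spec()) {
  srcs <- k3_sources()
  d <- matrix(p, 1)
  colnames(d) <- paste0("diet.", vapply(srcs, `[[`, "", "name"))
  grp <- cbind(data.frame(group = "g1", period = "pre", n = as.integer(n)),
               as.data.frame(d))
  scenario(srcs, grp, tdf = tdf, seed = seed)
}

# random point on the K-simplex
rsimplex <- function(K) {
  g <- stats::rgamma(K, 1)
  g / sum(g)
}

# brute-force Benjamini-Yekutieli from the published formula
by_brute <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- sapply(seq_len(m), function(i)
    min(1, min(m * cm * ps[i:m] / (i:m))))
  out <- numeric(m)
  out[o] <- adj
  out
}
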