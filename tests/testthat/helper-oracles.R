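# Independent oracles used by the unit and acceptance tests. These are
# written directly from the operational definitions, with a different
# structure from the package implementation, so agreement is informative.

# Brute-force O(m^2) Benjamini-Hochberg step-up: for the k-th smallest
# p-value, the adjusted value is min over ranks j >= k of m * p_(j) / j,
# capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    best <- 1
    for (j in k:m) {
      best <- min(best, m * sorted[j] / j)
    }
    adj_sorted[k] <- best
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Transliteration of the regulon-membership sentences, one predicate per
# clause. "but not in the other strains" = the other single mutant is
# unchanged; the parenthetical exceptions permit only the opposite
# direction in the complementary triple mutant.
regulon_oracle <- function(b, d, bce, cde) {
  dn <- function(x) x == "DOWN"
  up <- function(x) x == "UP"
  ns <- function(x) x == "NS"

  if (dn(b) && dn(bce) && ns(d) && !dn(cde))
    return(c(label = "SigB", direction = "down"))
  if (up(b) && up(bce) && ns(d) && !up(cde))
    return(c(label = "SigB", direction = "up"))
  if (dn(d) && dn(cde) && ns(b) && !dn(bce))
    return(c(label = "SigD", direction = "down"))
  if (up(d) && up(cde) && ns(b) && !up(bce))
    return(c(label = "SigD", direction = "up"))
  if (dn(bce) && dn(cde) && ns(b) && ns(d))
    return(c(label = "SigCorE", direction = "down"))
  if (up(bce) && up(cde) && ns(b) && ns(d))
    return(c(label = "SigCorE", direction = "up"))

  calls <- c(b, d, bce, cde)
  n_reg <- sum(calls != "NS")
  if (n_reg >= 2) {
    dir <- if (all(calls[calls != "NS"] == "DOWN")) "down"
           else if (all(calls[calls != "NS"] == "UP")) "up"
           else "mixed"
    return(c(label = "shared", direction = dir))
  }
  c(label = "none", direction = "na")
}

# All 3^4 = 81 four-strain status patterns.
all_status_patterns <- function() {
  expand.grid(b = c("UP", "DOWN", "NS"), d = c("UP", "DOWN", "NS"),
              bce = c("UP", "DOWN", "NS"), cde = c("UP", "DOWN", "NS"),
              stringsAsFactors = FALSE)
}

# Small labeled count matrix builder.
make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "integer"
  m
}

# Two-group fixture: n genes, 3 + 3 columns with the given NB means.
two_group_counts <- function(n, mu_ref, mu_test, alpha, seed) {
  set.seed(seed)
  ref <- matrix(rnbinom(n * 3, mu = mu_ref, size = 1 / alpha), n)
  tst <- matrix(rnbinom(n * 3, mu = mu_test, size = 1 / alpha), n)
  make_counts(cbind(ref, tst))
}
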