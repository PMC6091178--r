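## Independent oracles used to cross-check the implementation.  These stay
## deliberately naive (two-pass formulas, exhaustive enumeration) and never
## call the code paths they verify.

## Two-pass sample Pearson coefficient straight from the definition.
naivePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

## Exhaustive (guide, gene) threshold enumeration over a raw value matrix.
## Returns a data.frame of passing pairs with their naive coefficient.
bruteForceEdges <- function(values, guideIds, poolIds, tau, strict = TRUE) {
  rows <- list()
  for (g in guideIds) {
    for (t in setdiff(poolIds, guideIds)) {
      r <- naivePearson(values[g, ], values[t, ])
      if (is.na(r)) next
      pass <- if (strict) abs(r) > tau else abs(r) >= tau
      if (pass)
        rows[[length(rows) + 1L]] <- data.frame(
          guide = g, tf = t, r = r,
          sign = if (r > 0) "positive" else "negative",
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    guide = character(), tf = character(), r = numeric(),
    sign = character()))))
  out[order(out$guide, out$tf, method = "radix"), , drop = FALSE]
}

## Build a CorrelationTable directly from a coefficient matrix.
makeCorTable <- function(r, nSamples = 11L) {
  methods::new("CorrelationTable", r = r, nSamples = as.integer(nSamples))
}

## Random nonnegative expression matrix for property tests.
randomGradient <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  m <- matrix(abs(rnorm(nGenes * nSamples, mean = 10, sd = 5)),
              nrow = nGenes,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  ExpressionGradient(m)
}

## The toy three-edge network shared by several tests:
## r(G1,t1)=0.7, r(G1,t2)=-0.65, r(G2,t2)=-0.61, r(G2,t3)=0.2.
toyNetwork <- function(spec = thresholdSpec(0.6)) {
  r <- matrix(c(0.7, -0.65, 0.1,
                0.3, -0.61, 0.2), nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), c("t1", "t2", "t3")))
  ann <- TFFamilyAnnotation(c(t1 = "G2-like", t2 = "G2-like", t3 = "MYB"))
  buildNetwork(makeCorTable(r), ann, family = "all", spec = spec)
}
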