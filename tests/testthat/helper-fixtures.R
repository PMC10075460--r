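# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Full pipeline at the default desk scale (shared by the acceptance
# suite and end-to-end unit checks).
default_pipeline <- function() {
  memoize("default_pipeline", {
    t0 <- Sys.time()
    res <- run_pipeline(seed = 20260101, outdir = NULL, quiet = TRUE)
    attr(res, "elapsed_s") <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  })
}

# Small design: full treatment structure, reduced feature counts, for
# fast unit tests that still exercise every stage.
small_config <- function() {
  cfg <- default_config()
  cfg$generator$n_windows <- 200
  cfg$generator$n_cytosines <- 2000
  cfg$generator$n_transcripts <- 300
  cfg$generator$n_dmr_treatment <- 5
  cfg$generator$n_dmr_salinity <- c(2, 4, 8)
  cfg$generator$n_de_core <- 20
  cfg$generator$n_de_private <- c(2, 5, 10)
  cfg$generator$n_de_rho2 <- 10
  cfg$generator$n_de_interaction <- 8
  cfg$thresholds$n_perm <- 99
  cfg
}

# Brute-force BH step-up oracle (independent of stats::p.adjust).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q_sorted[i] <- min(candidates, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive two-sided Fisher oracle: enumerate all tables with the
# observed margins and sum probabilities <= the observed one.
fisher_enumeration <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1)
  }, numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Tiny two-group methylation fixture builder.
make_methyl_table <- function(meth, unmeth, pos = NULL,
                              context = "CpG", chrom = "chr1") {
  n <- nrow(meth)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  sites <- data.frame(chrom = chrom, pos = pos,
                      strand = rep_len(c("+", "-"), n),
                      context = rep_len(context, n),
                      stringsAsFactors = FALSE)
  methylation_table(sites, meth, unmeth)
}
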