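# shared internal helpers

# round half away from zero (base round() is banker's rounding)
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# normalize chromosome labels: strip "chr" prefix; idempotent
normalizeChromosome <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

.validChromosomes <- c(as.character(1:22), "X", "Y")

# master seed -> per-stage child seed (kept below 2^31)
childSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stage)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
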