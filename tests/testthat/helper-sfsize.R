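# shared fixtures, built in code

# bounds wide enough to hold limit cases (T -> 0, m -> 0) that the default
# optimization box intentionally excludes
wideBounds <- function() {
  b <- matrix(c(1e-12, 1e3), 2, 4)
  dimnames(b) <- list(c("lower", "upper"), c("nu1", "nu2", "T", "m"))
  b
}

# panmictic limit: one population of size 1, split in the immediate past
panmicticParams <- function() {
  splitMigParams(1, 1, 1e-9, 1e-9, bounds = wideBounds())
}

recoveryTruth <- function() splitMigParams(2, 4, 0.5, 0.5)

# hand-buildable dataset from an explicit allele matrix
makeDataset <- function(alleles, n1, n2) {
  alleles <- matrix(as.integer(alleles), nrow = nrow(alleles))
  new("GenotypeDataset",
      alleles = alleles,
      sampleIds = c(sprintf("a%d", seq_len(n1)), sprintf("b%d", seq_len(n2))),
      pop = c(rep("pop1", n1), rep("pop2", n2)),
      locusIds = sprintf("L%d", seq_len(nrow(alleles))),
      provenance = list(origin = "test"))
}

quickDataset <- function(seed = 42, L = 600, n1 = 3, n2 = 3) {
  simulateDataset(simConfig(n1, n2, L, recoveryTruth(), 0.05, seed = seed))
}
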