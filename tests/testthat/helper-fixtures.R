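# Shared fixtures built in code.

dashSpec <- function() {
  scaleSpec(sprintf("item%02d", 1:30), maxCategory = 4,
            optionalFlags = sprintf("item%02d", 1:30) == "item21",
            testletMap = list(activity = sprintf("item%02d", 1:20),
                              impairment = sprintf("item%02d", 22:30)))
}

# small deterministic response file on disk (1-5 coding, one missing cell)
writeTinyResponseFile <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "person,sex,i1,i2,i3",
    "A,male,1,3,5",
    "B,female,2,,4",
    "C,male,5,5,5"), path)
  path
}

tinySpec <- function() scaleSpec(c("i1", "i2", "i3"), maxCategory = 4)

# quick PCM simulation shared across tests
simFixture <- function(n = 300, items = 6, seed = 123, ...) {
  simulateResponses(simulationConfig(nPersons = n, nItems = items,
                                     seed = seed, ...))
}
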