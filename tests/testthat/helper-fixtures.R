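# Shared molecule fixtures, parsed once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_smiles <- function() {
  named <- c(
    methane = "C", ethane = "CC", benzene = "c1ccccc1", toluene = "Cc1ccccc1",
    styrene = "C=Cc1ccccc1", stilbene = "c1ccccc1/C=C/c1ccccc1",
    biphenyl = "c1ccccc1-c1ccccc1", naphthalene = "c1ccc2ccccc2c1",
    triphenylamine = "N(c1ccccc1)(c1ccccc1)c1ccccc1",
    nitroaniline4 = "Nc1ccc(cc1)[N+](=O)[O-]",
    nitrobenzene = "c1ccccc1[N+](=O)[O-]", anisole = "COc1ccccc1",
    benzonitrile = "N#Cc1ccccc1", pyridine = "c1ccncc1", furan = "c1ccoc1",
    thiophene = "c1ccsc1", azobenzene = "c1ccccc1/N=N/c1ccccc1",
    cinnamaldehyde = "O=C/C=C/c1ccccc1", butadiene = "C=CC=C",
    dmabenzene = "CN(C)c1ccccc1", phenol = "Oc1ccccc1"
  )
  polyenes <- setNames(vapply(2:9, function(k) strrep("C=C", k), ""),
                       paste0("polyene", 2:9))
  dapoly <- setNames(vapply(2:4, function(k) {
    paste0("CN(C)", strrep("C=C", k), "[N+](=O)[O-]")
  }, ""), paste0("dapoly", 2:4))
  c(named, polyenes, dapoly)
}

fixture_mols <- function() {
  if (is.null(.fixture_env$mols)) {
    .fixture_env$mols <- parse_molecules(fixture_smiles())
  }
  .fixture_env$mols
}

# measurement-table CSV written to a temp file
write_toy_measurements <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE)
  path
}
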