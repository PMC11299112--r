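## shared fixtures built in code

speciesTree <- function() {
  readTree(system.file("extdata", "saccharomyces_species.nwk",
                       package = "orfancestry"))
}

quartetTree <- function() {
  readTree("((A:0.1,B:0.1)N1:0.1,(C:0.1,D:0.1)N2:0.1)Root;")
}

writeFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  close(con)
  path
}
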