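# The brute-force likelihood oracle ships with the package (inst/oracle/) so
# the acceptance script can reuse it; tests load the same definitions.
source(system.file("oracle", "brute-force.R", package = "codonsel"), local = FALSE)
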