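# grouped operations in the overlap scan use data.table semantics
.datatable.aware <- TRUE

utils::globalVariables(c("win", "pos", "pa", "pb", ".N", "n_males", "n_females"))
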