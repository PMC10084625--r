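# data.table is used through :: with non-standard evaluation inside `[`;
# this flag tells data.table the package is aware of its semantics.
.datatable.aware <- TRUE
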