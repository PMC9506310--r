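# let data.table find its special symbols when called via ::
.datatable.aware <- TRUE
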