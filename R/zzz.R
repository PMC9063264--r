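.datatable.aware <- TRUE

#' @importFrom data.table data.table setorderv fwrite :=
NULL
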