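analyte,value
chloride,145
sulphate,350
nitrate,19
fluoride,585
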