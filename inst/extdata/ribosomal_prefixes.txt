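# gene-symbol prefixes treated as ribosomal proteins
RPL
RPS
MRPL
MRPS
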