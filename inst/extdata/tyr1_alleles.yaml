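# TYR1 heteroallele system: ORF coordinates (1-based, inclusive) and the
# expected PCR amplicon size for each allele.
tolerance_bp: 50
alleles:
  - name: "TYR1"
    start: 1
    end: 1358
    amplicon_bp: 1360
  - name: "yr1"
    start: 300
    end: 1358
    amplicon_bp: 1060
  - name: "ty"
    start: 1
    end: 700
    amplicon_bp: 700
  - name: "y"
    start: 300
    end: 700
    amplicon_bp: 400
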