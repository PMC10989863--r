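# Gene classes removed before top-N candidate selection.
# First match wins; `target` says whether `pattern` applies to the gene-table
# class label or to the gene symbol.
- rule: mitochondrial
  target: class
  pattern: "^mitochondrial$"
- rule: mitochondrial_symbol
  target: symbol
  pattern: "^mt:"
- rule: CR_designation
  target: symbol
  pattern: "^CR[0-9]+$"
- rule: asRNA
  target: class
  pattern: "^asRNA$"
- rule: hpRNA
  target: class
  pattern: "^hpRNA$"
- rule: snRNA
  target: class
  pattern: "^snRNA$"
- rule: snRNP
  target: class
  pattern: "^snRNP$"
- rule: snmRNA
  target: class
  pattern: "^snmRNA$"
- rule: snoRNA
  target: class
  pattern: "^snoRNA$"
- rule: lncRNA
  target: class
  pattern: "^lncRNA$"
- rule: sisRNA
  target: class
  pattern: "^sisRNA$"
- rule: pre_rRNA
  target: class
  pattern: "^pre_rRNA$"
- rule: ribosomal_structural
  target: class
  pattern: "^ribosomal_protein$"
- rule: ribosomal_symbol
  target: symbol
  pattern: "^Rp[LS][0-9]"
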