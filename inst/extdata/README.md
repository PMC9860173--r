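# Bundled fixtures

* `example_motifs.meme` — four **synthetic** example PWMs in MEME minimal
  format (`gata_like`, `grh_like`, `zld_like`, `bcd_like`). They are
  hand-written caricatures of the corresponding motif families built for
  testing the parser, information-content and scanning code; they are
  *not* matrices from any published motif collection.
* `gata_counts.tsv` — the same GATA-style motif as a 4-column count
  table, for the TSV reader.
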