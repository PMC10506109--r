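{
  "duffy": {
    "external": "doORF",
    "internal": "intORF",
    "noncoding": "lncRNA-ORF",
    "lncRNA": "lncRNA-ORF",
    "antisense_RNA": "lncRNA-ORF",
    "misc_RNA": "lncRNA-ORF",
    "TEC": "lncRNA-ORF",
    "processed_transcript": "lncRNA-ORF",
    "uORF": "uORF",
    "uoORF": "uoORF",
    "dORF": "dORF",
    "doORF": "doORF"
  },
  "ouspenskaia": {
    "3' dORF": "dORF",
    "3' overlap dORF": "doORF",
    "5' overlap uORF": "uoORF",
    "5' uORF": "uORF",
    "lncRNA": "lncRNA-ORF",
    "out-of-frame": "intORF"
  },
  "chothani": {
    "dORF": "dORF",
    "doORF": "doORF",
    "intORF": "intORF",
    "uORF": "uORF",
    "ncORF": "lncRNA-ORF",
    "overlap_uORF": "uoORF"
  }
}
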