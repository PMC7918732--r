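# Packaged regulator lists (synthetic stand-ins)

`epigenetic_regulators_synthetic.tsv` and `tf_regulators_synthetic.tsv` are
**synthetic stand-ins** for the curated Arabidopsis predictor lists used by the
pipeline: 286 epigenetic regulators (174 histone modification, 62 DNA
methylation, 30 chromatin remodeling, 20 siRNA biogenesis) and 1717
transcription factors (AtTFDB-style). The class and category structure and the
list sizes match the curated resource exactly; a small number of
literature-anchored entries carry their real AGI locus ids and symbols (e.g.
SYD/AT2G28290, BRM/AT2G46020, JMJ30, HDT1-4, UBC1/2, HOG1, PRMT4A; TFs KNAT1,
KNAT4, COL5, CDF3), while the remaining rows use generated AGI-format
placeholder ids. The two lists are disjoint: a gene carried by both files would
be rejected at load time, because regulator class determines downstream
filtering.

Format: TSV with a header (`gene`, `symbol`, `category`); `#`-prefixed lines
are comments; `category` is one of `histone_modification`, `dna_methylation`,
`chromatin_remodeling`, `sirna` for epigenetic regulators and `none` for TFs.
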