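order,group
Spiriferida,PT_e
Productida,PT_e
Orthotetida,PT_e
Orthida,PT_e
Dictyonellida,PT_e
Lingulida,PT_s
Terebratulida,PT_s
Athyridida,PT_s
Rhynchonellida,PT_s
Spiriferinida,PT_s
Craniida,PT_s
Thecideida,PT_s
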